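PROB_EPS <- 1e-10

clip_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

#' Derive reproducible substream seeds
#'
#' One master seed drives every source of randomness in a simulation run.
#' Substreams (development draws, validation draws, tuning resamples, ...)
#' get their own integer seeds through this counter scheme, so each
#' replicate is independently reproducible regardless of execution order
#' or worker count.
#'
#' @param seed master integer seed.
#' @param n number of seeds to derive.
#' @param stream integer substream label; different streams yield
#'   independent seed sequences from the same master seed.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n, stream = 1L) {
  base <- (abs(as.numeric(seed)) + 1000003 * abs(as.numeric(stream))) %%
    2147483647
  withr::with_seed(as.integer(base), sample.int(2147483646L, n))
}

# Newton-Raphson logistic ML fit; the single fitting engine shared by
# fit_mle() and the calibration metrics. X must include any intercept
# column. Convergence: max |score|/n < tol. Separation is flagged when
# the score does not converge and coefficients have drifted large.
logit_ml <- function(X, y, offset = NULL, tol = 1e-10, maxit = 100) {
  X <- as.matrix(X)
  if (is.null(offset)) offset <- rep(0, nrow(X))
  fit <- cpp_logit_newton(X, y, offset, tol, maxit)
  list(coef = drop(fit$coef), converged = fit$converged,
       separated = fit$separated)
}

# Split a data frame with outcome `y`, covariates x1..xp and optional
# true_prob into the pieces the fitting code needs.
dataset_parts <- function(data, outcome = "y") {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with an outcome column and covariates.")
  }
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column '", outcome, "' not found in `data`."))
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) {
    abort("the outcome column must contain only 0/1 values.")
  }
  covs <- setdiff(names(data), c(outcome, "true_prob"))
  if (length(covs) == 0) abort("no covariate columns found.")
  X <- as.matrix(data[covs])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(y), covs = covs,
       true_prob = if ("true_prob" %in% names(data)) data$true_prob else NULL)
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    abort("both outcome classes must be present.")
  }
  invisible(TRUE)
}
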