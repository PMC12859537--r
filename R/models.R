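new_risk_fit <- function(intercept, coefs, method, lambda = NULL,
                         shrinkage_factor = NULL, converged = TRUE,
                         extra = list()) {
  structure(
    c(list(intercept = unname(intercept), coefs = coefs, method = method,
           lambda = lambda, shrinkage_factor = shrinkage_factor,
           converged = converged), extra),
    class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat("<risk_fit>", x$method)
  if (!is.null(x$lambda)) cat(sprintf("  lambda = %.5g", x$lambda))
  if (!is.null(x$shrinkage_factor)) {
    cat(sprintf("  shrinkage factor = %.4f", x$shrinkage_factor))
  }
  if (!x$converged) cat("  [not converged]")
  cat("\n  intercept:", signif(x$intercept, 5), "\n")
  print(signif(x$coefs, 5))
  invisible(x)
}

#' @export
coef.risk_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefs)
}

#' Predict from a fitted risk model
#'
#' @param object a `risk_fit`.
#' @param newdata data frame containing the model's covariate columns.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.risk_fit <- function(object, newdata,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  miss <- setdiff(names(object$coefs), names(newdata))
  if (length(miss)) {
    abort(paste("newdata lacks covariate columns:",
                paste(miss, collapse = ", ")))
  }
  X <- as.matrix(newdata[names(object$coefs)])
  lp <- object$intercept + drop(X %*% object$coefs)
  if (type == "link") lp else plogis(lp)
}

#' @export
tidy.risk_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefs)),
         estimate = c(x$intercept, unname(x$coefs)))
}

#' @export
glance.risk_fit <- function(x, ...) {
  tibble(method = x$method,
         lambda = if (is.null(x$lambda)) NA_real_ else x$lambda,
         shrinkage_factor = if (is.null(x$shrinkage_factor)) NA_real_
                            else x$shrinkage_factor,
         n_coef = length(x$coefs),
         n_zero = sum(x$coefs == 0),
         converged = x$converged)
}

#' Fit logistic regression by maximum likelihood
#'
#' Newton-Raphson maximisation of the binomial log-likelihood. Fits that
#' fail to converge (e.g., separated data, where the MLE does not exist)
#' are returned with `converged = FALSE` so callers can exclude and
#' count them.
#'
#' @param data data frame with outcome column `y`, covariate columns,
#'   and optionally `true_prob` (ignored).
#' @return a `risk_fit`.
#' @examples
#' d <- generate_dataset(scenario(), 400, seed = 2)
#' fit_mle(d)
#' @export
fit_mle <- function(data) {
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  Xi <- cbind(1, parts$X)
  fit <- logit_ml(Xi, parts$y)
  coefs <- fit$coef[-1]
  names(coefs) <- parts$covs
  new_risk_fit(fit$coef[1], coefs, "mle", converged = fit$converged,
               extra = list(separated = fit$separated))
}

#' Build a descending tuning-parameter grid
#'
#' For lasso the grid starts at the smallest `lambda` at which all
#' penalized coefficients are exactly zero (the maximum absolute score
#' of the standardized covariates at the null model); for ridge, which
#' has no finite all-zero `lambda`, the upper anchor is that value
#' scaled up by `ridge_scale`. Values are log-equispaced down to
#' `lambda_min_ratio` times the anchor.
#'
#' @param data development data frame (outcome `y` plus covariates).
#' @param form `"ridge"` or `"lasso"`.
#' @param n_lambda grid length.
#' @param lambda_min_ratio ratio of smallest to largest grid value.
#' @param ridge_scale multiplier applied to the lasso anchor for ridge.
#' @return descending numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(data, form = c("ridge", "lasso"), n_lambda = 100,
                        lambda_min_ratio = 1e-4, ridge_scale = 1000) {
  form <- match.arg(form)
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  # tiny relative margin so the all-zero property at the anchor is
  # robust to rounding in the solver's score comparison
  lmax <- lambda_max(parts$X, parts$y) * (1 + 1e-8)
  if (form == "ridge") lmax <- lmax * ridge_scale
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# smallest lambda with an all-zero lasso fit: max absolute null-model
# score of the standardized covariates, (1/n) |Xs' (y - ybar)|
lambda_max <- function(X, y) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, m)^2))
  if (any(s < 1e-12)) abort("constant covariate column; cannot build grid.")
  Xs <- sweep(sweep(X, 2, m), 2, s, "/")
  max(abs(crossprod(Xs, y - mean(y)))) / n
}

#' Fit penalized logistic regression at a given tuning parameter
#'
#' Maximises the penalized log-likelihood `(1/n) l(beta) - lambda * s(beta)`
#' with `s(beta) = ||beta||_1` (lasso) or `||beta||_2^2 / 2` (ridge);
#' covariates are standardized internally (mean 0, SD 1 with denominator
#' `n`), the intercept is never penalized, and coefficients are returned
#' on the original scale. Lasso coefficients can be exactly zero.
#' `lambda = 0` reproduces the MLE.
#'
#' @inheritParams fit_mle
#' @param form `"ridge"` or `"lasso"`.
#' @param lambda nonnegative tuning parameter.
#' @param tol KKT/gradient tolerance of the solver.
#' @param maxit iteration cap per grid point.
#' @return a `risk_fit` with `method = form` and the `lambda` used.
#' @examples
#' d <- generate_dataset(scenario(), 300, seed = 3)
#' fit_penalized(d, "ridge", lambda = 0.05)
#' @export
fit_penalized <- function(data, form = c("ridge", "lasso"), lambda,
                          tol = 1e-8, maxit = 10000) {
  form <- match.arg(form)
  stopifnot(length(lambda) == 1, lambda >= 0)
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  # short warm-start path down to the requested lambda
  lmax <- lambda_max(parts$X, parts$y)
  if (form == "ridge") lmax <- lmax * 1000
  lo <- max(lambda, lmax * 1e-6)
  path <- exp(seq(log(lmax), log(lo), length.out = 12L))
  if (lambda < lo) path <- c(path, lambda)
  res <- cpp_penlogit_path(parts$X, parts$y, path,
                           alpha = if (form == "lasso") 1 else 0,
                           tol = tol, dtol = 0, maxit = maxit)
  co <- res$coef[, ncol(res$coef)]
  coefs <- co[-1]
  names(coefs) <- parts$covs
  new_risk_fit(co[1], coefs, form, lambda = lambda,
               converged = res$converged)
}

#' Fit Firth's bias-reduced logistic regression with intercept correction
#'
#' Maximises `l(beta) + 0.5 * log det I(beta)` by modified-score Newton
#' iteration (hat-diagonal score adjustment, step-halving, convergence
#' on score norm). Estimates remain finite under separation. The
#' intercept is then re-estimated alone by maximum likelihood with the
#' Firth linear predictor (minus its intercept) as a fixed offset, so
#' the mean predicted probability equals the observed event fraction.
#'
#' @inheritParams fit_mle
#' @param tol convergence tolerance on the modified score (max norm).
#' @param maxit iteration cap.
#' @return a `risk_fit` with `method = "firth"`.
#' @export
fit_firth <- function(data, tol = 1e-6, maxit = 100) {
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  X <- cbind(1, parts$X)
  y <- parts$y
  n <- nrow(X)
  q <- ncol(X)
  beta <- c(qlogis(mean(y)), numeric(q - 1))
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    ll + 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
  }
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    h <- rowSums((XW %*% solve(XtWX)) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    if (max(abs(U)) < tol) {
      converged <- TRUE
      break
    }
    d <- drop(solve(XtWX, U))
    f0 <- pen_ll(beta)
    step <- 1
    for (hh in 1:30) {
      bn <- beta + step * d
      if (pen_ll(bn) >= f0 - 1e-10) break
      step <- step / 2
    }
    beta <- bn
  }
  # intercept correction: ML re-estimation with fixed slope offset
  offs <- drop(parts$X %*% beta[-1])
  ic <- logit_ml(matrix(1, n, 1), y, offset = offs, tol = 1e-12)
  coefs <- beta[-1]
  names(coefs) <- parts$covs
  new_risk_fit(ic$coef[1], coefs, "firth", converged = converged,
               extra = list(uncorrected_intercept = beta[1]))
}

#' Fit bootstrap uniform shrinkage
#'
#' Fits the MLE, then estimates a single shrinkage factor as the average
#' calibration slope of models fitted on bootstrap resamples and
#' evaluated on the original data. All slopes are multiplied by this
#' factor and the intercept is re-estimated by maximum likelihood so the
#' average predicted probability equals the outcome prevalence.
#' Resamples whose MLE fails (separation, single-class draw) are skipped
#' and counted; more than 50% failures aborts with a diagnostic.
#'
#' @inheritParams fit_mle
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for resampling.
#' @return a `risk_fit` with `method = "boot_unif"`, the
#'   `shrinkage_factor`, and per-resample slopes in `$boot_slopes`.
#' @export
fit_boot_unif <- function(data, n_boot = 200, seed = 1L) {
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  X <- parts$X
  y <- parts$y
  n <- nrow(X)
  base <- fit_mle(data)
  if (!base$converged) {
    abort("MLE on the original data did not converge; cannot shrink.")
  }
  Xi <- cbind(1, X)
  idx <- withr::with_seed(as.integer(seed),
                          matrix(sample.int(n, n * n_boot, replace = TRUE),
                                 nrow = n))
  slopes <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    rows <- idx[, b]
    yb <- y[rows]
    if (length(unique(yb)) < 2) next
    fb <- logit_ml(Xi[rows, , drop = FALSE], yb)
    if (!fb$converged) next
    lp <- drop(Xi %*% fb$coef)   # bootstrap model on the *original* data
    slopes[b] <- calibration_slope(y, lp)
  }
  n_failed <- sum(is.na(slopes))
  if (n_failed > n_boot / 2) {
    abort(sprintf("%d of %d bootstrap fits failed; aborting.",
                  n_failed, n_boot))
  }
  shrink <- mean(slopes, na.rm = TRUE)
  coefs <- shrink * base$coefs
  ic <- logit_ml(matrix(1, n, 1), y, offset = drop(X %*% coefs),
                 tol = 1e-12)
  new_risk_fit(ic$coef[1], coefs, "boot_unif",
               shrinkage_factor = shrink,
               extra = list(boot_slopes = slopes, n_failed = n_failed))
}

#' Serialize a fitted model to structured text
#'
#' Writes method, tuning parameter, shrinkage factor, intercept and
#' named coefficients as JSON for audit and reuse.
#'
#' @param fit a `risk_fit`.
#' @param path file path.
#' @export
write_risk_fit <- function(fit, path) {
  stopifnot(inherits(fit, "risk_fit"))
  x <- list(method = fit$method, lambda = fit$lambda,
            shrinkage_factor = fit$shrinkage_factor,
            converged = fit$converged,
            intercept = fit$intercept, coefs = as.list(fit$coefs))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(fit)
}

#' @rdname write_risk_fit
#' @export
read_risk_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_risk_fit(x$intercept, unlist(x$coefs), x$method,
               lambda = x$lambda, shrinkage_factor = x$shrinkage_factor,
               converged = isTRUE(x$converged))
}
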