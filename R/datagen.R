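#' Generate a synthetic development or validation dataset
#'
#' Draws `n` covariate rows from a multivariate normal distribution with
#' mean zero and the scenario's block correlation matrix (unit
#' variances), computes the true event probabilities
#' `plogis(beta0 + (k * base_coefs)' x)`, and draws Bernoulli outcomes.
#' Bit-reproducible for a given `seed`.
#'
#' @param scn a [scenario()] with `k` and `beta0` set (see
#'   [calibrate_dgm()] if they are `NA`).
#' @param n number of rows.
#' @param seed integer seed.
#' @return a tibble with columns `y`, `x1` ... `xp` and `true_prob`.
#' @examples
#' d <- generate_dataset(scenario(), n = 200, seed = 1)
#' mean(d$y)
#' @export
generate_dataset <- function(scn, n, seed = 1L) {
  stopifnot(inherits(scn, "scenario"), n >= 1)
  if (is.na(scn$k) || is.na(scn$beta0)) {
    abort("scenario has uncalibrated k/beta0; run calibrate_dgm() first.")
  }
  p <- scn$p_true + scn$p_noise
  R <- chol(scenario_sigma(scn))
  beta <- scn$k * scn$base_coefs
  out <- withr::with_seed(as.integer(seed), {
    X <- matrix(rnorm(n * p), n, p) %*% R
    pr <- plogis(scn$beta0 + drop(X %*% beta))
    y <- rbinom(n, 1L, pr)
    list(X = X, pr = pr, y = y)
  })
  colnames(out$X) <- paste0("x", seq_len(p))
  d <- as_tibble(out$X)
  d <- tibble(y = out$y) |> dplyr::bind_cols(d)
  d$true_prob <- out$pr
  attr(d, "scenario") <- scn
  attr(d, "seed") <- as.integer(seed)
  d
}

#' Calibrate the data-generating mechanism to its targets
#'
#' Finds the intercept `beta0` and coefficient multiplier `k` such that
#' the generated outcomes match the scenario's target prevalence and the
#' true linear predictor attains the target C-statistic. The search uses
#' a large calibration sample (default 500,000 rows) with common random
#' numbers, alternating bisection in `k` (the C-statistic is monotone
#' increasing in `k`) and in `beta0` (prevalence is monotone increasing
#' in `beta0`), until both achieved values are within `tol` of target.
#'
#' @param scn a [scenario()]; its `k`/`beta0` values are ignored and
#'   re-estimated from `target_prevalence` and `target_c`.
#' @param n_calib calibration sample size.
#' @param seed integer seed for the calibration sample.
#' @param tol absolute tolerance on achieved prevalence and C-statistic.
#' @param k_range,beta0_range bisection brackets.
#' @return the scenario with `k` and `beta0` set; achieved values are in
#'   `attr(, "calibration")`.
#' @examples
#' \donttest{
#' scn <- scenario(target_prevalence = 0.5, target_c = 0.7, k = NA)
#' scn <- calibrate_dgm(scn, n_calib = 1e5, seed = 7)
#' scn$k
#' }
#' @export
calibrate_dgm <- function(scn, n_calib = 5e5, seed = 1L, tol = 0.005,
                          k_range = c(0.01, 10), beta0_range = c(-10, 10)) {
  stopifnot(inherits(scn, "scenario"))
  p <- scn$p_true + scn$p_noise
  R <- chol(scenario_sigma(scn))
  lp0 <- withr::with_seed(as.integer(seed), {
    X <- matrix(rnorm(n_calib * p), n_calib, p) %*% R
    drop(X %*% scn$base_coefs)
  })
  # Bernoulli layer integrated out (conditional expectation given the
  # simulated covariate sample): prevalence is the mean event
  # probability, and the C-statistic of the linear predictor is
  # sum_{i,j} p_i (1-p_j) 1(lp_i > lp_j) / (sum p)(sum (1-p)),
  # computed in O(n) on the sorted linear predictor
  lps <- sort(lp0)
  prev_at <- function(beta0, k) mean(plogis(beta0 + k * lp0))
  c_at <- function(beta0, k) {
    ps <- plogis(beta0 + k * lps)
    q <- 1 - ps
    below <- cumsum(q) - q   # sum of (1 - p_j) over lp_j < lp_i
    sum(ps * below) / (sum(ps) * sum(q))
  }

  # bisection to a small parameter interval: stopping on the achieved
  # value alone would leave the parameter imprecise wherever the
  # response curve is flat
  bisect <- function(f, lo, hi, target, what, xtol = 1e-3) {
    flo <- f(lo); fhi <- f(hi)
    if ((flo - target) * (fhi - target) > 0) {
      abort(sprintf(
        "cannot bracket target %s=%g: achieved range [%.4f, %.4f].",
        what, target, flo, fhi))
    }
    while (hi - lo > xtol) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  k <- if (is.na(scn$k)) mean(k_range) else scn$k
  beta0 <- 0
  for (round in 1:8) {
    beta0 <- bisect(function(b) prev_at(b, k),
                    beta0_range[1], beta0_range[2],
                    scn$target_prevalence, "prevalence")
    k <- bisect(function(kk) c_at(beta0, kk),
                k_range[1], k_range[2], scn$target_c, "C-statistic")
    ok <- abs(prev_at(beta0, k) - scn$target_prevalence) < tol &&
      abs(c_at(beta0, k) - scn$target_c) < tol
    if (ok) break
  }
  scn$k <- k
  scn$beta0 <- beta0
  attr(scn, "calibration") <- list(
    achieved_prevalence = prev_at(beta0, k),
    achieved_c = c_at(beta0, k),
    n_calib = n_calib, seed = as.integer(seed), tol = tol)
  scn
}

#' Read or write datasets as delimited text
#'
#' Datasets are stored as CSV with a header row: outcome column `y`,
#' covariates `x1` ... `xp`, and optionally `true_prob`.
#'
#' @param data a data frame as produced by [generate_dataset()].
#' @param path file path.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  dataset_parts(d)  # validates shape
  d
}
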