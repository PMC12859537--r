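#' Assemble a block correlation matrix for true and noise predictors
#'
#' True predictors form one equicorrelated block, noise predictors a
#' second, with a common cross-block correlation. The default study
#' design uses weak correlations: 0.1 within the true block, 0.05 within
#' the noise block, and 0 across blocks.
#'
#' @param p_true,p_noise number of true / noise predictors.
#' @param r_true,r_noise,r_cross pairwise correlations within the true
#'   block, within the noise block, and between blocks.
#' @return a `(p_true + p_noise)` square correlation matrix.
#' @examples
#' build_correlation_matrix(5, 7, 0.1, 0.05, 0)
#' @export
build_correlation_matrix <- function(p_true, p_noise, r_true = 0.1,
                                     r_noise = 0.05, r_cross = 0) {
  stopifnot(p_true >= 0, p_noise >= 0, p_true + p_noise >= 1)
  rs <- c(r_true, r_noise, r_cross)
  if (any(abs(rs) >= 1)) abort("all correlations must satisfy |r| < 1.")
  p <- p_true + p_noise
  S <- matrix(0, p, p)
  if (p_true > 0) S[seq_len(p_true), seq_len(p_true)] <- r_true
  if (p_noise > 0) {
    idx <- p_true + seq_len(p_noise)
    S[idx, idx] <- r_noise
    if (p_true > 0) {
      S[seq_len(p_true), idx] <- r_cross
      S[idx, seq_len(p_true)] <- r_cross
    }
  }
  diag(S) <- 1
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    abort(sprintf(paste0(
      "correlations (r_true=%g, r_noise=%g, r_cross=%g) do not give a ",
      "positive definite matrix (smallest eigenvalue %.3g)."),
      r_true, r_noise, r_cross, ev))
  }
  S
}

#' Define a data-generating scenario
#'
#' A scenario fully specifies the synthetic data-generating mechanism:
#' covariates are multivariate normal with mean zero, unit variances and
#' a block correlation structure; the binary outcome follows a logistic
#' model with linear predictor `beta0 + (k * base_coefs)' x`. The
#' defaults give the main study condition: 5 true and 7 noise predictors,
#' base coefficients (0.5, 0.3, 0.3, 0.25, 0.25, 0, ..., 0), `beta0 = 0`
#' and `k = 0.93`, which yield outcome prevalence 0.5 and a true
#' C-statistic of 0.7.
#'
#' @param p_true,p_noise number of true / noise predictors.
#' @param base_coefs pre-scaling coefficient vector of length
#'   `p_true + p_noise` with exactly `p_noise` trailing zeros.
#' @param k positive scalar multiplier applied to `base_coefs`; controls
#'   model strength (C-statistic). `NA` if still to be calibrated.
#' @param beta0 intercept; controls outcome prevalence. `NA` if still to
#'   be calibrated.
#' @param r_true,r_noise,r_cross block correlations, see
#'   [build_correlation_matrix()].
#' @param target_prevalence,target_c targets used by [calibrate_dgm()].
#' @return an object of class `"scenario"`.
#' @examples
#' scenario()                      # the main study condition
#' scenario(target_prevalence = 0.1, target_c = 0.8, k = NA, beta0 = NA)
#' @export
scenario <- function(p_true = 5, p_noise = 7,
                     base_coefs = c(0.5, 0.3, 0.3, 0.25, 0.25,
                                    rep(0, p_noise)),
                     k = 0.93, beta0 = 0,
                     r_true = 0.1, r_noise = 0.05, r_cross = 0,
                     target_prevalence = 0.5, target_c = 0.7) {
  p <- p_true + p_noise
  if (length(base_coefs) != p) {
    abort("`base_coefs` must have length p_true + p_noise.")
  }
  if (p_noise > 0 && any(base_coefs[p_true + seq_len(p_noise)] != 0)) {
    abort("`base_coefs` must end in exactly p_noise zeros.")
  }
  if (!is.na(k) && k <= 0) abort("`k` must be positive.")
  stopifnot(target_prevalence > 0, target_prevalence < 1,
            target_c > 0.5, target_c < 1)
  # validates positive definiteness as a side effect
  build_correlation_matrix(p_true, p_noise, r_true, r_noise, r_cross)
  structure(
    list(p_true = p_true, p_noise = p_noise, base_coefs = base_coefs,
         k = k, beta0 = beta0, r_true = r_true, r_noise = r_noise,
         r_cross = r_cross, target_prevalence = target_prevalence,
         target_c = target_c),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$p_true, "true +", x$p_noise, "noise predictors\n")
  cat("  base_coefs:", paste(signif(x$base_coefs, 3), collapse = ", "), "\n")
  cat(sprintf("  k = %s, beta0 = %s\n", format(x$k), format(x$beta0)))
  cat(sprintf("  correlations: true %g, noise %g, cross %g\n",
              x$r_true, x$r_noise, x$r_cross))
  cat(sprintf("  targets: prevalence %g, C-statistic %g\n",
              x$target_prevalence, x$target_c))
  invisible(x)
}

scenario_sigma <- function(scn) {
  build_correlation_matrix(scn$p_true, scn$p_noise, scn$r_true,
                           scn$r_noise, scn$r_cross)
}

#' Read or write a scenario definition as YAML
#'
#' @param scn a [scenario()] object.
#' @param path file path.
#' @return `read_scenario()` returns a `"scenario"`; `write_scenario()`
#'   returns `scn` invisibly.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  yaml::write_yaml(unclass(scn), path)
  invisible(scn)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  f <- yaml::read_yaml(path)
  do.call(scenario, f)
}
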