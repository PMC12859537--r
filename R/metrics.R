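#' Calibration slope
#'
#' Slope from the logistic regression of the binary outcome on a
#' model's linear predictor in validation data. 1 indicates perfect
#' calibration, < 1 overfitting (predictions too extreme), > 1
#' over-shrinkage. Returns `NA` for a degenerate (constant) linear
#' predictor or when the calibration fit itself is separated.
#'
#' @param y binary outcome vector (0/1).
#' @param lp linear predictor (log-odds scale).
#' @return slope, or `NA_real_` when undefined.
#' @examples
#' d <- generate_dataset(scenario(), 5000, seed = 4)
#' lp <- qlogis(d$true_prob)
#' calibration_slope(d$y, lp)  # close to 1: perfectly specified model
#' @export
calibration_slope <- function(y, lp) {
  check_two_classes(y)
  if (diff(range(lp)) < 1e-12) return(NA_real_)
  fit <- logit_ml(cbind(1, lp), y)
  if (!fit$converged || fit$separated) return(NA_real_)
  unname(fit$coef[2])
}

#' Calibration in-the-large
#'
#' Intercept of the logistic regression of the outcome with the linear
#' predictor as a fixed offset (slope forced to 1). 0 means the average
#' predicted probability equals the observed event proportion.
#'
#' @inheritParams calibration_slope
#' @return intercept on the log-odds scale.
#' @export
calibration_in_the_large <- function(y, lp) {
  check_two_classes(y)
  fit <- logit_ml(matrix(1, length(y), 1), y, offset = lp, tol = 1e-12)
  unname(fit$coef[1])
}

#' C-statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen event receives a higher predicted
#' risk than a randomly chosen non-event, ties counted one half.
#' Computed by midranks, equivalent to the all-pairs definition.
#'
#' @param y binary outcome vector (0/1).
#' @param p predictions (any monotone score).
#' @return value in `[0, 1]`.
#' @examples
#' c_statistic(c(1, 0, 1), c(0.9, 0.2, 0.2))  # (1 + 0.5) / 2
#' @export
c_statistic <- function(y, p) {
  check_two_classes(y)
  stopifnot(length(y) == length(p))
  cpp_cstat(as.numeric(y), as.numeric(p))
}

#' Brier score
#'
#' Mean squared difference between outcome and predicted probability.
#'
#' @inheritParams c_statistic
#' @export
brier_score <- function(y, p) {
  stopifnot(length(y) == length(p), all(p >= 0 & p <= 1))
  mean((y - p)^2)
}

#' Root mean square prediction error against true probabilities
#'
#' `sqrt(mean((true_p - est_p)^2))`; available in simulations where the
#' data-generating probabilities are known.
#'
#' @param true_p true event probabilities.
#' @param est_p estimated probabilities.
#' @export
rmspe <- function(true_p, est_p) {
  stopifnot(length(true_p) == length(est_p))
  sqrt(mean((true_p - est_p)^2))
}

#' Root mean square distance of the log calibration slope from target
#'
#' `sqrt(mean((log(cs) - log(target))^2))` over simulation replicates;
#' combines bias and variability of the calibration slope in one
#' number. Missing or nonpositive slopes must be excluded (and counted)
#' by the caller.
#'
#' @param cs_values positive calibration slopes, one per replicate.
#' @param target target slope (default 1, perfect calibration).
#' @export
rmsd_log_cs <- function(cs_values, target = 1) {
  if (length(cs_values) == 0) abort("empty calibration slope vector.")
  if (any(!is.finite(cs_values) | cs_values <= 0)) {
    abort("calibration slopes must be positive and non-missing; exclude degenerate replicates upstream.")
  }
  sqrt(mean((log(cs_values) - log(target))^2))
}

#' Probability of a well-calibrated model
#'
#' Proportion of replicates whose calibration slope falls inside
#' `[lo, hi]` (inclusive). Missing slopes count as not well calibrated.
#'
#' @inheritParams rmsd_log_cs
#' @param lo,hi well-calibration band (default 0.9 to 1.1).
#' @export
p_well_cal <- function(cs_values, lo = 0.9, hi = 1.1) {
  if (length(cs_values) == 0) abort("empty calibration slope vector.")
  mean(!is.na(cs_values) & cs_values >= lo & cs_values <= hi)
}

#' Paired head-to-head win proportion
#'
#' Proportion of paired replicates in which method A beats method B on
#' a metric; ties and pairs with missing values count as no win.
#'
#' @param metric_a,metric_b paired metric vectors (same replicates).
#' @param better `"less"` if smaller is better (e.g., `|log CS|`,
#'   RMSPE), `"greater"` if larger is better (e.g., C-statistic).
#' @export
head_to_head <- function(metric_a, metric_b, better = c("less", "greater")) {
  better <- match.arg(better)
  if (length(metric_a) != length(metric_b)) {
    abort("paired metric vectors must have the same length.")
  }
  win <- if (better == "less") metric_a < metric_b else metric_a > metric_b
  mean(ifelse(is.na(win), FALSE, win))
}

#' Validate a fitted model on new data
#'
#' Computes calibration slope, calibration in-the-large, C-statistic,
#' Brier score and (when `true_prob` is present in `newdata`) RMSPE.
#'
#' @param fit a `risk_fit`.
#' @param newdata validation data frame with outcome `y` and the model's
#'   covariates; a `true_prob` column enables RMSPE.
#' @return one-row tibble.
#' @export
validate_model <- function(fit, newdata) {
  validate_parts(fit, dataset_parts(newdata))
}

# shared with the simulation loop, which pre-splits the validation draw
# once per replicate instead of once per method
validate_parts <- function(fit, parts) {
  lp <- fit$intercept +
    drop(parts$X[, names(fit$coefs), drop = FALSE] %*% fit$coefs)
  p <- plogis(lp)
  tibble(
    method = fit$method,
    cs = calibration_slope(parts$y, lp),
    citl = calibration_in_the_large(parts$y, lp),
    c_stat = c_statistic(parts$y, p),
    brier = brier_score(parts$y, p),
    rmspe = if (is.null(parts$true_prob)) NA_real_
            else rmspe(parts$true_prob, p))
}
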