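SIM_METHODS <- c("mle", "firth", "boot_unif", "ridge", "lasso",
                 "mod_ridge", "mod_lasso", "boot_ridge", "boot_lasso")

fit_method <- function(method, dev, k_folds, B, repeats, n_boot,
                       n_lambda, tune_seed) {
  switch(
    method,
    mle = fit_mle(dev),
    firth = fit_firth(dev),
    boot_unif = fit_boot_unif(dev, n_boot = n_boot, seed = tune_seed),
    ridge = fit_tuned(dev, tune_standard(dev, "ridge", k = k_folds,
                                         seed = tune_seed,
                                         repeats = repeats,
                                         n_lambda = n_lambda)),
    lasso = fit_tuned(dev, tune_standard(dev, "lasso", k = k_folds,
                                         seed = tune_seed,
                                         repeats = repeats,
                                         n_lambda = n_lambda)),
    mod_ridge = fit_tuned(dev, tune_modified(dev, "ridge", k = k_folds,
                                             B = B, seed = tune_seed,
                                             n_lambda = n_lambda)),
    mod_lasso = fit_tuned(dev, tune_modified(dev, "lasso", k = k_folds,
                                             B = B, seed = tune_seed,
                                             n_lambda = n_lambda)),
    boot_ridge = fit_tuned(dev, tune_bootstrap(dev, "ridge", B = B,
                                               seed = tune_seed,
                                               n_lambda = n_lambda)),
    boot_lasso = fit_tuned(dev, tune_bootstrap(dev, "lasso", B = B,
                                               seed = tune_seed,
                                               n_lambda = n_lambda)),
    abort(paste("unknown method:", method)))
}

#' Run the Monte Carlo simulation for one scenario and sample size
#'
#' For each replicate, generates an independent development dataset of
#' size `n` and validation dataset of size `nval` from the scenario,
#' fits every requested method to the development data, and computes
#' validation metrics on the shared validation draw (so method
#' comparisons are paired). Per-replicate fitting failures (e.g.,
#' separation) are recorded as missing rows, never abort the run. Fully
#' reproducible from `seed`: each replicate's development, validation
#' and tuning seeds come from [derive_seeds()] substreams.
#'
#' @param scn a calibrated [scenario()].
#' @param n development sample size.
#' @param methods subset of `"mle"`, `"firth"`, `"boot_unif"`,
#'   `"ridge"`, `"lasso"`, `"mod_ridge"`, `"mod_lasso"`,
#'   `"boot_ridge"`, `"boot_lasso"`.
#' @param nsim number of replicates.
#' @param nval validation sample size per replicate.
#' @param k_folds folds for cross-validation tuning.
#' @param B resamples for modified/bootstrap tuning.
#' @param repeats repeated cross-validation count for standard tuning.
#' @param n_boot resamples for bootstrap uniform shrinkage.
#' @param n_lambda tuning grid length.
#' @param seed master seed.
#' @param output_dir optional directory; when given, per-replicate and
#'   summary CSVs are written there.
#' @return an object of class `"sim_result"`: a list with the
#'   per-replicate `metrics` tibble (columns `replicate`, `method`,
#'   `n`, `cs`, `citl`, `c_stat`, `brier`, `rmspe`, `lambda`,
#'   `shrinkage`, `converged`), the scenario and the configuration.
#' @examples
#' \donttest{
#' scn <- scenario()
#' sim <- run_scenario(scn, n = 300, methods = "mle", nsim = 20,
#'                     nval = 2000, seed = 9)
#' summary(sim)
#' }
#' @export
run_scenario <- function(scn, n, methods = c("mle", "mod_ridge"),
                         nsim = 100, nval = 50000, k_folds = 10, B = 100,
                         repeats = 1, n_boot = 200, n_lambda = 100,
                         seed = 1L, output_dir = NULL) {
  stopifnot(inherits(scn, "scenario"), nsim >= 1, nval >= 1000)
  methods <- match.arg(methods, SIM_METHODS, several.ok = TRUE)
  dev_seeds <- derive_seeds(seed, nsim, stream = 11L)
  val_seeds <- derive_seeds(seed, nsim, stream = 12L)
  tune_seeds <- derive_seeds(seed, nsim * length(methods), stream = 13L)
  rows <- vector("list", nsim * length(methods))
  ri <- 0L
  for (i in seq_len(nsim)) {
    dev <- generate_dataset(scn, n, dev_seeds[i])
    val <- generate_dataset(scn, nval, val_seeds[i])
    val_parts <- dataset_parts(val)
    for (m in seq_along(methods)) {
      ri <- ri + 1L
      ts <- tune_seeds[(i - 1L) * length(methods) + m]
      row <- tryCatch({
        fit <- fit_method(methods[m], dev, k_folds, B, repeats, n_boot,
                          n_lambda, ts)
        v <- validate_parts(fit, val_parts)
        v$method <- methods[m]   # simulation label, not the penalty form
        v$lambda <- if (is.null(fit$lambda)) NA_real_ else fit$lambda
        v$shrinkage <- if (is.null(fit$shrinkage_factor)) NA_real_
                       else fit$shrinkage_factor
        v$converged <- fit$converged
        v
      }, error = function(e) {
        tibble(method = methods[m], cs = NA_real_, citl = NA_real_,
               c_stat = NA_real_, brier = NA_real_, rmspe = NA_real_,
               lambda = NA_real_, shrinkage = NA_real_, converged = FALSE)
      })
      row$replicate <- i
      row$n <- n
      rows[[ri]] <- row
    }
  }
  metrics <- bind_rows(rows) |>
    select("replicate", "method", "n", "cs", "citl", "c_stat", "brier",
           "rmspe", "lambda", "shrinkage", "converged")
  out <- structure(
    list(metrics = metrics, scenario = scn,
         config = list(n = n, methods = methods, nsim = nsim, nval = nval,
                       k_folds = k_folds, B = B, repeats = repeats,
                       n_boot = n_boot, n_lambda = n_lambda, seed = seed)),
    class = "sim_result")
  if (!is.null(output_dir)) write_sim_result(out, output_dir)
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d replicates, n = %d, nval = %d\n",
              x$config$nsim, x$config$n, x$config$nval))
  cat("  methods:", paste(x$config$methods, collapse = ", "), "\n")
  print(summary(x))
  invisible(x)
}

#' Summarise a simulation run
#'
#' Per method: number of usable replicates, medians of the validation
#' metrics, the root mean square distance of the log calibration slope
#' from 1 (degenerate replicates excluded and counted in
#' `n_degenerate`), the probability of a well-calibrated model
#' (slope in `[0.9, 1.1]`; degenerate replicates count as not well
#' calibrated), and paired head-to-head win proportions against a
#' reference method: `p_better_cal` (smaller `|log CS|`),
#' `p_better_c` (larger C-statistic), `p_better_rmspe` (smaller RMSPE).
#'
#' @param object a `sim_result`.
#' @param reference method name for head-to-head columns (default
#'   `"mle"` when present).
#' @param ... unused.
#' @return a tibble, one row per method.
#' @export
summary.sim_result <- function(object, reference = "mle", ...) {
  summarise_replicates(object$metrics, reference = reference)
}

#' @rdname summary.sim_result
#' @param metrics a per-replicate metrics tibble with at least columns
#'   `replicate`, `method`, `cs`, `c_stat`, `rmspe`.
#' @export
summarise_replicates <- function(metrics, reference = "mle") {
  base <- metrics |>
    group_by(.data$method) |>
    summarise(
      n_rep = sum(!is.na(.data$cs) | !is.na(.data$c_stat)),
      n_degenerate = sum(is.na(.data$cs) | .data$cs <= 0),
      median_cs = median(.data$cs, na.rm = TRUE),
      median_c = median(.data$c_stat, na.rm = TRUE),
      median_brier = median(.data$brier, na.rm = TRUE),
      median_rmspe = median(.data$rmspe, na.rm = TRUE),
      rmsd_log_cs = {
        ok <- !is.na(.data$cs) & .data$cs > 0
        if (any(ok)) rmsd_log_cs(.data$cs[ok]) else NA_real_
      },
      p_well_cal = p_well_cal(.data$cs),
      .groups = "drop")
  if (!reference %in% metrics$method ||
      all(metrics$method == reference)) {
    return(base)
  }
  ref <- metrics |>
    filter(.data$method == reference) |>
    arrange(.data$replicate)
  h2h <- metrics |>
    filter(.data$method != reference) |>
    group_by(.data$method) |>
    summarise(
      p_better_cal = {
        ord <- order(.data$replicate)
        head_to_head(abs(log(.data$cs[ord])), abs(log(ref$cs)), "less")
      },
      p_better_c = {
        ord <- order(.data$replicate)
        head_to_head(.data$c_stat[ord], ref$c_stat, "greater")
      },
      p_better_rmspe = {
        ord <- order(.data$replicate)
        head_to_head(.data$rmspe[ord], ref$rmspe, "less")
      },
      .groups = "drop")
  left_join(base, h2h, by = "method")
}

# per-replicate and summary CSVs; numbers written at 10 significant
# digits so reruns with the same master seed reproduce files exactly
write_sim_result <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(d) {
    d |> mutate(dplyr::across(dplyr::where(is.numeric),
                              ~ signif(.x, 10)))
  }
  readr::write_csv(fmt(sim$metrics), file.path(dir, "replicates.csv"))
  readr::write_csv(fmt(summary(sim)), file.path(dir, "summary.csv"))
  lam <- sim$metrics |>
    filter(!is.na(.data$lambda)) |>
    select("replicate", "method", "lambda")
  if (nrow(lam)) {
    readr::write_csv(fmt(lam), file.path(dir, "selected_lambda.csv"))
  }
  cfg <- c(sim$config, list(scenario = unclass(sim$scenario)))
  yaml::write_yaml(cfg, file.path(dir, "run_config.yml"))
  invisible(sim)
}

#' Boxplots of validation metrics by method
#'
#' @param object a `sim_result`.
#' @param metric one of `"cs"`, `"c_stat"`, `"brier"`, `"rmspe"`.
#' @param ... unused.
#' @return a ggplot. For the calibration slope, the well-calibration
#'   band 0.9-1.1 is marked.
#' @export
autoplot.sim_result <- function(object,
                                metric = c("cs", "c_stat", "brier",
                                           "rmspe"), ...) {
  metric <- match.arg(metric)
  d <- object$metrics
  pl <- ggplot(d, aes(x = .data$method, y = .data[[metric]])) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = NULL, y = metric) +
    theme_minimal()
  if (metric == "cs") {
    pl <- pl +
      geom_hline(yintercept = c(0.9, 1, 1.1), linetype = c(3, 2, 3)) +
      labs(y = "calibration slope")
  }
  pl
}

#' Find the sample size giving a target expected calibration slope
#'
#' Simulation-based search for the smallest development sample size at
#' which the median validation calibration slope of the MLE reaches
#' `target_cs` (the usual criterion targets an expected shrinkage of
#' 0.9). Uses common random numbers: each replicate draws one
#' development dataset at the bracket's upper end and the candidate
#' sizes reuse its first `n` rows, so the median-slope curve is smooth
#' in `n` and bisection (step-rounded to `step`) is stable.
#'
#' @param scn a calibrated [scenario()].
#' @param target_cs target median calibration slope in (0, 1).
#' @param nsim replicates per candidate size.
#' @param nval validation rows per replicate.
#' @param n_range search bracket.
#' @param step granularity of the returned size.
#' @param seed master seed.
#' @return the recommended sample size (integer); the evaluated
#'   candidates are in `attr(, "search")`.
#' @export
find_recommended_n <- function(scn, target_cs = 0.9, nsim = 300,
                               nval = 10000, n_range = c(200, 3000),
                               step = 10, seed = 1L) {
  stopifnot(inherits(scn, "scenario"), target_cs > 0, target_cs < 1)
  n_lo <- ceiling(n_range[1] / step) * step
  n_hi <- floor(n_range[2] / step) * step
  dev_seeds <- derive_seeds(seed, nsim, stream = 21L)
  val_seeds <- derive_seeds(seed, nsim, stream = 22L)
  hist <- list()
  median_cs_at <- function(n) {
    cs <- rep(NA_real_, nsim)
    for (i in seq_len(nsim)) {
      dev <- generate_dataset(scn, n_hi, dev_seeds[i])[seq_len(n), ]
      val <- generate_dataset(scn, nval, val_seeds[i])
      fit <- fit_mle(dev)
      if (!fit$converged) next
      cs[i] <- calibration_slope(val$y, predict(fit, val, type = "link"))
    }
    m <- median(cs, na.rm = TRUE)
    hist[[length(hist) + 1L]] <<- tibble(n = n, median_cs = m)
    m
  }
  f_lo <- median_cs_at(n_lo)
  f_hi <- median_cs_at(n_hi)
  if (f_lo >= target_cs || f_hi < target_cs) {
    abort(sprintf(
      "target %.3f not bracketed: median CS is %.3f at n=%d and %.3f at n=%d.",
      target_cs, f_lo, n_lo, f_hi, n_hi))
  }
  lo <- n_lo
  hi <- n_hi
  while (hi - lo > step) {
    mid <- round((lo + hi) / 2 / step) * step
    if (mid <= lo) mid <- lo + step
    if (mid >= hi) mid <- hi - step
    if (median_cs_at(mid) >= target_cs) hi <- mid else lo <- mid
  }
  structure(as.integer(hi), search = bind_rows(hist))
}

#' Sensitivity of standard tuning to the number of folds
#'
#' Runs standard cross-validation tuning at each fold count on shared
#' replicates (identical development/validation draws and tuning
#' seeds across fold counts, so comparisons are paired) and reports
#' the selected tuning parameter and the validation calibration slope.
#'
#' @param scn a calibrated [scenario()].
#' @param n development sample size; `fold_list` may include `n` for
#'   leave-one-out.
#' @param fold_list fold counts to compare.
#' @param forms penalty forms to tune.
#' @param nsim replicates.
#' @param nval validation rows.
#' @param n_lambda grid length.
#' @param seed master seed.
#' @return tibble with columns `replicate`, `form`, `k_folds`,
#'   `lambda`, `cs`.
#' @export
folds_sensitivity <- function(scn, n, fold_list = c(5, 10, 20),
                              forms = c("ridge", "lasso"), nsim = 100,
                              nval = 10000, n_lambda = 100, seed = 1L) {
  stopifnot(all(fold_list >= 2), all(fold_list <= n))
  dev_seeds <- derive_seeds(seed, nsim, stream = 31L)
  val_seeds <- derive_seeds(seed, nsim, stream = 32L)
  tune_seeds <- derive_seeds(seed, nsim, stream = 33L)
  out <- list()
  for (i in seq_len(nsim)) {
    dev <- generate_dataset(scn, n, dev_seeds[i])
    val <- generate_dataset(scn, nval, val_seeds[i])
    for (form in forms) {
      grid <- lambda_grid(dev, form, n_lambda)
      for (k in fold_list) {
        row <- tryCatch({
          tr <- tune_standard(dev, form, k = k, seed = tune_seeds[i],
                              grid = grid)
          fit <- fit_tuned(dev, tr)
          cs <- calibration_slope(val$y, predict(fit, val, "link"))
          tibble(replicate = i, form = form, k_folds = k,
                 lambda = tr$selected_lambda, cs = cs)
        }, error = function(e) {
          tibble(replicate = i, form = form, k_folds = k,
                 lambda = NA_real_, cs = NA_real_)
        })
        out[[length(out) + 1L]] <- row
      }
    }
  }
  bind_rows(out)
}
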