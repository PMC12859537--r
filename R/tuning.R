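#' Pseudo-dataset size for modified tuning
#'
#' Size of the bootstrap pseudo-dataset, `round(n * k / (k - 1))`,
#' chosen so that after a k-fold split each cross-validation training
#' fold has the size of the original dataset.
#'
#' @param n original development sample size.
#' @param k number of cross-validation folds.
#' @examples
#' pseudo_size(900, 10)  # 1000
#' @export
pseudo_size <- function(n, k) {
  stopifnot(k >= 2)
  as.integer(round(n * k / (k - 1)))
}

# random fold assignment, redrawn (up to max_retry) if any cv-training
# set would contain a single outcome class
make_folds <- function(y, k, max_retry = 10) {
  n <- length(y)
  stopifnot(k >= 2, k <= n)
  for (r in seq_len(max_retry)) {
    foldid <- sample(rep(seq_len(k), length.out = n))
    ok <- TRUE
    for (f in seq_len(k)) {
      if (length(unique(y[foldid != f])) < 2) { ok <- FALSE; break }
    }
    if (ok) return(foldid)
  }
  abort("could not build folds with both outcome classes in every cv-training set.")
}

#' Cross-validated deviance over a tuning-parameter grid
#'
#' Randomly splits the data into `k` parts; for every fold, fits the
#' penalized model at each grid value on the other `k - 1` parts and
#' accumulates the binomial deviance
#' `-2 * sum(y log p + (1 - y) log(1 - p))` over the held-out
#' observations (predictions clipped away from 0/1). Returns the total
#' deviance per grid value divided by `n`. `k = n` gives leave-one-out
#' cross-validation.
#'
#' @param data development data frame (`y` + covariates).
#' @param form `"ridge"` or `"lasso"`.
#' @param grid descending lambda sequence (see [lambda_grid()]).
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed for the fold split (ignored when `foldid`
#'   is supplied).
#' @param foldid optional integer vector in `1..k` fixing the split.
#' @param tol,maxit solver control.
#' @param dtol path-mode early-stop threshold on the Newton/outer step
#'   size; CV curves tolerate a looser fit than final models, so the
#'   default trades sub-grid-step accuracy for speed. Set to 0 for the
#'   strict gradient/KKT contract.
#' @return tibble with columns `lambda` and `cv_deviance`.
#' @export
cv_deviance <- function(data, form = c("ridge", "lasso"), grid, k = 10,
                        seed = 1L, foldid = NULL, tol = 1e-6,
                        dtol = 0.02, maxit = 10000) {
  form <- match.arg(form)
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  n <- length(parts$y)
  if (is.null(foldid)) {
    foldid <- withr::with_seed(as.integer(seed), make_folds(parts$y, k))
  }
  dev <- cpp_cv_deviance(parts$X, parts$y, as.integer(foldid), grid,
                         alpha = if (form == "lasso") 1 else 0,
                         tol = tol, dtol = dtol, maxit = maxit)
  tibble(lambda = grid, cv_deviance = as.numeric(dev) / n)
}

# argmin with ties broken toward the larger lambda (grid is descending,
# so the first index among minimizers)
select_lambda_index <- function(dev) {
  which(dev <= min(dev))[1]
}

new_tune_result <- function(selected_index, grid, mean_deviance, method,
                            form, k_folds = NULL, B = NULL, repeats = NULL,
                            seed = NULL, n_failed = 0L) {
  structure(
    list(selected_lambda = grid[selected_index],
         selected_index = selected_index,
         grid = grid, mean_deviance = mean_deviance, method = method,
         form = form, k_folds = k_folds, B = B, repeats = repeats,
         seed = seed, n_failed = n_failed),
    class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> %s tuning for %s\n", x$method, x$form))
  cat(sprintf("  selected lambda = %.6g (grid point %d of %d)\n",
              x$selected_lambda, x$selected_index, length(x$grid)))
  if (!is.null(x$k_folds)) cat("  k =", x$k_folds, "")
  if (!is.null(x$B)) cat(" B =", x$B, "")
  cat("\n")
  if (x$n_failed > 0) cat("  dropped iterations:", x$n_failed, "\n")
  invisible(x)
}

#' @export
tidy.tune_result <- function(x, ...) {
  tibble(lambda = x$grid, mean_deviance = x$mean_deviance,
         selected = seq_along(x$grid) == x$selected_index)
}

#' @export
glance.tune_result <- function(x, ...) {
  tibble(method = x$method, form = x$form,
         selected_lambda = x$selected_lambda,
         k_folds = if (is.null(x$k_folds)) NA_integer_ else x$k_folds,
         B = if (is.null(x$B)) NA_integer_ else x$B,
         n_failed = x$n_failed)
}

#' Plot a cross-validated deviance curve
#'
#' @param object a `tune_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tune_result <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$lambda, y = .data$mean_deviance)) +
    geom_line() +
    geom_vline(xintercept = object$selected_lambda, linetype = 2) +
    scale_x_log10() +
    labs(x = expression(lambda), y = "cross-validated deviance / n",
         title = sprintf("%s tuning (%s)", object$method, object$form)) +
    theme_minimal()
}

#' Standard k-fold cross-validation tuning
#'
#' Selects the tuning parameter minimizing the cross-validated deviance
#' (ties broken toward the larger lambda, i.e., more shrinkage). With
#' `repeats > 1` the median of the per-repeat minimizers is taken,
#' which damps the dependence on a single random split.
#'
#' @inheritParams cv_deviance
#' @param repeats number of independent cross-validation repetitions.
#' @param grid optional lambda grid; computed from `data` by default.
#' @param n_lambda,lambda_min_ratio grid construction, see
#'   [lambda_grid()].
#' @return a `tune_result`.
#' @export
tune_standard <- function(data, form = c("ridge", "lasso"), k = 10,
                          seed = 1L, repeats = 1, grid = NULL,
                          n_lambda = 100, lambda_min_ratio = 1e-4,
                          tol = 1e-6, dtol = 0.02, maxit = 10000) {
  form <- match.arg(form)
  if (is.null(grid)) {
    grid <- lambda_grid(data, form, n_lambda, lambda_min_ratio)
  }
  seeds <- derive_seeds(seed, repeats, stream = 1L)
  curves <- matrix(NA_real_, length(grid), repeats)
  idx <- integer(repeats)
  for (r in seq_len(repeats)) {
    cvr <- cv_deviance(data, form, grid, k = k, seed = seeds[r],
                       tol = tol, dtol = dtol, maxit = maxit)
    curves[, r] <- cvr$cv_deviance
    idx[r] <- select_lambda_index(cvr$cv_deviance)
  }
  # median index, half-integers rounded down = toward the larger lambda
  sel <- as.integer(floor(median(idx)))
  new_tune_result(sel, grid, rowMeans(curves), "standard", form,
                  k_folds = k, repeats = repeats, seed = seed)
}

#' Modified cross-validation tuning on inflated pseudo-datasets
#'
#' For each of `B` iterations, draws with replacement a pseudo-dataset
#' of [pseudo_size()] rows from the development data — large enough
#' that each k-fold cross-validation training fold has the size of the
#' original dataset — and computes the cross-validated deviance curve
#' on a common grid. The selected lambda minimizes the pointwise
#' average of the `B` curves. Fit the final model on the *original*
#' data at the selected lambda (see [fit_tuned()]).
#'
#' @inheritParams tune_standard
#' @param B number of pseudo-dataset iterations.
#' @return a `tune_result`.
#' @export
tune_modified <- function(data, form = c("ridge", "lasso"), k = 10,
                          B = 100, seed = 1L, grid = NULL,
                          n_lambda = 100, lambda_min_ratio = 1e-4,
                          tol = 1e-6, dtol = 0.02, maxit = 10000) {
  form <- match.arg(form)
  stopifnot(B >= 1, k >= 2)
  if (is.null(grid)) {
    grid <- lambda_grid(data, form, n_lambda, lambda_min_ratio)
  }
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  n <- length(parts$y)
  n_ps <- pseudo_size(n, k)
  seeds <- derive_seeds(seed, B, stream = 2L)
  idx <- matrix(NA_integer_, n_ps, B)
  folds <- matrix(NA_integer_, n_ps, B)
  ok <- logical(B)
  for (b in seq_len(B)) {
    res <- withr::with_seed(seeds[b], {
      rows <- sample.int(n, n_ps, replace = TRUE)
      fid <- tryCatch(make_folds(parts$y[rows], k), error = function(e) NULL)
      list(rows = rows, fid = fid)
    })
    if (!is.null(res$fid)) {
      idx[, b] <- res$rows
      folds[, b] <- res$fid
      ok[b] <- TRUE
    }
  }
  if (!any(ok)) abort("all pseudo-dataset iterations failed.")
  dev <- cpp_modified_deviance(parts$X, parts$y,
                               idx[, ok, drop = FALSE] - 1L,
                               folds[, ok, drop = FALSE], grid,
                               alpha = if (form == "lasso") 1 else 0,
                               tol = tol, dtol = dtol, maxit = maxit)
  avg <- rowMeans(dev) / n_ps
  new_tune_result(select_lambda_index(avg), grid, avg, "modified", form,
                  k_folds = k, B = B, seed = seed,
                  n_failed = sum(!ok))
}

#' Bootstrap tuning
#'
#' For each of `B` bootstrap samples (size `n`, with replacement), fits
#' the penalized model at every grid value and evaluates the deviance
#' on the *original* dataset; the selected lambda minimizes the average
#' of the `B` deviance curves.
#'
#' @inheritParams tune_modified
#' @return a `tune_result`.
#' @export
tune_bootstrap <- function(data, form = c("ridge", "lasso"), B = 100,
                           seed = 1L, grid = NULL, n_lambda = 100,
                           lambda_min_ratio = 1e-4, tol = 1e-6,
                           dtol = 0.02, maxit = 10000) {
  form <- match.arg(form)
  stopifnot(B >= 1)
  if (is.null(grid)) {
    grid <- lambda_grid(data, form, n_lambda, lambda_min_ratio)
  }
  parts <- dataset_parts(data)
  check_two_classes(parts$y)
  n <- length(parts$y)
  idx <- withr::with_seed(derive_seeds(seed, 1, stream = 3L),
                          matrix(sample.int(n, n * B, replace = TRUE),
                                 nrow = n))
  keep <- vapply(seq_len(B),
                 function(b) length(unique(parts$y[idx[, b]])) == 2,
                 logical(1))
  if (!any(keep)) abort("all bootstrap samples were single-class.")
  dev <- cpp_boot_deviance(parts$X, parts$y, idx[, keep, drop = FALSE] - 1L,
                           grid, alpha = if (form == "lasso") 1 else 0,
                           tol = tol, dtol = dtol, maxit = maxit)
  avg <- rowMeans(dev) / n
  new_tune_result(select_lambda_index(avg), grid, avg, "bootstrap", form,
                  B = B, seed = seed, n_failed = sum(!keep))
}

#' Fit the final penalized model at a tuned lambda
#'
#' Convenience wrapper: fits on the full development data at the lambda
#' chosen by a tuning method (the final step of every tuning
#' algorithm).
#'
#' @param data development data frame.
#' @param tuning a `tune_result`.
#' @param ... passed to [fit_penalized()].
#' @return a `risk_fit` with the tuning method recorded.
#' @export
fit_tuned <- function(data, tuning, ...) {
  stopifnot(inherits(tuning, "tune_result"))
  fit <- fit_penalized(data, tuning$form, tuning$selected_lambda, ...)
  fit$tuning <- tuning$method
  fit
}
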