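test_that("logistic MLE matches the closed-form 2x2 solution", {
  d <- table_data(20, 10, 10, 20)
  fit <- fit_mle(d)
  expect_equal(unname(fit$coefs["x1"]), log(20 * 20 / (10 * 10)),
               tolerance = 1e-6)
  expect_equal(fit$intercept, log(10 / 20), tolerance = 1e-6)
  # agreement with glm on continuous data
  d2 <- toy_data(300, 3, seed = 4)
  g <- glm(y ~ x1 + x2 + x3, binomial, data = d2)
  expect_equal(unname(coef(fit_mle(d2))), unname(coef(g)),
               tolerance = 1e-8)
})

test_that("null data give near-zero slopes; separation is flagged", {
  d <- withr::with_seed(9, data.frame(y = rbinom(20000, 1, 0.5),
                                      x1 = rnorm(20000),
                                      x2 = rnorm(20000)))
  fit <- fit_mle(d)
  expect_lt(max(abs(fit$coefs)), 0.05)

  fs <- fit_mle(separated_data())
  expect_false(fs$converged)
  expect_true(fs$separated)
})

test_that("MLE recovers the data-generating coefficients at large n", {
  d <- generate_dataset(main_scn, 100000, seed = 13)
  fit <- fit_mle(d)
  truth <- main_scn$k * main_scn$base_coefs
  # logistic SEs at this n and prevalence are around 0.007
  expect_lt(max(abs(fit$coefs - truth)), 0.025)
})

test_that("lambda = 0 reproduces the MLE for both penalty forms", {
  d <- generate_dataset(main_scn, 400, seed = 17)
  mle <- coef(fit_mle(d))
  expect_equal(coef(fit_penalized(d, "ridge", 0)), mle, tolerance = 1e-6)
  expect_equal(coef(fit_penalized(d, "lasso", 0)), mle, tolerance = 1e-6)
})

test_that("extreme ridge penalty shrinks to the null model", {
  d <- generate_dataset(main_scn, 400, seed = 18)
  grid <- lambda_grid(d, "ridge")
  fit <- fit_penalized(d, "ridge", grid[1] * 100)
  expect_lt(max(abs(fit$coefs)), 1e-4)
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-4)
})

test_that("lasso is exactly zero at and above lambda_max", {
  d <- generate_dataset(main_scn, 300, seed = 19)
  grid <- lambda_grid(d, "lasso")
  fit <- fit_penalized(d, "lasso", grid[1])
  expect_identical(sum(fit$coefs == 0), 12L)
  fit2 <- fit_penalized(d, "lasso", grid[1] * 2)
  expect_identical(sum(fit2$coefs == 0), 12L)
})

test_that("lambda grids are log-equispaced with the documented anchors", {
  d <- toy_data(200, 4, seed = 21, beta = c(1, -0.5, 0.3, 0))
  g <- lambda_grid(d, "lasso", n_lambda = 100, lambda_min_ratio = 1e-4)
  expect_length(g, 100)
  steps <- diff(log(g))
  expect_lt(diff(range(steps)), 1e-12)
  expect_equal(g[100] / g[1], 1e-4, tolerance = 1e-10)

  # lasso anchor equals the max absolute standardized null-model score
  X <- as.matrix(d[paste0("x", 1:4)])
  Xs <- scale(X, scale = sqrt(colMeans(scale(X, scale = FALSE)^2)))
  by_hand <- max(abs(crossprod(Xs, d$y - mean(d$y)))) / nrow(d)
  expect_equal(g[1], by_hand, tolerance = 1e-7)
  # ridge anchor is the lasso anchor times the documented constant
  gr <- lambda_grid(d, "ridge")
  expect_equal(gr[1], by_hand * 1000, tolerance = 1e-7)

  expect_error(lambda_grid(data.frame(y = c(0, 1), x1 = c(1, 1)), "lasso"),
               "constant")
})

test_that("solver agrees with glmnet along a path (both forms)", {
  library(glmnet)
  d <- generate_dataset(main_scn, 500, seed = 23)
  X <- as.matrix(d[paste0("x", 1:12)])
  for (form in c("lasso", "ridge")) {
    a <- if (form == "lasso") 1 else 0
    grid <- lambda_grid(d, form, n_lambda = 25, lambda_min_ratio = 1e-3)
    ref <- glmnet(X, d$y, family = "binomial", alpha = a, lambda = grid,
                  thresh = 1e-12)
    mine <- modtune:::cpp_penlogit_path(X, d$y, grid, a, 1e-9, 0, 10000)
    expect_lt(max(abs(mine$coef - as.matrix(rbind(ref$a0, ref$beta)))),
              1e-5)
  }
  # glmnet's own computed lambda_max agrees with ours
  ref <- glmnet(X, d$y, family = "binomial", alpha = 1)
  expect_equal(ref$lambda[1], modtune:::lambda_max(X, d$y),
               tolerance = 1e-8)
})

test_that("penalized objective beats brute-force probes on tiny problems", {
  for (seed in 1:4) {
    d <- toy_data(25, 2, seed = seed, beta = c(1, -0.8))
    lam <- 0.08
    for (form in c("ridge", "lasso")) {
      fit <- fit_penalized(d, form, lam)
      obj <- pen_objective(d, fit$intercept, fit$coefs, lam, form)
      probes <- withr::with_seed(seed + 100,
                                 matrix(runif(3 * 10000, -3, 3), ncol = 3))
      pobj <- apply(probes, 1, function(b)
        pen_objective(d, b[1], b[2:3], lam, form))
      expect_gte(obj, max(pobj) - 1e-8)
      # and local perturbations of the solution itself
      pert <- withr::with_seed(seed + 200,
                               matrix(rnorm(3 * 500, 0, 1e-3), ncol = 3))
      lobj <- apply(pert, 1, function(e)
        pen_objective(d, fit$intercept + e[1], fit$coefs + e[2:3],
                      lam, form))
      expect_gte(obj, max(lobj) - 1e-9)
    }
  }
})

test_that("ridge objective matches a smooth-optimizer oracle", {
  d <- toy_data(20, 2, seed = 5, beta = c(1.2, -1))
  lam <- 0.05
  fit <- fit_penalized(d, "ridge", lam)
  o <- optim(c(0, 0, 0), function(b)
    -pen_objective(d, b[1], b[2:3], lam, "ridge"),
    method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(pen_objective(d, fit$intercept, fit$coefs, lam, "ridge"),
               -o$value, tolerance = 1e-4)
})

test_that("ridge slope norm shrinks monotonically in lambda", {
  d <- generate_dataset(main_scn, 400, seed = 27)
  X <- as.matrix(d[paste0("x", 1:12)])
  grid <- lambda_grid(d, "ridge", n_lambda = 40)
  path <- modtune:::cpp_penlogit_path(X, d$y, grid, 0, 1e-8, 0, 10000)$coef
  norms <- sqrt(colSums(path[-1, ]^2))
  # grid is descending, so norms must be non-decreasing along it
  expect_true(all(diff(norms) > -1e-8))
})

test_that("Firth's penalty equals the half-cell correction on 2x2 data", {
  d <- table_data(5, 3, 2, 8)
  fit <- fit_firth(d)
  closed <- log((5.5 * 8.5) / (3.5 * 2.5))
  expect_equal(unname(fit$coefs["x1"]), closed, tolerance = 1e-4)
  # brute-force maximization of l(beta) + 0.5 log det I(beta)
  X <- cbind(1, d$x1)
  pen <- function(b) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    sum(d$y * eta - log1p(exp(eta))) +
      0.5 * determinant(crossprod(X * sqrt(p * (1 - p))))$modulus
  }
  o <- optim(c(0, 0), function(b) -pen(b), method = "BFGS",
             control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefs["x1"]), o$par[2], tolerance = 1e-4)
})

test_that("Firth stays finite under separation and corrects the intercept", {
  fs <- fit_firth(separated_data())
  expect_true(all(is.finite(coef(fs))))
  expect_lt(max(abs(coef(fs))), 10)

  d <- generate_dataset(main_scn, 300, seed = 29)
  fit <- fit_firth(d)
  expect_equal(mean(predict(fit, d)), mean(d$y), tolerance = 1e-8)
})

test_that("Firth approaches the MLE as n grows", {
  d <- generate_dataset(main_scn, 50000, seed = 30)
  ff <- fit_firth(d)
  fm <- fit_mle(d)
  expect_lt(max(abs(ff$coefs - fm$coefs)), 0.01)
})

test_that("bootstrap uniform shrinkage averages resample calibration slopes", {
  d <- generate_dataset(main_scn, 150, seed = 41)
  n_boot <- 40
  fit <- fit_boot_unif(d, n_boot = n_boot, seed = 77)

  # independent oracle: same resamples via the documented seed scheme,
  # glm fits, calibration slope on the original data via glm
  X <- as.matrix(d[paste0("x", 1:12)])
  idx <- withr::with_seed(77L, matrix(sample.int(150, 150 * n_boot,
                                                 replace = TRUE), nrow = 150))
  slopes <- vapply(seq_len(n_boot), function(b) {
    db <- d[idx[, b], ]
    g <- suppressWarnings(glm(y ~ . - true_prob, binomial, data = db))
    lp <- coef(g)[1] + drop(X %*% coef(g)[-1])
    unname(coef(glm(d$y ~ lp, binomial))[2])
  }, numeric(1))
  expect_equal(fit$shrinkage_factor, mean(slopes), tolerance = 1e-6)

  # slopes scaled uniformly; intercept restores the event rate
  base <- fit_mle(d)
  expect_equal(fit$coefs, fit$shrinkage_factor * base$coefs,
               tolerance = 1e-10)
  expect_equal(mean(predict(fit, d)), mean(d$y), tolerance = 1e-8)
})

test_that("all fitted models predict inside (0, 1)", {
  d <- generate_dataset(main_scn, 250, seed = 43)
  nd <- generate_dataset(main_scn, 500, seed = 44)
  fits <- list(fit_mle(d), fit_firth(d),
               fit_boot_unif(d, 30, seed = 1),
               fit_penalized(d, "ridge", 0.05),
               fit_penalized(d, "lasso", 0.02))
  for (f in fits) {
    p <- predict(f, nd)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("risk fits round-trip through JSON and expose tidy summaries", {
  d <- generate_dataset(main_scn, 200, seed = 45)
  fit <- fit_penalized(d, "lasso", 0.03)
  f <- withr::local_tempfile(fileext = ".json")
  write_risk_fit(fit, f)
  fit2 <- read_risk_fit(f)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-12)
  expect_equal(fit2$method, "lasso")
  expect_equal(fit2$lambda, fit$lambda)

  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 13)
  gl <- glance(fit)
  expect_equal(gl$method, "lasso")
  expect_equal(gl$n_zero, sum(fit$coefs == 0))
})
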