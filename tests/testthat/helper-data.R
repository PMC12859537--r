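# Small builders and independent oracles shared across tests.

# 2x2 table data: a = (x=1, y=1), b = (x=1, y=0), c = (x=0, y=1),
# d = (x=0, y=0)
table_data <- function(a, b, c, d) {
  data.frame(
    y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    x1 = c(rep(1, a + b), rep(0, c + d)))
}

# quasi-separated toy data: x1 separates y perfectly
separated_data <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
    data.frame(y = rep(c(0, 1), each = n / 2), x1 = x)
  })
}

# random small logistic dataset
toy_data <- function(n = 40, p = 2, seed = 1, beta = NULL) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    if (is.null(beta)) beta <- rep(0.5, p)
    y <- rbinom(n, 1, plogis(X %*% beta))
    d <- data.frame(y = y, X)
    names(d) <- c("y", paste0("x", seq_len(p)))
    d
  })
}

# penalized objective under the package's scaling convention:
# (1/n) loglik - lambda * s(std-scale slopes); intercept unpenalized,
# covariates standardized with denominator-n SD
pen_objective <- function(data, intercept, coefs, lambda, form) {
  y <- data$y
  X <- as.matrix(data[setdiff(names(data), c("y", "true_prob"))])
  eta <- intercept + drop(X %*% coefs)
  ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) / nrow(X)
  s <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  bs <- coefs * s   # slopes on the standardized scale
  pen <- if (form == "ridge") sum(bs^2) / 2 else sum(abs(bs))
  ll - lambda * pen
}

# all-pairs C-statistic, the O(n^2) definition
c_stat_pairs <- function(y, p) {
  ev <- p[y == 1]
  ne <- p[y == 0]
  tot <- 0
  for (e in ev) tot <- tot + sum(e > ne) + 0.5 * sum(e == ne)
  tot / (length(ev) * length(ne))
}

main_scn <- scenario()
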