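// Penalized logistic regression path solver.
//
// Objective (glmnet convention): minimise over (b0, b)
//   -(1/N) * sum_i c_i [ y_i * eta_i - log(1 + exp(eta_i)) ] + lambda * P(b)
// with P(b) = ||b||_1 for lasso and ||b||_2^2 / 2 for ridge, the intercept
// b0 unpenalised, and covariates standardised internally to (weighted)
// mean 0 and SD 1 (denominator N = sum of weights). Coefficients are
// returned on the original scale. The case weights c_i are observation
// counts: a bootstrap resample or pseudo-dataset is the original rows
// with multinomial counts, so fitting its unique rows with weights is
// exactly the duplicated-row fit at ~2/3 of the row count.
//
// Ridge uses damped Newton steps; lasso uses IRLS with coordinate-wise
// soft-thresholding (exact zeros) and active-set sweeps. Two regimes:
//   dtol = 0 : strict — run to gradient / KKT max-norm < tol
//              (the contract for final model fits);
//   dtol > 0 : path mode for cross-validation curves — stop once the
//              Newton/outer step is below dtol. The gradient used for
//              stopping is always exact; in this mode the weighted
//              Hessian cross-product may be reused across neighbouring
//              grid points (it enters only as a step preconditioner,
//              so reuse affects speed, not the fixed point).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double WMIN = 1e-10;    // floor for IRLS weights
// |eta| cap equivalent to clipping probabilities to [1e-10, 1 - 1e-10]
static const double ETA_CLIP = 23.025850929940457;

static inline double softplus(double x) {
  return (x > 0.0 ? x : 0.0) + std::log1p(std::exp(-std::abs(x)));
}

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// fused pass: probabilities and floored IRLS weights from eta
static inline void mu_w(const vec& eta, vec& pr, vec& w) {
  const uword n = eta.n_elem;
  for (uword i = 0; i < n; ++i) {
    double e = eta(i);
    e = e > 40.0 ? 40.0 : (e < -40.0 ? -40.0 : e);
    double q = 1.0 / (1.0 + std::exp(-e));
    pr(i) = q;
    double ww = q * (1.0 - q);
    w(i) = ww < WMIN ? WMIN : ww;
  }
}

// Per-path solver state: standardized design, counts, current iterate,
// and (for ridge path mode) the cached unpenalized Hessian block.
struct PathWork {
  mat Xs;
  vec y, cwt;       // outcomes and observation counts/weights
  double N;         // total weight
  vec pr, w, eta, b;
  mat Xw;           // weighted-design scratch for lasso sweeps
  double b0;
  mat A;            // cached (1/N) [1 Xs]' C W [1 Xs]
  vec bA;
  double b0A;
  bool Avalid = false;
};

// weighted negative average log-likelihood
static double nll(const PathWork& W, const vec& eta) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    s += W.cwt(i) * (softplus(eta(i)) - W.y(i) * eta(i));
  return s / W.N;
}

static void build_A(PathWork& W) {
  const uword p = W.Xs.n_cols;
  vec we = W.cwt % W.w;
  vec sw = sqrt(we);
  mat Xw = W.Xs.each_col() % sw;
  W.A.set_size(p + 1, p + 1);
  W.A(0, 0) = accu(we) / W.N;
  rowvec xw = (we.t() * W.Xs) / W.N;
  W.A(0, span(1, p)) = xw;
  W.A(span(1, p), 0) = xw.t();
  W.A(span(1, p), span(1, p)) = (Xw.t() * Xw) / W.N;
  W.bA = W.b;
  W.b0A = W.b0;
  W.Avalid = true;
}

static bool solve_ridge(PathWork& W, double lam, double tol, double dtol,
                        int maxit) {
  const uword p = W.Xs.n_cols;
  const bool path_mode = dtol > 0.0;
  vec g(p + 1);
  for (int it = 0; it < maxit; ++it) {
    mu_w(W.eta, W.pr, W.w);
    vec cr = W.cwt % (W.y - W.pr);
    g(0) = -accu(cr) / W.N;
    g.subvec(1, p) = -(W.Xs.t() * cr) / W.N + lam * W.b;
    if (norm(g, "inf") < tol) return true;
    bool stale = !W.Avalid ||
      std::abs(W.b0 - W.b0A) > 0.1 || norm(W.b - W.bA, "inf") > 0.1;
    if (!path_mode || stale) build_A(W);
    mat H = W.A;
    H.submat(1, 1, p, p).diag() += lam;
    vec d = solve(H, -g, solve_opts::likely_sympd);
    double dmax = norm(d, "inf");
    if (dmax > 2.0) {
      // rare: damp large steps by backtracking on the penalised objective
      double f0 = nll(W, W.eta) + 0.5 * lam * dot(W.b, W.b);
      double step = 1.0;
      for (int h = 0; h < 40; ++h) {
        vec bn = W.b + step * d.subvec(1, p);
        vec en = (W.b0 + step * d(0)) + W.Xs * bn;
        double f1 = nll(W, en) + 0.5 * lam * dot(bn, bn);
        if (f1 <= f0 + 1e-12 || h == 39) {
          W.b0 += step * d(0);
          W.b = bn;
          W.eta = en;
          break;
        }
        step *= 0.5;
      }
    } else {
      W.b0 += d(0);
      W.b += d.subvec(1, p);
      W.eta += d(0) + W.Xs * d.subvec(1, p);
    }
    if (path_mode && dmax < dtol) return true;
  }
  mu_w(W.eta, W.pr, W.w);
  vec cr = W.cwt % (W.y - W.pr);
  g(0) = -accu(cr) / W.N;
  g.subvec(1, p) = -(W.Xs.t() * cr) / W.N + lam * W.b;
  return norm(g, "inf") < tol;
}

static bool solve_lasso(PathWork& W, double lam, double tol, double dtol,
                        int maxit) {
  const uword p = W.Xs.n_cols;
  const double itol = dtol > 0.0 ? dtol * 0.3 : std::max(tol, 1e-12) * 1e-2;
  vec xv(p);
  for (int outer = 0; outer < maxit; ++outer) {
    mu_w(W.eta, W.pr, W.w);
    // working residual of z = eta + (y - pr) / w around the current fit
    vec r = (W.y - W.pr) / W.w;
    vec we = W.cwt % W.w;
    W.Xw = W.Xs.each_col() % we;    // weighted design, reused all sweeps
    for (uword j = 0; j < p; ++j)
      xv(j) = dot(W.Xw.col(j), W.Xs.col(j)) / W.N;
    double wsum = accu(we);
    double chg = 0.0;   // max coefficient change this outer iteration
    bool full_sweep = true;
    for (int inner = 0; inner < 10000; ++inner) {
      double dmax = 0.0;
      double db0 = dot(we, r) / wsum;
      if (db0 != 0.0) {
        W.b0 += db0;
        r -= db0;
        dmax = std::max(dmax, std::abs(db0));
      }
      for (uword j = 0; j < p; ++j) {
        if (!full_sweep && W.b(j) == 0.0) continue;   // active-set sweep
        double bj = W.b(j);
        double u = dot(W.Xw.col(j), r) / W.N + xv(j) * bj;
        double bn = soft(u, lam) / xv(j);
        if (bn != bj) {
          r -= (bn - bj) * W.Xs.col(j);
          W.b(j) = bn;
          dmax = std::max(dmax, std::abs(bn - bj));
        }
      }
      chg = std::max(chg, dmax);
      if (dmax < itol) {
        if (full_sweep) break;
        // strict mode: one more full sweep to catch activation violators;
        // path mode skips it — every grid point opens with a full sweep,
        // so a late activation is picked up within one grid step anyway
        if (dtol == 0.0) { full_sweep = true; continue; }
        break;
      }
      full_sweep = false;
    }
    W.eta = W.b0 + W.Xs * W.b;
    if (dtol > 0.0 && chg < dtol) return true;
    if (dtol == 0.0 || chg < dtol * 10) {
      // KKT conditions of the actual objective
      mu_w(W.eta, W.pr, W.w);
      vec res = W.cwt % (W.y - W.pr);
      double kkt = std::abs(accu(res) / W.N);
      for (uword j = 0; j < p; ++j) {
        double gj = -dot(W.Xs.col(j), res) / W.N;
        double v = (W.b(j) == 0.0)
          ? std::max(0.0, std::abs(gj) - lam)
          : std::abs(gj + lam * ((W.b(j) > 0) ? 1.0 : -1.0));
        kkt = std::max(kkt, v);
      }
      if (kkt < tol) return true;
    }
  }
  return false;
}

// fit the whole path on weighted rows; (p+1) x L matrix, original scale
static mat fit_path(const mat& X, const vec& y, const vec& cwt,
                    const vec& lambda, double alpha, double tol,
                    double dtol, int maxit, bool& ok) {
  const uword p = X.n_cols, L = lambda.n_elem;
  PathWork W;
  W.N = accu(cwt);
  rowvec m = (cwt.t() * X) / W.N;
  mat Xc = X.each_row() - m;
  rowvec s = sqrt((cwt.t() * square(Xc)) / W.N);
  s.transform([](double v) { return v < 1e-12 ? 1.0 : v; });
  W.Xs = std::move(Xc);
  W.Xs.each_row() /= s;
  W.y = y;
  W.cwt = cwt;
  double ybar = dot(cwt, y) / W.N;
  W.b0 = std::log(ybar / (1.0 - ybar));
  W.b.zeros(p);
  W.eta.set_size(X.n_rows);
  W.eta.fill(W.b0);
  W.pr.set_size(X.n_rows);
  W.w.set_size(X.n_rows);
  mat out(p + 1, L);
  ok = true;
  for (uword l = 0; l < L; ++l) {
    bool conv = (alpha == 0.0)
      ? solve_ridge(W, lambda(l), tol, dtol, maxit)
      : solve_lasso(W, lambda(l), tol, dtol, maxit);
    if (!conv) ok = false;
    vec bo = W.b / s.t();
    out(0, l) = W.b0 - dot(bo, m.t());
    out(span(1, p), l) = bo;
  }
  return out;
}

// total (count-weighted) binomial deviance of each coefficient column on
// (X, y, cwt); the eta clamp equals clipping p to [1e-10, 1 - 1e-10]
static vec path_deviance(const mat& coef, const mat& X, const vec& y,
                         const vec& cwt) {
  const uword L = coef.n_cols, p = X.n_cols, n = X.n_rows;
  mat Eta = X * coef.rows(1, p);
  Eta.each_row() += coef.row(0);
  vec dev(L);
  for (uword l = 0; l < L; ++l) {
    double s = 0.0;
    for (uword i = 0; i < n; ++i) {
      double e = Eta(i, l);
      e = e > ETA_CLIP ? ETA_CLIP : (e < -ETA_CLIP ? -ETA_CLIP : e);
      s += cwt(i) * (y(i) * e - softplus(e));
    }
    dev(l) = -2.0 * s;
  }
  return dev;
}

// [[Rcpp::export]]
Rcpp::List cpp_penlogit_path(const arma::mat& X, const arma::vec& y,
                             const arma::vec& lambda, double alpha,
                             double tol, double dtol, int maxit) {
  bool ok;
  vec ones(X.n_rows, fill::ones);
  mat coef = fit_path(X, y, ones, lambda, alpha, tol, dtol, maxit, ok);
  return Rcpp::List::create(Rcpp::Named("coef") = coef,
                            Rcpp::Named("converged") = ok);
}

// [[Rcpp::export]]
arma::vec cpp_path_deviance(const arma::mat& coef, const arma::mat& X,
                            const arma::vec& y) {
  vec ones(X.n_rows, fill::ones);
  return path_deviance(coef, X, y, ones);
}

// total held-out deviance per lambda, summed over folds
// [[Rcpp::export]]
arma::vec cpp_cv_deviance(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& foldid, const arma::vec& lambda,
                          double alpha, double tol, double dtol, int maxit) {
  int k = foldid.max();
  vec dev(lambda.n_elem, fill::zeros);
  for (int f = 1; f <= k; ++f) {
    uvec test = find(foldid == f);
    uvec train = find(foldid != f);
    bool ok;
    vec ones_tr(train.n_elem, fill::ones), ones_te(test.n_elem, fill::ones);
    mat coef = fit_path(X.rows(train), y.elem(train), ones_tr, lambda,
                        alpha, tol, dtol, maxit, ok);
    dev += path_deviance(coef, X.rows(test), y.elem(test), ones_te);
  }
  return dev;
}

// modified tuning inner loop: column b of idx (0-based rows into X) is a
// pseudo-dataset, column b of folds its fold assignment; each fold fit
// collapses the drawn rows to unique base rows with counts. Returns the
// L x B matrix of fold-summed held-out deviances.
// [[Rcpp::export]]
arma::mat cpp_modified_deviance(const arma::mat& X, const arma::vec& y,
                                const arma::umat& idx,
                                const arma::imat& folds,
                                const arma::vec& lambda, double alpha,
                                double tol, double dtol, int maxit) {
  const uword B = idx.n_cols, n = X.n_rows, nps = idx.n_rows;
  mat dev(lambda.n_elem, B);
  vec cnt_tr(n), cnt_te(n);
  for (uword bcol = 0; bcol < B; ++bcol) {
    int k = folds.col(bcol).max();
    vec total(lambda.n_elem, fill::zeros);
    for (int f = 1; f <= k; ++f) {
      cnt_tr.zeros();
      cnt_te.zeros();
      for (uword i = 0; i < nps; ++i) {
        uword row = idx(i, bcol);
        if (folds(i, bcol) == f) cnt_te(row) += 1.0;
        else cnt_tr(row) += 1.0;
      }
      uvec rtr = find(cnt_tr > 0);
      uvec rte = find(cnt_te > 0);
      bool ok;
      mat coef = fit_path(X.rows(rtr), y.elem(rtr), cnt_tr.elem(rtr),
                          lambda, alpha, tol, dtol, maxit, ok);
      total += path_deviance(coef, X.rows(rte), y.elem(rte),
                             cnt_te.elem(rte));
    }
    dev.col(bcol) = total;
  }
  return dev;
}

// bootstrap tuning: fit on each column of idx (0-based rows, collapsed
// to counts), score on the full original (X, y); L x B total deviances
// [[Rcpp::export]]
arma::mat cpp_boot_deviance(const arma::mat& X, const arma::vec& y,
                            const arma::umat& idx, const arma::vec& lambda,
                            double alpha, double tol, double dtol, int maxit) {
  const uword B = idx.n_cols, n = X.n_rows;
  mat dev(lambda.n_elem, B);
  vec ones_n(n, fill::ones), cnt(n);
  for (uword bcol = 0; bcol < B; ++bcol) {
    cnt.zeros();
    for (uword i = 0; i < idx.n_rows; ++i) cnt(idx(i, bcol)) += 1.0;
    uvec rows = find(cnt > 0);
    bool ok;
    mat coef = fit_path(X.rows(rows), y.elem(rows), cnt.elem(rows),
                        lambda, alpha, tol, dtol, maxit, ok);
    dev.col(bcol) = path_deviance(coef, X, y, ones_n);
  }
  return dev;
}

// small-p logistic Newton-Raphson MLE with optional offset; X includes
// any intercept column. Convergence: max |score| < tol * n. Mirrors the
// classical IRLS with step-halving on the log-likelihood.
// [[Rcpp::export]]
Rcpp::List cpp_logit_newton(const arma::mat& X, const arma::vec& y,
                            const arma::vec& offset, double tol,
                            int maxit) {
  const uword n = X.n_rows, q = X.n_cols;
  const double dn = (double)n;
  vec beta(q, fill::zeros);
  vec eta = offset;
  vec pr(n), w(n);
  bool converged = false;
  auto loglik = [&](const vec& e) {
    double s = 0.0;
    for (uword i = 0; i < n; ++i) s += y(i) * e(i) - softplus(e(i));
    return s;
  };
  for (int it = 0; it < maxit; ++it) {
    mu_w(eta, pr, w);
    vec g = X.t() * (y - pr);
    if (norm(g, "inf") < tol * dn) { converged = true; break; }
    mat Xw = X.each_col() % sqrt(w);
    mat H = Xw.t() * Xw;
    vec d;
    bool solved = solve(d, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!solved) break;
    // step at rounding level: the quadratic model cannot improve further
    if (norm(d, "inf") < 1e-14 * (1.0 + norm(beta, "inf"))) {
      converged = norm(g, "inf") < std::max(tol, 1e-8) * dn;
      break;
    }
    double f0 = loglik(eta);
    // acceptance slack scaled to the objective magnitude: |loglik| grows
    // with n and its evaluation noise swamps an absolute threshold
    double slack = 1e-10 * (1.0 + std::abs(f0));
    double step = 1.0;
    vec bn, en;
    for (int h = 0; h < 40; ++h) {
      bn = beta + step * d;
      en = offset + X * bn;
      if (loglik(en) >= f0 - slack) break;
      step *= 0.5;
    }
    beta = bn;
    eta = en;
  }
  // separation: the likelihood maximum lies at infinity; Newton either
  // stalls or "converges" onto saturated probabilities at huge betas
  bool separated = norm(beta, "inf") > 15.0;
  return Rcpp::List::create(
    Rcpp::Named("coef") = beta,
    Rcpp::Named("converged") = converged && !separated,
    Rcpp::Named("separated") = separated);
}


// C-statistic via midranks: average rank of events, tied values share
// their midrank — identical to the all-pairs definition with half ties
// [[Rcpp::export]]
double cpp_cstat(const arma::vec& y, const arma::vec& p) {
  const uword n = p.n_elem;
  uvec ord = sort_index(p);
  vec r(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && p(ord(j + 1)) == p(ord(i))) ++j;
    double mid = 0.5 * ((double)(i + 1) + (double)(j + 1));
    for (uword t = i; t <= j; ++t) r(ord(t)) = mid;
    i = j + 1;
  }
  double n1 = 0.0, rsum = 0.0;
  for (uword t = 0; t < n; ++t) {
    if (y(t) == 1.0) { n1 += 1.0; rsum += r(t); }
  }
  double n0 = (double)n - n1;
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}
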