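#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Iteratively reweighted least squares for a Bernoulli GLM with logit link.
// X must already carry the intercept column. An optional ridge penalty
// (applied to every coefficient except the first, assumed intercept) is the
// fallback used by the R wrapper when quasi-separation is detected; the
// log-likelihood is always the unpenalised one evaluated at the returned
// coefficients.
// [[Rcpp::export(name = ".cpp_logit_irls")]]
List cpp_logit_irls(const arma::mat& X, const arma::vec& y,
                    double ridge = 0.0, int max_iter = 50,
                    double tol = 1e-8) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec eta(n, arma::fill::zeros), mu(n), w(n), z(n);
  bool converged = false;
  bool singular = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    mu = 1.0 / (1.0 + arma::exp(-eta));
    w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat H = X.t() * Xw;
    if (ridge > 0.0) {
      for (arma::uword j = 1; j < p; ++j) H(j, j) += ridge;
    }
    arma::vec bn;
    if (!arma::solve(bn, H, Xw.t() * z, arma::solve_opts::no_approx)) {
      singular = true;
      break;
    }
    if (arma::abs(bn - beta).max() < tol) {
      beta = bn;
      converged = true;
      eta = X * beta;
      break;
    }
    beta = bn;
    eta = X * beta;
    // quasi-separation: coefficients diverge without converging; stop early
    // (the caller refits with a ridge penalty)
    if (ridge == 0.0 && p > 1 &&
        arma::abs(beta.subvec(1, p - 1)).max() > 15.0) {
      break;
    }
  }
  mu = 1.0 / (1.0 + arma::exp(-eta));
  // clamp fitted probabilities away from 0/1 for the log-likelihood
  arma::vec muc = arma::clamp(mu, 1e-12, 1.0 - 1e-12);
  double ll = arma::accu(y % arma::log(muc) + (1.0 - y) % arma::log(1.0 - muc));
  return List::create(_["coefficients"] = beta,
                      _["fitted"] = mu,
                      _["loglik"] = ll,
                      _["converged"] = converged,
                      _["singular"] = singular,
                      _["iterations"] = it + 1);
}

// ---- internal helpers for the panel engine --------------------------------

// Plain IRLS on a design that already has its intercept column.
static bool irls(const arma::mat& X, const arma::vec& y, double ridge,
                 int max_iter, double tol, arma::vec& beta, double& loglik,
                 bool& converged) {
  const arma::uword p = X.n_cols;
  beta.zeros(p);
  arma::vec eta(X.n_rows, arma::fill::zeros), mu, w, z;
  converged = false;
  for (int it = 0; it < max_iter; ++it) {
    mu = 1.0 / (1.0 + arma::exp(-eta));
    w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat H = X.t() * Xw;
    if (ridge > 0.0) for (arma::uword j = 1; j < p; ++j) H(j, j) += ridge;
    arma::vec bn;
    if (!arma::solve(bn, H, Xw.t() * z, arma::solve_opts::no_approx))
      return false;
    if (arma::abs(bn - beta).max() < tol) {
      beta = bn;
      converged = true;
      eta = X * beta;
      break;
    }
    beta = bn;
    eta = X * beta;
    if (ridge == 0.0 && p > 1 &&
        arma::abs(beta.subvec(1, p - 1)).max() > 15.0)
      break;
  }
  mu = arma::clamp(1.0 / (1.0 + arma::exp(-(X * beta))), 1e-12, 1.0 - 1e-12);
  loglik = arma::accu(y % arma::log(mu) + (1.0 - y) % arma::log(1.0 - mu));
  return true;
}

// Separation-guarded fit: refit with a small ridge when IRLS fails to
// converge or the slopes diverge / probabilities saturate.
static bool guarded_fit(const arma::mat& X, const arma::vec& y, double ridge,
                        arma::vec& beta, double& loglik, bool& separated) {
  bool converged = false;
  separated = false;
  bool ok = irls(X, y, 0.0, 30, 1e-8, beta, loglik, converged);
  bool extreme = false;
  if (ok) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-(X * beta)));
    extreme = mu.min() < 1e-10 || mu.max() > 1.0 - 1e-10;
    if (X.n_cols > 1 && arma::abs(beta.subvec(1, X.n_cols - 1)).max() > 12.0)
      extreme = true;
  }
  if (!ok || !converged || extreme) {
    separated = true;
    ok = irls(X, y, ridge, 30, 1e-8, beta, loglik, converged);
  }
  return ok;
}

// AUC with ties counted one half.
static double auc_ties(const arma::vec& s, const arma::vec& y) {
  const arma::uword n = s.n_elem;
  arma::uvec ord = arma::stable_sort_index(s);
  arma::vec r(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && s(ord(j + 1)) == s(ord(i))) ++j;
    double avg = (static_cast<double>(i) + static_cast<double>(j)) / 2.0 + 1.0;
    for (arma::uword k = i; k <= j; ++k) r(ord(k)) = avg;
    i = j + 1;
  }
  double n1 = arma::accu(y);
  double n0 = static_cast<double>(n) - n1;
  double s1 = arma::accu(r % y);
  return (s1 - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// Evaluate every candidate panel over a shared stratified fold assignment:
// per panel, the mean and SD of the held-out fold AUCs plus the AIC of the
// full-training refit. Z is the standardised training design; panels are
// 1-based column index vectors.
// [[Rcpp::export(name = ".cpp_panel_cv")]]
NumericMatrix cpp_panel_cv(const arma::mat& Z, const arma::vec& y,
                           const List& panels, const arma::ivec& folds,
                           int n_folds, double ridge = 1e-4) {
  const int np = panels.size();
  NumericMatrix out(np, 3);
  colnames(out) = CharacterVector::create("mean_auc", "sd_auc", "aic");
  std::vector<arma::uvec> tr_idx(n_folds), te_idx(n_folds);
  for (int f = 0; f < n_folds; ++f) {
    tr_idx[f] = arma::find(folds != f + 1);
    te_idx[f] = arma::find(folds == f + 1);
  }
  arma::vec beta;
  double loglik;
  bool separated;
  for (int k = 0; k < np; ++k) {
    arma::uvec cols = as<arma::uvec>(panels[k]) - 1;
    arma::mat Xp(Z.n_rows, cols.n_elem + 1, arma::fill::ones);
    Xp.cols(1, cols.n_elem) = Z.cols(cols);
    arma::vec aucs(n_folds);
    for (int f = 0; f < n_folds; ++f) {
      arma::mat Xtr = Xp.rows(tr_idx[f]);
      arma::vec ytr = y.elem(tr_idx[f]);
      if (!guarded_fit(Xtr, ytr, ridge, beta, loglik, separated)) {
        aucs(f) = NA_REAL;
        continue;
      }
      arma::vec sc = Xp.rows(te_idx[f]) * beta;
      aucs(f) = auc_ties(sc, y.elem(te_idx[f]));
    }
    if (!guarded_fit(Xp, y, ridge, beta, loglik, separated)) {
      out(k, 0) = NA_REAL; out(k, 1) = NA_REAL; out(k, 2) = NA_REAL;
      continue;
    }
    out(k, 0) = arma::mean(aucs);
    out(k, 1) = arma::stddev(aucs);
    out(k, 2) = 2.0 * (cols.n_elem + 1.0) - 2.0 * loglik;
  }
  return out;
}

// Wald standard errors from the observed information at beta (unpenalised).
// [[Rcpp::export(name = ".cpp_logit_se")]]
arma::vec cpp_logit_se(const arma::mat& X, const arma::vec& beta,
                       double ridge = 0.0) {
  arma::vec eta = X * beta;
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec w = mu % (1.0 - mu);
  w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
  arma::mat H = X.t() * (X.each_col() % w);
  if (ridge > 0.0) {
    for (arma::uword j = 1; j < X.n_cols; ++j) H(j, j) += ridge;
  }
  arma::mat Hi;
  if (!arma::inv_sympd(Hi, H)) {
    if (!arma::inv(Hi, H)) {
      return arma::vec(X.n_cols, arma::fill::value(NA_REAL));
    }
  }
  return arma::sqrt(Hi.diag());
}
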