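// Logistic-regression IRLS engine.
//
// The supra-multiplicativity threshold scan refits an (n x p) logistic model
// once per load cut-off per simulated replicate, so the fitter is kept in
// compiled code and the scan warm-starts every alternative fit from the null
// coefficients.  Semantics (convergence rule, separation flag) follow the
// package's documented contract; stats::glm is the cross-check in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct IrlsFit {
  arma::vec beta;
  arma::vec se;
  double loglik;
  bool converged;
  bool separated;
  bool singular;
  int iter;
};

double bernoulli_loglik(const arma::vec &y, const arma::vec &eta) {
  // log L = sum y*eta - log(1 + exp(eta)), computed stably
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double e = eta[i];
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

IrlsFit irls(const arma::mat &X, const arma::vec &y, arma::vec beta,
             int max_iter, double tol) {
  const arma::uword p = X.n_cols;
  IrlsFit out;
  out.beta = beta;
  out.se = arma::vec(p, arma::fill::value(NA_REAL));
  out.converged = false;
  out.separated = false;
  out.singular = false;
  out.iter = 0;

  arma::vec eta = X * beta;
  double ll = bernoulli_loglik(y, eta);
  arma::mat XtWX(p, p);

  for (int it = 1; it <= max_iter; ++it) {
    out.iter = it;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    // working response: z = eta + (y - mu) / w
    arma::vec z = eta + (y - mu) / w;
    arma::vec sw = arma::sqrt(w);
    arma::mat Xs = X.each_col() % sw;      // trans(Xs)*Xs dispatches to syrk
    XtWX = Xs.t() * Xs;
    arma::vec Xtwz = X.t() * (w % z);
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, Xtwz,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) {
      out.singular = true;
      break;
    }
    arma::vec eta_new = X * beta_new;
    double ll_new = bernoulli_loglik(y, eta_new);
    // step-halving if the Newton step overshoots
    int halvings = 0;
    while (ll_new < ll - 1e-12 && halvings < 25) {
      beta_new = 0.5 * (beta_new + beta);
      eta_new = X * beta_new;
      ll_new = bernoulli_loglik(y, eta_new);
      ++halvings;
    }
    double rel = std::fabs(ll_new - ll) / (std::fabs(ll_new) + 0.1);
    beta = beta_new;
    eta = eta_new;
    double ll_old = ll;
    ll = ll_new;
    if (rel < tol && it > 1) {
      out.converged = true;
      break;
    }
    (void)ll_old;
  }

  out.beta = beta;
  out.loglik = ll;

  // separation: saturated fitted probabilities together with diverging betas
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  bool saturated = (mu.min() < 1e-10) || (mu.max() > 1.0 - 1e-10);
  bool diverging = arma::abs(beta).max() > 10.0;
  out.separated = saturated && diverging;

  if (!out.singular) {
    arma::vec mu2 = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu2 % (1.0 - mu2);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec sw = arma::sqrt(w);
    arma::mat Xs = X.each_col() % sw;
    arma::mat info = Xs.t() * Xs;
    arma::mat cov;
    if (arma::inv_sympd(cov, info)) {
      out.se = arma::sqrt(cov.diag());
    } else {
      out.singular = true;
    }
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_logistic_fit(const arma::mat &X, const arma::vec &y,
                      const arma::vec &start, int max_iter, double tol) {
  IrlsFit f = irls(X, y, start, max_iter, tol);
  return List::create(
      _["coefficients"] = f.beta, _["std_errors"] = f.se,
      _["log_likelihood"] = f.loglik, _["converged"] = f.converged,
      _["separated"] = f.separated, _["singular"] = f.singular,
      _["iterations"] = f.iter);
}

// Threshold scan: fit the null model once, then for each cut-off T append the
// indicator column I(L >= T) and refit warm-started from the null solution.
// Returns per-threshold alternative log-likelihood, indicator estimate and
// standard error, plus convergence / separation / singularity flags.
// [[Rcpp::export]]
List cpp_smt_scan(const arma::mat &Xnull, const arma::vec &y,
                  const arma::vec &L, const arma::vec &thresholds,
                  int max_iter, double tol) {
  const arma::uword n = Xnull.n_rows;
  const arma::uword p = Xnull.n_cols;
  const arma::uword m = thresholds.n_elem;

  arma::vec start0(p, arma::fill::zeros);
  double ybar = arma::mean(y);
  start0[0] = std::log(ybar / (1.0 - ybar));
  IrlsFit null_fit = irls(Xnull, y, start0, max_iter, tol);

  arma::mat X(n, p + 1);
  X.cols(0, p - 1) = Xnull;

  arma::vec ll_alt(m), pi_hat(m), pi_se(m);
  LogicalVector conv(m), sep(m), sing(m);

  for (arma::uword k = 0; k < m; ++k) {
    for (arma::uword i = 0; i < n; ++i)
      X(i, p) = (L[i] >= thresholds[k]) ? 1.0 : 0.0;
    arma::vec start(p + 1, arma::fill::zeros);
    if (null_fit.beta.is_finite())
      start.head(p) = null_fit.beta;
    else
      start[0] = start0[0];
    IrlsFit f = irls(X, y, start, max_iter, tol);
    ll_alt[k] = f.loglik;
    pi_hat[k] = f.beta[p];
    pi_se[k] = f.se[p];
    conv[k] = f.converged;
    sep[k] = f.separated;
    sing[k] = f.singular;
  }

  return List::create(
      _["null_loglik"] = null_fit.loglik,
      _["null_converged"] = null_fit.converged,
      _["null_separated"] = null_fit.separated,
      _["null_singular"] = null_fit.singular,
      _["alt_loglik"] = ll_alt, _["pi"] = pi_hat, _["se"] = pi_se,
      _["converged"] = conv, _["separated"] = sep, _["singular"] = sing);
}
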