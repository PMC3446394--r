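// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
using namespace Rcpp;

// Logistic regression by iteratively reweighted least squares with
// step-halving (monotone log-likelihood ascent) and a small ridge
// stabiliser on the normal equations. Under (quasi-)separation the
// likelihood plateaus and the fit stops with finite, clamped values.
// stats::glm is the independent cross-check in the test suite.
namespace {

struct IrlsFit {
  arma::vec beta;
  double loglik = 0.0, aic = 0.0;
  bool converged = false;
};

double loglik_at(const arma::mat& X, const arma::vec& y, const arma::vec& beta) {
  arma::vec eta = arma::clamp(X * beta, -30.0, 30.0);
  arma::vec mu = arma::clamp(1.0 / (1.0 + arma::exp(-eta)), 1e-12, 1.0 - 1e-12);
  return arma::accu(y % arma::log(mu) + (1.0 - y) % arma::log(1.0 - mu));
}

IrlsFit irls(const arma::mat& X, const arma::vec& y, arma::vec beta,
             int maxit, double tol, double ridge) {
  const arma::uword p = X.n_cols;
  if (beta.n_elem != p) beta = arma::zeros(p);
  IrlsFit out;
  double ll = loglik_at(X, y, beta);
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = arma::clamp(X * beta, -30.0, 30.0);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
    arma::vec z = eta + (y - mu) / w;
    arma::mat A = X.t() * (X.each_col() % w);
    A.diag() += ridge * (double)X.n_rows;
    arma::vec b = X.t() * (w % z);
    arma::vec beta_new;
    if (!arma::solve(beta_new, A, b, arma::solve_opts::likely_sympd)) {
      A.diag() += 1e-3 * (double)X.n_rows;
      if (!arma::solve(beta_new, A, b)) break;
    }
    // step-halving: never accept a likelihood decrease
    double ll_new = loglik_at(X, y, beta_new);
    int halvings = 0;
    while (ll_new < ll - 1e-10 && halvings < 20) {
      beta_new = 0.5 * (beta_new + beta);
      ll_new = loglik_at(X, y, beta_new);
      ++halvings;
    }
    if (ll_new < ll - 1e-10) { out.converged = true; break; }  // plateau
    const double delta = arma::abs(beta_new - beta).max();
    const double gain = ll_new - ll;
    beta = beta_new;
    ll = ll_new;
    if (delta < tol || gain < 1e-8 * (1.0 + std::fabs(ll))) {
      out.converged = true;
      break;
    }
  }
  out.beta = beta;
  out.loglik = ll;
  out.aic = 2.0 * (double)p - 2.0 * ll;
  return out;
}

}  // namespace

// Single logistic fit. X must already contain the intercept column.
// Returns coefficients, log-likelihood, AIC, Wald standard errors and
// convergence/separation flags.
// [[Rcpp::export]]
List logit_fit_cpp(const arma::mat& X, const arma::vec& y,
                   Nullable<NumericVector> beta_start = R_NilValue,
                   int maxit = 60, double tol = 1e-9, double ridge = 1e-8) {
  const arma::uword p = X.n_cols;
  arma::vec beta;
  if (beta_start.isNotNull()) {
    NumericVector b0(beta_start);
    if ((arma::uword)b0.size() == p) beta = arma::vec(b0.begin(), p);
  }
  IrlsFit fit = irls(X, y, beta, maxit, tol, ridge);
  // Wald SEs from the final weighted information matrix
  arma::vec eta = arma::clamp(X * fit.beta, -30.0, 30.0);
  arma::vec mu = arma::clamp(1.0 / (1.0 + arma::exp(-eta)), 1e-12, 1.0 - 1e-12);
  arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
  arma::mat A = X.t() * (X.each_col() % w);
  A.diag() += ridge * (double)X.n_rows;
  arma::vec se(p); se.fill(NA_REAL);
  arma::mat Ainv;
  if (arma::inv_sympd(Ainv, A)) se = arma::sqrt(Ainv.diag());
  const bool separated = arma::abs(fit.beta).max() > 50.0;
  return List::create(
    _["coefficients"] = NumericVector(fit.beta.begin(), fit.beta.end()),
    _["se"] = NumericVector(se.begin(), se.end()),
    _["loglik"] = fit.loglik,
    _["aic"] = fit.aic,
    _["converged"] = fit.converged,
    _["separated"] = separated);
}

// Backward elimination by AIC over the columns of X (intercept added
// internally). Every deletion candidate is scored each step: a one-step
// Newton coefficient vector for the reduced model is obtained by
// Schur-complement downdating of the current fit's information inverse,
// and its actual (clamped) log-likelihood is evaluated. Because that
// coefficient vector is a feasible point of the reduced model, the
// resulting AIC estimate can only overstate the converged candidate AIC,
// so an accepted removal is guaranteed to reduce the true AIC, which is
// then re-established by a fully converged warm refit. The best
// `refit_tries` candidates are confirmed by converged refits before the
// search stops. With `exact = true` every candidate is evaluated by a
// fully converged refit (the classical backward search). Returns 1-based
// indices of the retained columns and the removal path.
// [[Rcpp::export]]
List backward_aic_cpp(const arma::mat& X, const arma::vec& y,
                      int refit_tries = 3, bool exact = false,
                      int maxit = 50, double tol = 1e-8,
                      double ridge = 1e-8) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat Xc(n, p + 1);
  Xc.col(0).ones();
  if (p > 0) Xc.cols(1, p) = X;
  std::vector<int> active(p);
  for (arma::uword j = 0; j < p; ++j) active[j] = (int)(j + 1);
  IrlsFit cur = irls(Xc, y, arma::vec(), maxit, tol, ridge);
  std::vector<int> removed;
  std::vector<double> aic_path;
  while (!active.empty()) {
    const arma::uword pc = active.size();
    arma::vec approx_aic(pc);
    if (exact) {
      for (arma::uword j = 0; j < pc; ++j) {
        arma::mat Xr = Xc;
        Xr.shed_col(j + 1);
        arma::vec warm = cur.beta;
        warm.shed_row(j + 1);
        approx_aic[j] = irls(Xr, y, warm, maxit, tol, ridge).aic;
      }
    } else {
      // shared one-step downdate scores for all candidates
      arma::vec eta = arma::clamp(Xc * cur.beta, -30.0, 30.0);
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
      arma::vec zz = eta + (y - mu) / w;
      arma::mat A = Xc.t() * (Xc.each_col() % w);
      A.diag() += ridge * (double)n;
      arma::mat Ainv;
      if (!arma::inv_sympd(Ainv, A)) {
        A.diag() += 1e-3 * (double)n;
        Ainv = arma::pinv(A);
      }
      arma::vec bvec = Xc.t() * (w % zz);
      arma::vec bn = Ainv * bvec;          // full one-step Newton update
      arma::vec u = Xc * bn;
      arma::mat V = Xc * Ainv;             // n x (pc + 1)
      for (arma::uword j = 0; j < pc; ++j) {
        const double d = Ainv(j + 1, j + 1);
        const double c = d > 0 ? bn[j + 1] / d : 0.0;
        arma::vec eta_j = arma::clamp(u - c * V.col(j + 1), -30.0, 30.0);
        arma::vec mu_j = arma::clamp(1.0 / (1.0 + arma::exp(-eta_j)),
                                     1e-12, 1.0 - 1e-12);
        const double ll_j = arma::accu(y % arma::log(mu_j) +
                                       (1.0 - y) % arma::log(1.0 - mu_j));
        approx_aic[j] = 2.0 * (double)pc - 2.0 * ll_j;  // (pc-1 features + icept)
      }
    }
    arma::uvec ord = arma::sort_index(approx_aic);
    const arma::uword tries =
        exact ? 1 : std::min((arma::uword)std::max(refit_tries, 1), pc);
    bool accepted = false;
    for (arma::uword t = 0; t < tries; ++t) {
      const arma::uword j = ord[t];
      arma::mat Xr = Xc;
      Xr.shed_col(j + 1);
      arma::vec warm = cur.beta;
      warm.shed_row(j + 1);
      IrlsFit f = exact ? irls(Xr, y, warm, maxit, tol, ridge)
                        : irls(Xr, y, warm, maxit, tol, ridge);
      if (f.aic < cur.aic) {
        removed.push_back(active[j]);
        active.erase(active.begin() + j);
        Xc.shed_col(j + 1);
        cur = f;
        aic_path.push_back(cur.aic);
        accepted = true;
        break;
      }
    }
    if (!accepted) break;
  }
  IntegerVector sel(active.size());
  for (size_t j = 0; j < active.size(); ++j) sel[j] = active[j];
  return List::create(_["selected"] = sel, _["aic"] = cur.aic,
                      _["removed"] = wrap(removed),
                      _["aic_path"] = wrap(aic_path));
}
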