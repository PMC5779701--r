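// Graphical lasso by block coordinate descent (Friedman, Hastie & Tibshirani
// style): cycle over nodes, solve each node's lasso subproblem on the current
// covariance estimate W, with the L1 penalty applied to off-diagonal entries
// only (diagonal of W stays at diag(S)). The inner lasso uses an active-set
// strategy: full sweeps establish the support, then only nonzero coefficients
// are iterated until convergence.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One inner-lasso coordinate pass for node j over the index set `set`;
// returns the largest coefficient change.
static double lasso_pass(const arma::mat& S, const arma::mat& W, arma::mat& B,
                         int j, double rho, const std::vector<int>& set) {
  int p = S.n_rows;
  double del = 0.0;
  for (int i : set) {
    double r = S(i, j);
    for (int k = 0; k < p; ++k)
      if (k != j && k != i) r -= W(k, i) * B(k, j);
    double bnew = soft(r, rho) / W(i, i);
    double ch = std::fabs(bnew - B(i, j));
    if (ch > del) del = ch;
    B(i, j) = bnew;
  }
  return del;
}

// One glasso fit with warm start in W (covariance) and B (regression coefs).
static bool glasso_core(const arma::mat& S, double rho, double tol, int maxit,
                        arma::mat& W, arma::mat& B, int& iters) {
  int p = S.n_rows;
  std::vector<int> full, active;
  full.reserve(p - 1);
  bool converged = false;
  for (iters = 1; iters <= maxit; ++iters) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      full.clear();
      for (int i = 0; i < p; ++i) if (i != j) full.push_back(i);
      double del = lasso_pass(S, W, B, j, rho, full);
      if (del >= tol) {
        for (int it2 = 0; it2 < 1000 && del >= tol; ++it2) {
          active.clear();
          for (int i : full) if (B(i, j) != 0.0) active.push_back(i);
          if (active.empty()) break;
          del = lasso_pass(S, W, B, j, rho, active);
          if (del < tol) del = lasso_pass(S, W, B, j, rho, full);
        }
      }
      // w12 = W11 * beta
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        double w = 0.0;
        for (int k = 0; k < p; ++k)
          if (k != j) w += W(i, k) * B(k, j);
        double d = std::fabs(w - W(i, j));
        if (d > maxdiff) maxdiff = d;
        W(i, j) = w;
        W(j, i) = w;
      }
    }
    if (maxdiff < tol) { converged = true; break; }
  }
  return converged;
}

// Recover the precision matrix from (W, B); exact zeros in B give exact zeros
// in Theta, preserving the lasso support.
static arma::mat theta_from_wb(const arma::mat& W, const arma::mat& B) {
  int p = W.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k)
      if (k != j) dot += W(k, j) * B(k, j);
    double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    for (int i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}

//' @noRd
// [[Rcpp::export]]
List cpp_glasso(arma::mat S, double rho, double tol, int maxit) {
  int p = S.n_rows;
  if (rho <= 0.0) {
    arma::mat Theta = arma::inv_sympd(S);
    return List::create(_["Theta"] = Theta, _["W"] = S, _["iters"] = 0,
                        _["converged"] = true);
  }
  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  int iters = 0;
  bool conv = glasso_core(S, rho, tol, maxit, W, B, iters);
  arma::mat Theta = theta_from_wb(W, B);
  return List::create(_["Theta"] = Theta, _["W"] = W, _["iters"] = iters,
                      _["converged"] = conv);
}

//' @noRd
// [[Rcpp::export]]
List cpp_glasso_path(arma::mat S, arma::vec lambdas, double tol, int maxit) {
  int p = S.n_rows, m = lambdas.n_elem;
  arma::cube Thetas(p, p, m);
  arma::vec loglik(m);
  arma::ivec n_edges(m);
  LogicalVector converged(m);
  arma::mat W = S;                         // warm start across the path
  arma::mat B(p, p, arma::fill::zeros);
  for (int l = 0; l < m; ++l) {
    int iters = 0;
    bool conv = glasso_core(S, lambdas(l), tol, maxit, W, B, iters);
    converged[l] = conv;
    arma::mat Theta = theta_from_wb(W, B);
    Thetas.slice(l) = Theta;
    double ld, sign;
    arma::log_det(ld, sign, Theta);
    loglik(l) = ld - arma::accu(S % Theta);
    int e = 0;
    for (int i = 0; i < p - 1; ++i)
      for (int j = i + 1; j < p; ++j)
        if (std::fabs(Theta(i, j)) > 1e-10) ++e;
    n_edges(l) = e;
  }
  return List::create(_["Thetas"] = Thetas, _["loglik"] = loglik,
                      _["n_edges"] = n_edges, _["converged"] = converged);
}
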