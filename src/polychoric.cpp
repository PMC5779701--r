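#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include "bvn.h"

using namespace Rcpp;

static const double PROB_FLOOR = 1e-12;

// Negative two-step log likelihood of a contingency table under the latent
// bivariate normal model, thresholds held fixed. The CDF grid's boundary
// cells (rows/columns at +-Inf) reduce to univariate normal probabilities
// that do not depend on rho, so they are precomputed once per table.
struct NllCtx {
  std::vector<double> tab;          // nr x nc counts
  int nr, nc;
  std::vector<double> ta, tb;       // finite thresholds
  std::vector<double> G;            // (nr+1) x (nc+1) CDF grid, boundary fixed
  mutable long n_eval = 0;

  void init() {
    G.assign((nr + 1) * (nc + 1), 0.0);
    for (int i = 0; i <= nr; ++i) G[i * (nc + 1)] = 0.0;
    for (int j = 0; j <= nc; ++j) G[j] = 0.0;
    for (int i = 1; i < nr; ++i)
      G[i * (nc + 1) + nc] = R::pnorm(ta[i - 1], 0.0, 1.0, 1, 0);
    for (int j = 1; j < nc; ++j)
      G[nr * (nc + 1) + j] = R::pnorm(tb[j - 1], 0.0, 1.0, 1, 0);
    G[nr * (nc + 1) + nc] = 1.0;
  }

  double nll(double rho) const {
    std::vector<double> Gr(G);
    for (int i = 1; i < nr; ++i)
      for (int j = 1; j < nc; ++j)
        Gr[i * (nc + 1) + j] = bvn_cdf(ta[i - 1], tb[j - 1], rho);
    double out = 0.0;
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        double nij = tab[i * nc + j];
        if (nij <= 0.0) continue;
        double pij = Gr[(i + 1) * (nc + 1) + (j + 1)] - Gr[i * (nc + 1) + (j + 1)]
                   - Gr[(i + 1) * (nc + 1) + j] + Gr[i * (nc + 1) + j];
        if (pij < PROB_FLOOR) pij = PROB_FLOOR;
        out -= nij * std::log(pij);
      }
    }
    return out;
  }
};

static double nll_at(double rho, const NllCtx& c) { return c.nll(rho); }

// Classical Brent scalar minimizer on [a, b].
static double brent_min(double a, double b, const NllCtx& ctx, double tol,
                        double* fmin_out) {
  const double golden = 0.3819660112501051;
  const double eps = std::sqrt(2.220446049250313e-16);
  double x = a + golden * (b - a), w = x, v = x;
  double fx = nll_at(x, ctx), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 200; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x >= xm) ? a - x : b - x;
      d = golden * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = nll_at(u, ctx);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  if (fmin_out) *fmin_out = fx;
  return x;
}

// Fit rho for one table with given thresholds. Returns rho, nll, boundary flag.
static void fit_table(const std::vector<double>& tab, int nr, int nc,
                      const std::vector<double>& ta,
                      const std::vector<double>& tb, double bound, double tol,
                      double& rho, int& flag) {
  NllCtx ctx;
  ctx.tab = tab; ctx.nr = nr; ctx.nc = nc; ctx.ta = ta; ctx.tb = tb;
  ctx.init();
  double fmin;
  rho = brent_min(-bound, bound, ctx, tol, &fmin);
  // Brent never evaluates the endpoints; when the minimizer runs toward a
  // bound (monotone likelihood, e.g. empty off-diagonal 2x2 cells), compare
  // against the endpoints explicitly so the estimate lands on the bound.
  if (std::fabs(rho) > 0.9 * bound) {
    double flo = nll_at(-bound, ctx), fhi = nll_at(bound, ctx);
    if (flo < fmin) { rho = -bound; fmin = flo; }
    if (fhi < fmin) { rho = bound; fmin = fhi; }
  }
  flag = (std::fabs(std::fabs(rho) - bound) < 1e-4) ? 1 : 0;
}

// Margins -> standard-normal thresholds (strictly increasing; zero-mass
// boundary or interior categories merge and contribute no cut point).
static std::vector<double> margins_to_thresholds(const std::vector<double>& counts,
                                                 double n) {
  std::vector<double> th;
  double cum = 0.0;
  for (size_t k = 0; k + 1 < counts.size(); ++k) {
    cum += counts[k];
    if (cum > 0.0 && cum < n) {
      double q = R::qnorm(cum / n, 0.0, 1.0, 1, 0);
      if (th.empty() || q > th.back()) th.push_back(q);
    }
  }
  return th;
}

//' @noRd
// [[Rcpp::export]]
List cpp_polychoric_table(NumericMatrix tab, double bound, double tol) {
  int nr = tab.nrow(), nc = tab.ncol();
  double n = 0.0;
  std::vector<double> t(nr * nc), rmarg(nr, 0.0), cmarg(nc, 0.0);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      t[i * nc + j] = tab(i, j);
      rmarg[i] += tab(i, j);
      cmarg[j] += tab(i, j);
      n += tab(i, j);
    }
  // drop zero-mass rows/columns (merged categories)
  std::vector<double> t2;
  std::vector<double> rm2, cm2;
  std::vector<int> rkeep, ckeep;
  for (int i = 0; i < nr; ++i) if (rmarg[i] > 0) { rkeep.push_back(i); rm2.push_back(rmarg[i]); }
  for (int j = 0; j < nc; ++j) if (cmarg[j] > 0) { ckeep.push_back(j); cm2.push_back(cmarg[j]); }
  int nr2 = rkeep.size(), nc2 = ckeep.size();
  if (nr2 < 2 || nc2 < 2)
    return List::create(_["rho"] = NA_REAL, _["flag"] = 3,
                        _["thresholds_row"] = NumericVector(0),
                        _["thresholds_col"] = NumericVector(0));
  t2.resize(nr2 * nc2);
  for (int i = 0; i < nr2; ++i)
    for (int j = 0; j < nc2; ++j)
      t2[i * nc2 + j] = t[rkeep[i] * nc + ckeep[j]];
  std::vector<double> ta = margins_to_thresholds(rm2, n);
  std::vector<double> tb = margins_to_thresholds(cm2, n);
  double rho; int flag;
  fit_table(t2, nr2, nc2, ta, tb, bound, tol, rho, flag);
  return List::create(_["rho"] = rho, _["flag"] = flag,
                      _["thresholds_row"] = NumericVector(ta.begin(), ta.end()),
                      _["thresholds_col"] = NumericVector(tb.begin(), tb.end()));
}

// Build the pairwise-complete contingency table for columns a and b of an
// integer matrix with NA for missing, then fit rho. Categories are the values
// observed in the pairwise subset.
static void pair_fit(const IntegerMatrix& X, int a, int b, int min_n,
                     double bound, double tol, double& rho, int& flag,
                     int& npair) {
  int n = X.nrow();
  std::vector<int> xa, xb;
  xa.reserve(n); xb.reserve(n);
  for (int i = 0; i < n; ++i) {
    int va = X(i, a), vb = X(i, b);
    if (va == NA_INTEGER || vb == NA_INTEGER) continue;
    xa.push_back(va); xb.push_back(vb);
  }
  npair = (int)xa.size();
  if (npair < min_n) { rho = NA_REAL; flag = 2; return; }
  std::vector<int> ua(xa), ub(xb);
  std::sort(ua.begin(), ua.end()); ua.erase(std::unique(ua.begin(), ua.end()), ua.end());
  std::sort(ub.begin(), ub.end()); ub.erase(std::unique(ub.begin(), ub.end()), ub.end());
  int nr = ua.size(), nc = ub.size();
  if (nr < 2 || nc < 2) { rho = NA_REAL; flag = 3; return; }
  std::vector<double> tab(nr * nc, 0.0), rmarg(nr, 0.0), cmarg(nc, 0.0);
  for (int i = 0; i < npair; ++i) {
    int r = std::lower_bound(ua.begin(), ua.end(), xa[i]) - ua.begin();
    int c = std::lower_bound(ub.begin(), ub.end(), xb[i]) - ub.begin();
    tab[r * nc + c] += 1.0;
    rmarg[r] += 1.0; cmarg[c] += 1.0;
  }
  std::vector<double> ta = margins_to_thresholds(rmarg, (double)npair);
  std::vector<double> tb = margins_to_thresholds(cmarg, (double)npair);
  fit_table(tab, nr, nc, ta, tb, bound, tol, rho, flag);
}

//' @noRd
// [[Rcpp::export]]
List cpp_polychoric_pair(IntegerMatrix X, int a, int b, int min_n,
                         double bound, double tol) {
  double rho; int flag, npair;
  pair_fit(X, a - 1, b - 1, min_n, bound, tol, rho, flag, npair);
  return List::create(_["rho"] = rho, _["flag"] = flag, _["n"] = npair);
}

//' @noRd
// [[Rcpp::export]]
List cpp_polychoric_matrix(IntegerMatrix X, int min_n, double bound,
                           double tol) {
  int p = X.ncol();
  NumericMatrix R(p, p);
  IntegerMatrix Np(p, p), Flag(p, p);
  int n = X.nrow();
  for (int j = 0; j < p; ++j) {
    R(j, j) = 1.0;
    int cnt = 0;
    for (int i = 0; i < n; ++i) if (X(i, j) != NA_INTEGER) ++cnt;
    Np(j, j) = cnt;
  }
  for (int a = 0; a < p - 1; ++a) {
    for (int b = a + 1; b < p; ++b) {
      double rho; int flag, npair;
      pair_fit(X, a, b, min_n, bound, tol, rho, flag, npair);
      R(a, b) = R(b, a) = rho;
      Flag(a, b) = Flag(b, a) = flag;
      Np(a, b) = Np(b, a) = npair;
    }
  }
  return List::create(_["R"] = R, _["n_pairwise"] = Np, _["flag"] = Flag);
}
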