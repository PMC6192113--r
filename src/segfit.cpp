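// Core numerical routines for segmented-regression fitting: least-squares
// RSS of the hinge (broken-stick) design at fixed breakpoints, batch grid
// evaluation, and one restart of the iterative-linearization breakpoint
// search. Mirrors the algorithm documented in R/segreg.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Solve min ||y - X beta|| via normal equations + Cholesky; returns false
// when X is (numerically) rank deficient. rss is clamped at zero because
// the y'y - beta'X'y form can go slightly negative for interpolating fits.
static bool ls_rss(const arma::mat& X, const arma::vec& y, double yty,
                   double& rss) {
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  arma::mat R;
  if (!arma::chol(R, XtX)) return false;
  arma::vec d = R.diag();
  if (d.min() < 1e-7 * d.max()) return false;
  arma::vec z = arma::solve(arma::trimatl(R.t()), Xty);
  double fit = arma::dot(z, z);
  rss = yty - fit;
  if (rss < 0) rss = 0;
  return true;
}

static bool ls_coef(const arma::mat& X, const arma::vec& y,
                    arma::vec& coef) {
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  arma::mat R;
  if (!arma::chol(R, XtX)) return false;
  arma::vec d = R.diag();
  if (d.min() < 1e-7 * d.max()) return false;
  arma::vec z = arma::solve(arma::trimatl(R.t()), Xty);
  coef = arma::solve(arma::trimatu(R), z);
  return true;
}

static void fill_hinge(arma::mat& X, const arma::vec& t,
                       const arma::vec& b) {
  const int n = t.n_elem, k = b.n_elem;
  for (int j = 0; j < k; ++j) {
    const double bj = b(j);
    for (int i = 0; i < n; ++i) {
      const double v = t(i) - bj;
      X(i, 2 + j) = v > 0 ? v : 0;
    }
  }
}

// RSS of the hinge design at one breakpoint set; -1 signals rank loss.
static double hinge_rss_at(const arma::vec& y, const arma::vec& t,
                           const arma::vec& b, arma::mat& X, double yty) {
  fill_hinge(X, t, b);
  double rss;
  if (!ls_rss(X, y, yty, rss)) return -1.0;
  return rss;
}

// [[Rcpp::export]]
double cpp_hinge_rss(const arma::vec& y, const arma::vec& t,
                     const arma::vec& b) {
  const int n = t.n_elem, k = b.n_elem;
  arma::mat X(n, k + 2);
  X.col(0).ones();
  X.col(1) = t;
  return hinge_rss_at(y, t, b, X, arma::dot(y, y));
}

// Batch RSS over candidate breakpoint sets (columns of B); NA = rank loss.
// [[Rcpp::export]]
NumericVector cpp_grid_rss(const arma::vec& y, const arma::vec& t,
                           const arma::mat& B) {
  const int n = t.n_elem, k = B.n_rows, m = B.n_cols;
  arma::mat X(n, k + 2);
  X.col(0).ones();
  X.col(1) = t;
  const double yty = arma::dot(y, y);
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double r = hinge_rss_at(y, t, B.col(j), X, yty);
    out[j] = r < 0 ? NA_REAL : r;
  }
  return out;
}

// One restart of the iterative linearization (see R/segreg.R for the
// algorithm description: gap covariates, movability guard, trust region,
// step halving with a minimum inter-breakpoint gap).
// [[Rcpp::export]]
List cpp_seg_iterate(const arma::vec& y, const arma::vec& t,
                     const arma::vec& ut, arma::vec b, double lo, double hi,
                     double tol_abs, int max_iter, double min_gap) {
  const int n = t.n_elem, k = b.n_elem, T = ut.n_elem;
  const double rng = ut(T - 1) - ut(0);
  const double yty = arma::dot(y, y);
  arma::mat Xh(n, k + 2);
  Xh.col(0).ones();
  Xh.col(1) = t;
  double cur = hinge_rss_at(y, t, b, Xh, yty);
  if (cur < 0) return List::create(_["ok"] = false);
  int it = 0;
  while (it < max_iter) {
    ++it;
    if (cur <= 0) break;
    // movability: >= 2 distinct times in (b_i, b_{i+1}]; the first
    // breakpoint also needs >= 2 distinct times at or below it
    std::vector<int> mov;
    for (int i = 0; i < k; ++i) {
      const double up = (i < k - 1) ? b(i + 1) : arma::datum::inf;
      int cnt = 0;
      for (int j = 0; j < T; ++j) {
        if (ut(j) > b(i) && ut(j) <= up) ++cnt;
      }
      if (i == 0) {
        int below = 0;
        for (int j = 0; j < T; ++j) {
          if (ut(j) <= b(0)) ++below;
        }
        if (below < 2) cnt = 0;
      }
      if (cnt >= 2) mov.push_back(i);
    }
    const int m = mov.size();
    if (m == 0) break;
    arma::mat X(n, k + 2 + m);
    X.col(0).ones();
    X.col(1) = t;
    fill_hinge(X, t, b);
    for (int j = 0; j < m; ++j) {
      const double bj = b(mov[j]);
      for (int i = 0; i < n; ++i) X(i, k + 2 + j) = t(i) > bj ? -1.0 : 0.0;
    }
    arma::vec coef;
    if (!ls_coef(X, y, coef)) return List::create(_["ok"] = false);
    arma::vec step(k, arma::fill::zeros);
    bool bad = false;
    for (int j = 0; j < m; ++j) {
      const double delta = coef(2 + mov[j]);
      const double gamma = coef(k + 2 + j);
      if (!std::isfinite(delta) || std::fabs(delta) < 1e-12) {
        bad = true;
        break;
      }
      double s = gamma / delta;
      if (s > rng / 2) s = rng / 2;
      if (s < -rng / 2) s = -rng / 2;
      step(mov[j]) = s;
    }
    if (bad) return List::create(_["ok"] = false);
    bool accepted = false;
    arma::vec bp(k);
    double newr = -1;
    for (int h = 0; h <= 20; ++h) {
      for (int i = 0; i < k; ++i) {
        double v = b(i) + step(i);
        if (v < lo) v = lo;
        if (v > hi) v = hi;
        bp(i) = v;
      }
      bool collide = false;
      for (int i = 1; i < k; ++i) {
        if (bp(i) - bp(i - 1) < min_gap) {
          collide = true;
          break;
        }
      }
      if (!collide) {
        newr = hinge_rss_at(y, t, bp, Xh, yty);
        if (newr >= 0 && newr <= cur * (1 + 1e-10) + 1e-300) {
          accepted = true;
          break;
        }
      }
      step *= 0.5;
    }
    if (!accepted) break;
    double moved = 0;
    for (int i = 0; i < k; ++i) {
      moved = std::max(moved, std::fabs(bp(i) - b(i)));
    }
    b = bp;
    if (newr < cur) cur = newr;
    if (moved < tol_abs) break;
  }
  return List::create(_["ok"] = true, _["b"] = b, _["rss"] = cur,
                      _["n_iter"] = it);
}
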