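// Lloyd's k-means accelerated with Elkan's triangle-inequality bounds.
//
// Exact Lloyd iterations: identical assignments/centroids to the naive
// loop, but per-point/per-center lower bounds plus the upper bound to the
// assigned center let most distance evaluations be skipped.  Centroid sums
// are maintained incrementally (only points that switch clusters are
// touched).  An empty cluster is re-seeded at the point farthest (by
// current bound) from its centroid.  Convergence: no assignment changes or
// maxIter reached.  Data are held transposed (d x n) so per-point access
// is contiguous.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double dcol(const mat& A, uword ia, const mat& B, uword ib) {
  const double* a = A.colptr(ia);
  const double* b = B.colptr(ib);
  double s = 0.0;
  const uword d = A.n_rows;
  for (uword t = 0; t < d; ++t) { double v = a[t] - b[t]; s += v * v; }
  return std::sqrt(s);
}

// [[Rcpp::export(name = ".lloydCpp")]]
Rcpp::List lloydCpp(const arma::mat& X, const arma::mat& C0, int maxIter) {
  const uword n = X.n_rows, k = C0.n_rows;
  const mat Xt = X.t();              // d x n
  mat Ct = C0.t();                   // d x k
  const vec xsq = sum(X % X, 1);

  uvec assign(n);
  vec u(n);
  mat lb(k, n);                      // lower bounds, one column per point

  // initial full assignment with exact distances (BLAS)
  {
    mat D = -2.0 * (X * Ct);         // n x k
    D.each_row() += sum(Ct % Ct, 0);
    D.each_col() += xsq;
    D.transform([](double v) { return v < 0 ? 0 : std::sqrt(v); });
    for (uword i = 0; i < n; ++i) {
      rowvec di = D.row(i);
      uword j1 = di.index_min();
      assign(i) = j1;
      u(i) = di(j1);
      lb.col(i) = di.t();
    }
  }

  mat Csum(Ct.n_rows, k, fill::zeros);
  vec cnt(k, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    Csum.col(assign(i)) += Xt.col(i);
    cnt(assign(i)) += 1.0;
  }

  mat dcc(k, k, fill::zeros);
  vec s(k), shift(k);
  int it = 0;
  for (it = 1; it <= maxIter; ++it) {
    for (uword j = 0; j < k; ++j) {
      if (cnt(j) == 0) {             // empty cluster: farthest point by bound
        uword far = u.index_max();
        uword a = assign(far);
        Csum.col(a) -= Xt.col(far); cnt(a) -= 1.0;
        Csum.col(j) += Xt.col(far); cnt(j) += 1.0;
        assign(far) = j;
        u(far) = 0.0;
        lb(j, far) = 0.0;
      }
    }

    // centroid update; track per-center motion
    for (uword j = 0; j < k; ++j) {
      vec cj = Csum.col(j) / cnt(j);
      shift(j) = norm(cj - Ct.col(j), 2);
      Ct.col(j) = cj;
    }

    // bound maintenance
    for (uword i = 0; i < n; ++i) {
      u(i) += shift(assign(i));
      double* lbi = lb.colptr(i);
      for (uword j = 0; j < k; ++j) {
        lbi[j] -= shift(j);
        if (lbi[j] < 0) lbi[j] = 0;
      }
    }

    // inter-center distances and s(a) = 0.5 min_{b != a} d(a,b)
    s.fill(datum::inf);
    for (uword a = 0; a + 1 < k; ++a)
      for (uword b = a + 1; b < k; ++b) {
        double d = dcol(Ct, a, Ct, b);
        dcc(a, b) = dcc(b, a) = d;
        if (0.5 * d < s(a)) s(a) = 0.5 * d;
        if (0.5 * d < s(b)) s(b) = 0.5 * d;
      }

    uword changed = 0;
    for (uword i = 0; i < n; ++i) {
      uword a = assign(i);
      if (u(i) <= s(a)) continue;
      bool stale = true;
      double* lbi = lb.colptr(i);
      for (uword j = 0; j < k; ++j) {
        if (j == a) continue;
        if (u(i) <= lbi[j] || u(i) <= 0.5 * dcc(a, j)) continue;
        if (stale) {                 // tighten the upper bound once
          u(i) = dcol(Xt, i, Ct, a);
          lbi[a] = u(i);
          stale = false;
          if (u(i) <= lbi[j] || u(i) <= 0.5 * dcc(a, j)) continue;
        }
        double d = dcol(Xt, i, Ct, j);
        lbi[j] = d;
        if (d < u(i)) {
          Csum.col(a) -= Xt.col(i); cnt(a) -= 1.0;
          Csum.col(j) += Xt.col(i); cnt(j) += 1.0;
          a = j;
          assign(i) = j;
          u(i) = d;
          ++changed;
        }
      }
    }
    if (changed == 0) break;
  }

  // exact final SSE and assignment (BLAS)
  mat D = -2.0 * (X * Ct);
  D.each_row() += sum(Ct % Ct, 0);
  D.each_col() += xsq;
  double sse = 0.0;
  for (uword i = 0; i < n; ++i) {
    uword j1 = D.row(i).index_min();
    assign(i) = j1;
    double v = D(i, j1);
    sse += v > 0 ? v : 0;
  }

  return Rcpp::List::create(
    Rcpp::Named("centers") = Ct.t(),
    Rcpp::Named("assign") = Rcpp::IntegerVector(assign.begin(), assign.end()),
    Rcpp::Named("sse") = sse,
    Rcpp::Named("iterations") = it);
}
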