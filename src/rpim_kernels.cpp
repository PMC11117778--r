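#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// k nearest nodes for each query point, sorted by ascending Euclidean
// distance with ties broken by ascending node id (0-based comparison,
// returned 1-based).  Brute force; N and m stay small enough in 2D.
// [[Rcpp::export]]
List cpp_knn(const arma::mat& pts, const arma::mat& nodes, const int k) {
  const int m = pts.n_rows, N = nodes.n_rows;
  if (k > N) stop("k exceeds node count");
  IntegerMatrix idx(k, m);
  NumericMatrix dst(k, m);
  std::vector< std::pair<double, int> > cand(N);
  for (int q = 0; q < m; ++q) {
    const double px = pts(q, 0), py = pts(q, 1);
    for (int i = 0; i < N; ++i) {
      const double dx = nodes(i, 0) - px, dy = nodes(i, 1) - py;
      cand[i] = std::make_pair(dx * dx + dy * dy, i);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(j, q) = cand[j].second + 1;
      dst(j, q) = std::sqrt(cand[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// RPIM shape functions phi and (optionally) their x/y derivatives for a
// batch of evaluation points.  MQ-RBF R(d) = (d^2 + c^2)^p with a linear
// polynomial basis [1, x, y]; per point the moment system
//   G = [R P; P' 0]  (n+3 x n+3)
// is solved directly.  neigh holds 1-based node ids (kmax x m), ncnt the
// number of nodes actually used per point (boundary fallback may use fewer).
// [[Rcpp::export]]
List cpp_rpim_batch(const arma::mat& pts, const arma::mat& nodes,
                    const IntegerMatrix& neigh, const IntegerVector& ncnt,
                    const double c, const double p, const bool deriv) {
  const int m = pts.n_rows, kmax = neigh.nrow();
  NumericMatrix phi(kmax, m), dphx(kmax, m), dphy(kmax, m);
  const double c2 = c * c;
  for (int q = 0; q < m; ++q) {
    const int n = ncnt[q];
    const double px = pts(q, 0), py = pts(q, 1);
    arma::mat X(n, 2);
    for (int i = 0; i < n; ++i) {
      const int id = neigh(i, q) - 1;
      X(i, 0) = nodes(id, 0);
      X(i, 1) = nodes(id, 1);
    }
    arma::mat G(n + 3, n + 3, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      G(i, i) = std::pow(c2, p);
      for (int j = i + 1; j < n; ++j) {
        const double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1);
        const double v = std::pow(dx * dx + dy * dy + c2, p);
        G(i, j) = v;
        G(j, i) = v;
      }
      G(i, n) = 1.0;     G(n, i) = 1.0;
      G(i, n + 1) = X(i, 0); G(n + 1, i) = X(i, 0);
      G(i, n + 2) = X(i, 1); G(n + 2, i) = X(i, 1);
    }
    arma::mat B(n + 3, deriv ? 3 : 1, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      const double dx = px - X(i, 0), dy = py - X(i, 1);
      const double d2 = dx * dx + dy * dy;
      B(i, 0) = std::pow(d2 + c2, p);
      if (deriv) {
        const double t = 2.0 * p * std::pow(d2 + c2, p - 1.0);
        B(i, 1) = t * dx;
        B(i, 2) = t * dy;
      }
    }
    B(n, 0) = 1.0; B(n + 1, 0) = px; B(n + 2, 0) = py;
    if (deriv) { B(n + 1, 1) = 1.0; B(n + 2, 2) = 1.0; }
    arma::mat S;
    const bool ok = arma::solve(S, G, B,
                                arma::solve_opts::no_approx);
    if (!ok)
      stop("degenerate node geometry in influence domain (point %d)", q + 1);
    for (int i = 0; i < n; ++i) {
      phi(i, q) = S(i, 0);
      if (deriv) { dphx(i, q) = S(i, 1); dphy(i, q) = S(i, 2); }
    }
  }
  if (deriv)
    return List::create(_["phi"] = phi, _["dx"] = dphx, _["dy"] = dphy);
  return List::create(_["phi"] = phi);
}
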