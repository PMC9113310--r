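// Numerical kernels: second-order-section IIR filtering, the debiased
// weighted phase-lag index over all parcel pairs, and union-find component
// extent for the NBS permutation null.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form-II-transposed cascade of biquads. `sos` is L x 6 rows
// (b0 b1 b2 a0 a1 a2) with a0 == 1.
// [[Rcpp::export]]
NumericVector sos_filter(const NumericMatrix& sos, const NumericVector& x) {
  const int L = sos.nrow(), n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < L; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int t = 0; t < n; ++t) {
      const double xt = y[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt + z2;
      z2 = b2 * xt - a2 * yt;
      y[t] = yt;
    }
  }
  return y;
}

// Debiased WPLI between all row pairs of an analytic-signal matrix Z
// (parcels x samples). Per-sample observations I_t = Im(z_i conj(z_j));
// value = ((sum I)^2 - sum I^2) / ((sum |I|)^2 - sum I^2).
// Entries with a degenerate denominator are NA (undefined edge).
// [[Rcpp::export]]
NumericMatrix dwpli_all_pairs(const arma::cx_mat& Z) {
  const arma::uword P = Z.n_rows, N = Z.n_cols;
  NumericMatrix out(P, P);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (arma::uword i = 0; i < P; ++i) {
    for (arma::uword j = i + 1; j < P; ++j) {
      double s = 0.0, s2 = 0.0, sa = 0.0, scale = 0.0;
      for (arma::uword t = 0; t < N; ++t) {
        const std::complex<double> zi = Z(i, t), zj = Z(j, t);
        const double I = zi.imag() * zj.real() - zi.real() * zj.imag();
        s += I;
        s2 += I * I;
        sa += std::fabs(I);
        scale += std::abs(zi) * std::abs(zj);
      }
      const double denom = sa * sa - s2;
      double v = NA_REAL;
      if (scale > 0.0 && denom > 1e-12 * scale * scale)
        v = (s * s - s2) / denom;
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Maximum connected-component extent (edge count) of the graph given by the
// 1-based edge list (ei, ej) over `n_nodes` nodes. Union-find with path
// compression; used per permutation in the NBS null.
// [[Rcpp::export]]
int max_component_edges(const IntegerVector& ei, const IntegerVector& ej,
                        int n_nodes) {
  const int m = ei.size();
  if (m == 0) return 0;
  std::vector<int> parent(n_nodes);
  for (int v = 0; v < n_nodes; ++v) parent[v] = v;
  std::function<int(int)> find = [&](int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  };
  for (int e = 0; e < m; ++e) {
    int a = find(ei[e] - 1), b = find(ej[e] - 1);
    if (a != b) parent[a] = b;
  }
  std::vector<int> count(n_nodes, 0);
  int best = 0;
  for (int e = 0; e < m; ++e) {
    const int r = find(ei[e] - 1);
    if (++count[r] > best) best = count[r];
  }
  return best;
}
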