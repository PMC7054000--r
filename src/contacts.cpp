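#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Accumulate ideal-chain contact weights over all snapshots of a
// trajectory. For each snapshot the bridged pairs (left_e, right_e) define
// zero-weight shortcuts on the 1D backbone; the effective separation
// between bin centers is the shortest-path distance, computed from
// all-pairs shortest paths among the (at most 2 * n_extruders) bridge
// endpoints. Contact weight is (1 + s_eff / scale)^(-exponent). Semantics
// identical to the R helper effective_separation().
// [[Rcpp::export]]
NumericMatrix accumulate_gaussian_contacts_cpp(NumericVector centers,
                                               IntegerMatrix left,
                                               IntegerMatrix right,
                                               double scale,
                                               double exponent) {
  const int B = centers.size();
  const int n_snap = left.nrow();
  const int n_ext = left.ncol();
  const int m = 2 * n_ext;
  NumericMatrix acc(B, B);
  std::vector<double> ep(m), D(m * m), A(B * m), Tm(B * m);
  const bool p32 = std::abs(exponent - 1.5) < 1e-12;

  for (int s = 0; s < n_snap; ++s) {
    for (int e = 0; e < n_ext; ++e) {
      ep[2 * e] = (double)left(s, e);
      ep[2 * e + 1] = (double)right(s, e);
    }
    // base endpoint distances; bridge edges weight 0
    for (int u = 0; u < m; ++u)
      for (int v = 0; v < m; ++v) D[u * m + v] = std::abs(ep[u] - ep[v]);
    for (int e = 0; e < n_ext; ++e)
      D[(2 * e) * m + (2 * e + 1)] = D[(2 * e + 1) * m + (2 * e)] = 0.0;
    // Floyd-Warshall on the endpoint graph
    for (int k = 0; k < m; ++k)
      for (int u = 0; u < m; ++u) {
        const double duk = D[u * m + k];
        for (int v = 0; v < m; ++v) {
          const double c = duk + D[k * m + v];
          if (c < D[u * m + v]) D[u * m + v] = c;
        }
      }
    // A[i, u] = |x_i - ep_u|; Tm[i, v] = min_u A[i, u] + D[u, v]
    for (int i = 0; i < B; ++i)
      for (int u = 0; u < m; ++u) A[i * m + u] = std::abs(centers[i] - ep[u]);
    for (int i = 0; i < B; ++i)
      for (int v = 0; v < m; ++v) {
        double best = R_PosInf;
        for (int u = 0; u < m; ++u) {
          const double c = A[i * m + u] + D[u * m + v];
          if (c < best) best = c;
        }
        Tm[i * m + v] = best;
      }
    // pairwise effective separation and contact weight
    double *pa = REAL(acc);
    const double *pc = REAL(centers);
    for (int i = 0; i < B; ++i) {
      const double *ti = Tm.data() + (size_t)i * m;
      const double ci = pc[i];
      for (int j = i; j < B; ++j) {
        double se = std::abs(ci - pc[j]);
        const double *aj = A.data() + (size_t)j * m;
        for (int v = 0; v < m; ++v) {
          const double c = ti[v] + aj[v];
          if (c < se) se = c;
        }
        const double z = 1.0 + se / scale;
        const double w = p32 ? 1.0 / (z * std::sqrt(z)) : std::pow(z, -exponent);
        pa[(R_xlen_t)j * B + i] += w;
        if (i != j) pa[(R_xlen_t)i * B + j] += w;
      }
    }
  }
  return acc;
}
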