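#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact permutation null of Spearman's statistic for tie-free samples.
//
// For untied data rho = 1 - 6 D / (n (n^2 - 1)) with D = sum_i (i - pi(i))^2,
// so the permutation distribution of rho is determined by the distribution of
// D over the n! permutations. That distribution is computed exactly by a
// dynamic program over rank subsets: g[S] is the count vector over D-values
// for assignments of positions 1..|S| to the rank set S, extended one
// position at a time. Cost O(2^n * n * Dmax), feasible through n = 13
// (the cohort size this pipeline targets) without enumerating n!.
//
// Returns counts[d + 1] = #permutations with D = d, d = 0..n(n^2-1)/3.
// Counts are exact in doubles (13! < 2^53).

// [[Rcpp::export(name = ".spearman_d_null_cpp")]]
NumericVector spearman_d_null_cpp(int n) {
  if (n < 1 || n > 13) stop("exact null supported for 1 <= n <= 13");
  const int dmax = n * (n * n - 1) / 3;
  const int len = dmax + 1;
  const size_t nsub = (size_t)1 << n;
  std::vector< std::vector<double> > g(nsub);
  g[0].assign(1, 1.0);
  for (size_t S = 0; S + 1 < nsub; ++S) {
    if (g[S].empty()) continue;
    int pos = 0; // next position index (1-based) = popcount(S) + 1
    for (int j = 0; j < n; ++j)
      if (S & ((size_t)1 << j)) ++pos;
    ++pos;
    for (int j = 0; j < n; ++j) {
      const size_t bit = (size_t)1 << j;
      if (S & bit) continue;
      const int shift = (pos - (j + 1)) * (pos - (j + 1));
      std::vector<double> &dst = g[S | bit];
      const std::vector<double> &src = g[S];
      const size_t need = src.size() + shift;
      if (dst.size() < need) dst.resize(std::min((size_t)len, need), 0.0);
      for (size_t d = 0; d < src.size(); ++d)
        if (src[d] != 0.0) dst[d + shift] += src[d];
    }
    g[S].clear();
    g[S].shrink_to_fit();
  }
  NumericVector out(len);
  const std::vector<double> &full = g[nsub - 1];
  for (size_t d = 0; d < full.size(); ++d) out[d] = full[d];
  return out;
}
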