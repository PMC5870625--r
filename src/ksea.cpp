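#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted running-sum enrichment statistic over a ranked list.
// `w` holds |fc|^1 of the ranked (descending fold change) sites; `pos` holds
// the 0-based, ascending positions of the substrate set in that ranking.
// Hits advance the running sum by w/N_R, misses retract it by 1/(N - k);
// the statistic is the signed extremum of the running sum. Between hits the
// sum decays linearly, so extrema occur only at hit positions or just before
// the next hit, which keeps each evaluation O(k).
static double es_stat(const double* w, int N, const int* pos, int k) {
  double NR = 0.0;
  for (int i = 0; i < k; ++i) NR += w[pos[i]];
  // NR == 0 is rejected on the R side before calling
  double miss = (N == k) ? 0.0 : 1.0 / (double)(N - k);
  double best = 0.0, besta = 0.0, cum = 0.0;
  for (int i = 0; i < k; ++i) {
    int p = pos[i]; // 0-based; misses seen before this hit = p - i
    double lead = (double)(p - i) * miss;
    double before = cum - lead;
    cum += w[p] / NR;
    double at = cum - lead;
    double aat = std::fabs(at), abe = std::fabs(before);
    if (aat > besta) { besta = aat; best = at; }
    if (abe > besta) { besta = abe; best = before; }
  }
  return best;
}

// [[Rcpp::export]]
double ksea_es_cpp(NumericVector ranked_abs, IntegerVector positions) {
  int N = ranked_abs.size(), k = positions.size();
  std::vector<int> pos(k);
  for (int i = 0; i < k; ++i) {
    pos[i] = positions[i] - 1;
    if (pos[i] < 0 || pos[i] >= N) stop("substrate position out of range");
  }
  std::sort(pos.begin(), pos.end());
  return es_stat(REAL(ranked_abs), N, pos.data(), k);
}

// Null enrichment statistics for `n_perm` uniform random substrate sets of
// size k. Uses R's RNG (partial Fisher-Yates), so set.seed() on the R side
// makes the draw reproducible.
// [[Rcpp::export]]
NumericVector ksea_null_cpp(NumericVector ranked_abs, int k, int n_perm) {
  int N = ranked_abs.size();
  if (k < 1 || k > N) stop("invalid substrate count");
  NumericVector out(n_perm);
  std::vector<int> idx(N), pos(k);
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (double)(N - i));
      if (j >= N) j = N - 1; // guard against unif_rand() returning 1.0
      std::swap(idx[i], idx[j]);
    }
    std::copy(idx.begin(), idx.begin() + k, pos.begin());
    std::sort(pos.begin(), pos.end());
    out[b] = es_stat(REAL(ranked_abs), N, pos.data(), k);
  }
  return out;
}
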