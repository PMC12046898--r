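#include <Rcpp.h>
using namespace Rcpp;

// Longest collinear chain by dynamic programming. Anchors must be pre-sorted
// by (ra, rb); both ranks strictly increase along a chain and consecutive
// rank gaps in both genomes are bounded by max_gap. Score is the anchor
// count. Ties resolve to the earliest anchor in sort order, which makes the
// extraction deterministic. Returns 1-based indices of the best chain.
// [[Rcpp::export]]
IntegerVector chain_dp_cpp(IntegerVector ra, IntegerVector rb, int max_gap) {
  int n = ra.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> best(n, 1), prev(n, -1);
  int besti = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      if (ra[j] < ra[i] && rb[j] < rb[i] &&
          ra[i] - ra[j] <= max_gap && rb[i] - rb[j] <= max_gap) {
        if (best[j] + 1 > best[i]) {
          best[i] = best[j] + 1;
          prev[i] = j;
        }
      }
    }
    if (best[i] > best[besti]) besti = i;
  }
  std::vector<int> chain;
  for (int k = besti; k >= 0; k = prev[k]) chain.push_back(k + 1);
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}
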