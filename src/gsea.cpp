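// Permutation kernel for pre-ranked GSEA.
//
// The enrichment score for a hit set is the signed extreme deviation of
// the running sum that adds |s|^w / (total hit weight) at hits and
// subtracts 1/(M - m) at misses, walking the ranking from top to bottom.
// Extremes can only occur immediately before or after a hit, so the score
// of one hit placement costs O(m) given sorted hit positions. The null
// draws uniform m-subsets of 1..M with R's RNG (partial Fisher-Yates), so
// results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// w: weights in ranking order (length M); hits: sorted 0-based positions.
static double es_walk(const NumericVector& w, const std::vector<int>& hits,
                      const double* wcum_unused) {
  const int M = w.size();
  const int m = hits.size();
  const double miss = 1.0 / (double)(M - m);
  double W = 0.0;
  for (int t = 0; t < m; ++t) W += w[hits[t]];
  const bool unit = (W <= 0.0);  // all hit weights zero: classic (unweighted) steps
  if (unit) W = (double)m;
  double cum = 0.0, maxdev = R_NegInf, mindev = R_PosInf;
  for (int t = 0; t < m; ++t) {
    const int r = hits[t];            // 0-based rank of the t-th hit
    const double misses_before = (double)(r - t);
    const double pre = cum / W - misses_before * miss;
    if (pre < mindev) mindev = pre;
    cum += unit ? 1.0 : w[r];
    const double post = cum / W - misses_before * miss;
    if (post > maxdev) maxdev = post;
  }
  // the running sum returns to 0 at the end; 0 bounds both extremes
  if (maxdev < 0.0) maxdev = 0.0;
  if (mindev > 0.0) mindev = 0.0;
  return (maxdev >= -mindev) ? maxdev : mindev;
}

// [[Rcpp::export]]
double cpp_gsea_es(NumericVector w, IntegerVector hits1) {
  std::vector<int> hits(hits1.size());
  for (int t = 0; t < hits1.size(); ++t) hits[t] = hits1[t] - 1;
  std::sort(hits.begin(), hits.end());
  return es_walk(w, hits, nullptr);
}

// Count permutations whose ES reaches es_obs (>=). Returns the count for B
// uniform random hit placements of size m among M ranks.
// [[Rcpp::export]]
int cpp_gsea_null_count(NumericVector w, int m, int B, double es_obs) {
  const int M = w.size();
  std::vector<int> idx(M);
  for (int i = 0; i < M; ++i) idx[i] = i;
  std::vector<int> hits(m);
  int count = 0;
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < m; ++t) {
      int j = t + (int)(unif_rand() * (double)(M - t));
      if (j >= M) j = M - 1;
      std::swap(idx[t], idx[j]);
    }
    hits.assign(idx.begin(), idx.begin() + m);
    std::sort(hits.begin(), hits.end());
    if (es_walk(w, hits, nullptr) >= es_obs) ++count;
  }
  return count;
}
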