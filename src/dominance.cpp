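#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Fenwick (binary indexed) tree over 1..n holding insertion counts.
static inline void bit_add(std::vector<int>& bit, int i) {
  for (; i <= (int)bit.size() - 1; i += i & (-i)) bit[i]++;
}
static inline int bit_sum(const std::vector<int>& bit, int i) {
  int s = 0;
  for (; i > 0; i -= i & (-i)) s += bit[i];
  return s;
}

// For each point i, the number of points j (including i itself) with
// z[j] >= z[i] AND t[j] >= t[i].  Plane sweep in decreasing z with a
// Fenwick tree over dense t-ranks; groups of tied z are inserted before
// any of their members is queried so that equality counts as dominance.
// O(n log n); the all-pairs scan used as the oracle in tests is O(n^2).
// [[Rcpp::export]]
IntegerVector dominance_counts(NumericVector z, NumericVector t) {
  const int n = z.size();
  if (t.size() != n) stop("z and t must have equal length");
  IntegerVector out(n);
  if (n == 0) return out;

  // dense ascending ranks of t (ties share a rank)
  std::vector<int> idx(n), trank(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return t[a] < t[b]; });
  int r = 0;
  for (int k = 0; k < n; ++k) {
    if (k > 0 && t[idx[k]] > t[idx[k - 1]]) ++r;
    trank[idx[k]] = r + 1;  // 1-based
  }
  const int nrank = r + 1;

  // order of decreasing z
  std::vector<int> zord(n);
  for (int i = 0; i < n; ++i) zord[i] = i;
  std::sort(zord.begin(), zord.end(),
            [&](int a, int b) { return z[a] > z[b]; });

  std::vector<int> bit(nrank + 1, 0);
  int inserted = 0;
  int k = 0;
  while (k < n) {
    int g = k;  // [k, g) = group of equal z
    while (g < n && z[zord[g]] == z[zord[k]]) ++g;
    for (int j = k; j < g; ++j) {
      bit_add(bit, trank[zord[j]]);
      ++inserted;
    }
    for (int j = k; j < g; ++j) {
      int i = zord[j];
      out[i] = inserted - bit_sum(bit, trank[i] - 1);
    }
    k = g;
  }
  return out;
}
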