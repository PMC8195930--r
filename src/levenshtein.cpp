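#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// Full unit-cost edit distance, two-row dynamic programme.
static int lev_full(const char *a, int la, const char *b, int lb) {
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Banded variant: returns the distance if <= k, otherwise any value > k.
// Only cells with |i - j| <= k can lie on a path of cost <= k, so the
// DP is restricted to a diagonal band of width 2k + 1.
static int lev_bounded(const char *a, int la, const char *b, int lb, int k) {
  if (std::abs(la - lb) > k) return k + 1;
  if (la == 0) return lb;
  if (lb == 0) return la;
  const int BIG = k + 1;
  std::vector<int> prev(lb + 1, BIG), cur(lb + 1, BIG);
  for (int j = 0; j <= std::min(lb, k); ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - k), jhi = std::min(lb, i + k);
    cur[jlo - 1] = (i - k <= 0) ? i : BIG;
    int rowmin = cur[jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      int del = (j <= i + k - 1) ? prev[j] + 1 : BIG;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
      if (cur[j] > BIG) cur[j] = BIG;
      rowmin = std::min(rowmin, cur[j]);
    }
    if (jhi < lb) cur[jhi + 1 > lb ? lb : jhi + 1] = BIG;
    if (rowmin > k) return BIG;  // early abandon: whole band exceeds k
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), BIG);
  }
  return prev[lb];
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1)
    stop("lengths of a and b must match or be 1");
  if (b.size() != n && b.size() != 1)
    stop("lengths of a and b must match or be 1");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, a.size() == 1 ? 0 : i));
    const char *sb = CHAR(STRING_ELT(b, b.size() == 1 ? 0 : i));
    out[i] = lev_full(sa, std::strlen(sa), sb, std::strlen(sb));
  }
  return out;
}

// All unordered pairs (i, j), i < j, with distance <= max_dist.
// Sequences are bucketed by length so that pairs whose length difference
// already exceeds max_dist are never compared.
// [[Rcpp::export]]
DataFrame cpp_bounded_pairs(CharacterVector seqs, int max_dist) {
  int n = seqs.size();
  std::vector<const char *> s(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    s[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = std::strlen(s[i]);
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int x, int y) { return len[x] < len[y]; });

  std::vector<int> ii, jj, dd;
  for (int a = 0; a < n; ++a) {
    int i = order[a];
    for (int b = a + 1; b < n; ++b) {
      int j = order[b];
      if (len[j] - len[i] > max_dist) break;  // sorted by length
      int d = lev_bounded(s[i], len[i], s[j], len[j], max_dist);
      if (d <= max_dist) {
        ii.push_back(std::min(i, j) + 1);
        jj.push_back(std::max(i, j) + 1);
        dd.push_back(d);
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}
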