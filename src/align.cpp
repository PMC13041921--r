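#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with optional banding.
// Scores: match +1, mismatch -1, gap -2 (linear). Identity is computed
// over all aligned columns, gap columns included.
//
// band <= 0 requests the full DP matrix; band > 0 restricts the search to
// diagonals within `band` of the main diagonal (suitable for pre-anchored
// pairs where the net indel offset is small).

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, int band = 0) {
  const int n = a.size(), m = b.size();
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  const int NEG = -1000000000;

  if (n == 0 || m == 0) stop("empty sequence in alignment");
  if (band > 0 && std::abs(n - m) > band)
    band = std::abs(n - m) + band; // widen so the corner is reachable

  // DP over rows of b-index; traceback matrix stored as bytes.
  // 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> prev(m + 1, NEG), cur(m + 1, NEG);

  int lo0 = 0, hi0 = m;
  if (band > 0) hi0 = std::min(m, band);
  for (int j = 0; j <= hi0; ++j) { prev[j] = GAP * j; if (j) tb[j] = 2; }

  for (int i = 1; i <= n; ++i) {
    int lo = 0, hi = m;
    if (band > 0) { lo = std::max(0, i - band); hi = std::min(m, i + band); }
    std::fill(cur.begin(), cur.end(), NEG);
    if (lo == 0) { cur[0] = GAP * i; tb[(size_t)i * (m + 1)] = 1; }
    for (int j = std::max(1, lo); j <= hi; ++j) {
      int sdiag = (prev[j - 1] == NEG) ? NEG
        : prev[j - 1] + ((a[i - 1] == b[j - 1]) ? MATCH : MISMATCH);
      int sup   = (prev[j] == NEG) ? NEG : prev[j] + GAP;
      int sleft = (cur[j - 1] == NEG) ? NEG : cur[j - 1] + GAP;
      int best = sdiag; unsigned char t = 0;
      if (sup > best)   { best = sup;   t = 1; }
      if (sleft > best) { best = sleft; t = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  if (score <= NEG / 2) stop("band too narrow for alignment");

  // traceback
  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  int matches = 0;
  const int cols = aa.size();
  for (int c = 0; c < cols; ++c) if (aa[c] == bb[c]) ++matches;

  return List::create(
    _["a_aln"] = aa, _["b_aln"] = bb, _["score"] = score,
    _["matches"] = matches, _["columns"] = cols,
    _["identity"] = cols ? (double)matches / cols : 0.0);
}

// Tally recurrence intervals between consecutive occurrences of identical
// k-mers. `starts` carries, for each k-mer occurring >= 2 times, the sorted
// 1-based start positions grouped contiguously; `group` marks group ids.
// Returns counts per interval length in [1, max_period].

// [[Rcpp::export(name = ".interval_tally_cpp")]]
IntegerVector interval_tally_cpp(IntegerVector starts, IntegerVector group,
                                 int max_period) {
  IntegerVector out(max_period);
  const int n = starts.size();
  for (int i = 1; i < n; ++i) {
    if (group[i] != group[i - 1]) continue;
    int d = starts[i] - starts[i - 1];
    if (d >= 1 && d <= max_period) out[d - 1]++;
  }
  return out;
}
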