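#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Fitting ("semi-global") alignment: the whole read is placed somewhere inside
// the reference; edits = substitutions + indels, unit cost each. Returns the
// placement with the fewest edits (ties: fewest mismatches, then leftmost end).

static inline char canon(char c) {
  if (c == 'u') c = 'U';
  if (c == 'U') return 'T';
  return (char) toupper(c);
}

// [[Rcpp::export(name = ".fit_align_cpp")]]
List fit_align_cpp(std::string read, std::string ref, bool gapped) {
  int m = (int) read.size(), n = (int) ref.size();
  for (int i = 0; i < m; ++i) read[i] = canon(read[i]);
  for (int j = 0; j < n; ++j) ref[j] = canon(ref[j]);

  if (m == 0 || n == 0)
    return List::create(_["edits"] = NA_INTEGER);

  if (!gapped) {
    // slide the full read over every offset; substitutions only
    if (m > n) return List::create(_["edits"] = NA_INTEGER);
    int best = m + 1, best_start = -1;
    for (int off = 0; off + m <= n; ++off) {
      int mm = 0;
      for (int i = 0; i < m && mm < best; ++i)
        if (read[i] != ref[off + i]) ++mm;
      if (mm < best) { best = mm; best_start = off; }
    }
    return List::create(_["edits"] = best, _["mismatches"] = best,
                        _["gaps"] = 0,
                        _["start"] = best_start + 1, _["end"] = best_start + m);
  }

  // DP over read rows; free leading/trailing gaps in the reference only.
  // dp[i][j] = min edits aligning read[0..i) to a suffix of ref[..j) that
  // starts anywhere (row 0 = 0 everywhere).
  std::vector<std::vector<int> > dp(m + 1, std::vector<int>(n + 1, 0));
  for (int i = 1; i <= m; ++i) {
    dp[i][0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = dp[i - 1][j - 1] + (read[i - 1] == ref[j - 1] ? 0 : 1);
      int del = dp[i][j - 1] + 1;  // gap in read (ref base skipped)
      int ins = dp[i - 1][j] + 1;  // gap in ref (read base inserted)
      int v = sub;
      if (del < v) v = del;
      if (ins < v) v = ins;
      dp[i][j] = v;
    }
  }
  int best = dp[m][0], best_end = 0;
  for (int j = 1; j <= n; ++j)
    if (dp[m][j] < best) { best = dp[m][j]; best_end = j; }

  // traceback from (m, best_end) counting mismatches and gaps
  int i = m, j = best_end, mism = 0, gaps = 0;
  while (i > 0) {
    if (j > 0 && dp[i][j] == dp[i - 1][j - 1] +
        (read[i - 1] == ref[j - 1] ? 0 : 1)) {
      if (read[i - 1] != ref[j - 1]) ++mism;
      --i; --j;
    } else if (j > 0 && dp[i][j] == dp[i][j - 1] + 1) {
      ++gaps; --j;
    } else {
      ++gaps; --i;
    }
  }
  return List::create(_["edits"] = best, _["mismatches"] = mism,
                      _["gaps"] = gaps,
                      _["start"] = j + 1, _["end"] = best_end);
}
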