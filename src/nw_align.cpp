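#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment score over unit columns.
//
// a, b: integer matrices whose columns are alignment units; a unit pair is
// scored as the sum over rows of match/mismatch.  Nucleotide scoring uses
// 1-row matrices; codon-unit scoring uses 3-row matrices, so both scores
// share a per-nucleotide scale.  The gap cost applies per unit column.
// [[Rcpp::export(name = ".nw_score_c")]]
double nw_score_c(IntegerMatrix a, IntegerMatrix b,
                  double match, double mismatch, double gap) {
  const int n = a.ncol(), m = b.ncol(), r = a.nrow();
  if (r != b.nrow()) stop("unit sizes differ");
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= m; ++j) {
      double sub = 0.0;
      for (int k = 0; k < r; ++k)
        sub += (a(k, i - 1) == b(k, j - 1)) ? match : mismatch;
      double best = prev[j - 1] + sub;
      if (prev[j] + gap > best) best = prev[j] + gap;
      if (cur[j - 1] + gap > best) best = cur[j - 1] + gap;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
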