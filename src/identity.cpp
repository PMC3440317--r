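#include <Rcpp.h>

using namespace Rcpp;

// Pairwise identity counts between equal-length peptides given as an
// n x L integer matrix (residue codes). Entry (i,j) is the number of
// positions at which peptides i and j carry the same residue.
// [[Rcpp::export]]
IntegerMatrix pairwise_match_counts(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = L;
    for (int j = i + 1; j < n; ++j) {
      int m = 0;
      for (int p = 0; p < L; ++p)
        if (seqs(i, p) == seqs(j, p)) ++m;
      out(i, j) = m;
      out(j, i) = m;
    }
  }
  return out;
}
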