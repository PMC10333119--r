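#include <Rcpp.h>
using namespace Rcpp;

// Uncorrected pairwise p-distances with pairwise deletion.
// Positions where either sequence carries a gap ('-') or an ambiguous
// base (anything other than A/C/G/T) are excluded from the comparison.
// Pairs with fewer than min_overlap compared positions get NA.

static inline bool is_valid(char c) {
  switch (c) {
  case 'A': case 'C': case 'G': case 'T':
  case 'a': case 'c': case 'g': case 't':
    return true;
  default:
    return false;
  }
}

static inline char upcase(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

// [[Rcpp::export(name = ".pdist_matrix_cpp")]]
NumericMatrix pdist_matrix_cpp(CharacterVector seqs, int min_overlap) {
  const int n = seqs.size();
  if (n == 0) return NumericMatrix(0, 0);
  const int len = LENGTH(STRING_ELT(seqs, 0));
  std::vector<const char*> ptr(n);
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(seqs, i);
    if (LENGTH(s) != len)
      stop("all sequences must have equal aligned length");
    ptr[i] = CHAR(s);
  }
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const char *a = ptr[i], *b = ptr[j];
      int compared = 0, mism = 0;
      for (int k = 0; k < len; ++k) {
        const char ca = a[k], cb = b[k];
        if (!is_valid(ca) || !is_valid(cb)) continue;
        ++compared;
        if (upcase(ca) != upcase(cb)) ++mism;
      }
      double val = (compared < min_overlap)
        ? NA_REAL
        : static_cast<double>(mism) / static_cast<double>(compared);
      d(i, j) = val;
      d(j, i) = val;
    }
  }
  return d;
}
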