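#include <Rcpp.h>
using namespace Rcpp;

// Tabular-method numerator relationship matrix. sire/dam are 1-based row
// indices into the topologically ordered pedigree, 0 for unknown.
// [[Rcpp::export(name = ".tabularA")]]
NumericMatrix tabularA(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s > 0) v += A(j, s - 1);
      if (d > 0) v += A(j, d - 1);
      v *= 0.5;
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + ((s > 0 && d > 0) ? 0.5 * A(s - 1, d - 1) : 0.0);
  }
  return A;
}
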