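#include <Rcpp.h>
using namespace Rcpp;

// Numerator relationship matrix (2x kinship) by the tabular method.
// father/mother are 1-based indices into the (already topologically
// sorted) individual vector, 0 for unknown/founder.  Requires parents
// to precede children; the R wrapper guarantees this.
// [[Rcpp::export(name = ".nrmTabular")]]
NumericMatrix nrmTabular(IntegerVector father, IntegerVector mother) {
  int n = father.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int f = father[i], m = mother[i];
    if (f > i || m > i)
      stop("parents must precede children (individual %d)", i + 1);
    // diagonal: 1 + inbreeding coefficient
    if (f > 0 && m > 0)
      A(i, i) = 1.0 + 0.5 * A(f - 1, m - 1);
    else
      A(i, i) = 1.0;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (f > 0) a += 0.5 * A(j, f - 1);
      if (m > 0) a += 0.5 * A(j, m - 1);
      A(i, j) = a;
      A(j, i) = a;
    }
  }
  return A;
}
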