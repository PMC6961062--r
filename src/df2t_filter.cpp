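#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// b, a: coefficients padded to equal length n, a[0] == 1.
// zi: initial state of length n - 1 (may be all zeros).
// Returns the filtered signal; the final state is attached as attribute "zf".
// [[Rcpp::export]]
NumericVector df2t_filter(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  int n = b.size();
  int m = x.size();
  NumericVector y(m);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < m; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (n > 1 ? z[0] : 0.0);
    for (int j = 0; j < n - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (n > 1)
      z[n - 2] = b[n - 1] * xi - a[n - 1] * yi;
    y[i] = yi;
  }
  y.attr("zf") = NumericVector(z.begin(), z.end());
  return y;
}
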