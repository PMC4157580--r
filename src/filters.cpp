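#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, a[0] assumed 1 (signal::butter
// returns normalized coefficients). Single pass; zero initial conditions.
// [[Rcpp::export(name = ".iirFilter")]]
NumericVector iirFilter(NumericVector b, NumericVector a, NumericVector x) {
  int n = x.size(), nb = b.size(), na = a.size();
  int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; i++) {
    double yi = b[0] * x[i] + w[0];
    for (int j = 1; j < nw; j++) {
      double bj = (j < nb) ? b[j] : 0.0;
      double aj = (j < na) ? a[j] : 0.0;
      w[j - 1] = bj * x[i] - aj * yi + ((j < nw - 1) ? w[j] : 0.0);
    }
    y[i] = yi;
  }
  return y;
}
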