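#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter; a[0] must be 1 (coefficients are
// normalised on the R side). Used by the zero-phase filtering wrapper.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  const int nb = b.size();
  const int na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j) {
      const double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
      const double aj = (j + 1 < na) ? a[j + 1] : 0.0;
      z[j] = bj * xi + z[j + 1] - aj * yi;
    }
    if (nz > 0) {
      const double bl = (nz < nb) ? b[nz] : 0.0;
      const double al = (nz < na) ? a[nz] : 0.0;
      z[nz - 1] = bl * xi - al * yi;
    }
    y[i] = yi;
  }
  return y;
}
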