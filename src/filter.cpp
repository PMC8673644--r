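#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit state, so that audio can
// be filtered chunk by chunk with bit-identical results to a single pass over
// the whole file. a[0] must be 1 (coefficients from signal::butter are
// already normalised).
//
// state zi has length max(len(a), len(b)) - 1; pass zeros for a cold start.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
List iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                    NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  if (zi.size() != nz) stop("filter state has wrong length");
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(zi.begin(), zi.end());
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}
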