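#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit initial state.
// b, a: transfer-function coefficients (a[0] must be 1 after normalisation);
// zi: initial conditions of length max(len(a), len(b)) - 1.
// [[Rcpp::export(name = ".iir_df2t")]]
NumericVector iir_df2t(NumericVector b, NumericVector a, NumericVector x,
                       NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (aa[0] == 0.0) stop("leading denominator coefficient is zero");
  for (int i = 0; i < n; ++i) { bb[i] /= aa[0]; }
  for (int i = n - 1; i >= 0; --i) aa[i] /= aa[0];

  int nz = n - 1;
  if (zi.size() != nz) stop("zi must have length %d", nz);
  std::vector<double> z(zi.begin(), zi.end());

  int nx = x.size();
  NumericVector y(nx);
  for (int t = 0; t < nx; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}
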