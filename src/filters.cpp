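#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length
// max(length(a), length(b)) - 1). Coefficients must be normalized (a[0] == 1).
// Mirrors the classic lfilter contract so that zero-phase filtering can seed
// the state with the steady-state step response.
// [[Rcpp::export(name = ".lfilter_cpp")]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  int n = x.size();
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nfilt - 1, 0.0);
  if (zi.size() == (R_xlen_t)(nfilt - 1))
    for (int i = 0; i < nfilt - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + (nfilt > 1 ? z[0] : 0.0);
    for (int i = 0; i < nfilt - 2; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    if (nfilt > 1)
      z[nfilt - 2] = bb[nfilt - 1] * xm - aa[nfilt - 1] * ym;
    y[m] = ym;
  }
  return y;
}
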