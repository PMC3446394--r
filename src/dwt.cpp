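#include <Rcpp.h>
using namespace Rcpp;

// One level of the separable periodized 2-D wavelet transform.
// Both input dimensions must be even. y[k] = sum_m f[m] x[(2k + m) mod N]
// along each axis, for the low- and high-pass filters.
// [[Rcpp::export]]
List dwt2_level_cpp(NumericMatrix x, NumericVector lo, NumericVector hi) {
  const int nr = x.nrow(), nc = x.ncol(), L = lo.size();
  const int hr = nr / 2, hc = nc / 2;
  NumericMatrix A(hr, nc), D(hr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int k = 0; k < hr; ++k) {
      double a = 0.0, d = 0.0;
      for (int m = 0; m < L; ++m) {
        const double v = x((2 * k + m) % nr, c);
        a += lo[m] * v;
        d += hi[m] * v;
      }
      A(k, c) = a;
      D(k, c) = d;
    }
  }
  NumericMatrix LL(hr, hc), LH(hr, hc), HL(hr, hc), HH(hr, hc);
  for (int k = 0; k < hc; ++k) {
    for (int r = 0; r < hr; ++r) {
      double ll = 0.0, lh = 0.0, hl = 0.0, hh = 0.0;
      for (int m = 0; m < L; ++m) {
        const int cc = (2 * k + m) % nc;
        ll += lo[m] * A(r, cc);
        lh += hi[m] * A(r, cc);
        hl += lo[m] * D(r, cc);
        hh += hi[m] * D(r, cc);
      }
      LL(r, k) = ll;
      LH(r, k) = lh;
      HL(r, k) = hl;
      HH(r, k) = hh;
    }
  }
  return List::create(_["LL"] = LL, _["LH"] = LH, _["HL"] = HL, _["HH"] = HH);
}
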