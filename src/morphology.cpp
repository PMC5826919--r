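#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat (ball) structuring element.
// Offsets (dx, dy) index columns/rows; h gives the element height at each
// offset. Offsets falling outside the image are ignored, so the operators
// are defined up to the frame edge.
//
// Loop order: offsets outermost, pixels innermost down columns, so each
// offset is one contiguous shifted-block pass over the image.

// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix img, IntegerVector dx,
                             IntegerVector dy, NumericVector h,
                             bool dilate) {
  const int nr = img.nrow(), nc = img.ncol(), no = dx.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), dilate ? R_NegInf : R_PosInf);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int o = 0; o < no; ++o) {
    const int ox = dx[o], oy = dy[o];
    const double ho = h[o];
    const int c0 = std::max(0, -ox), c1 = std::min(nc, nc - ox);
    const int r0 = std::max(0, -oy), r1 = std::min(nr, nr - oy);
    for (int c = c0; c < c1; ++c) {
      const double* s = src + (size_t)(c + ox) * nr + (r0 + oy);
      double* d = dst + (size_t)c * nr + r0;
      const int len = r1 - r0;
      if (dilate) {
        for (int i = 0; i < len; ++i) {
          const double v = s[i] + ho;
          if (v > d[i]) d[i] = v;
        }
      } else {
        for (int i = 0; i < len; ++i) {
          const double v = s[i] - ho;
          if (v < d[i]) d[i] = v;
        }
      }
    }
  }
  return out;
}
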