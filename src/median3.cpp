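#include <Rcpp.h>
#include <algorithm>

using namespace Rcpp;

// 3x3 median filter with replicated edges. Works on one image plane.
// [[Rcpp::export(name = ".median3x3_cpp")]]
NumericMatrix median3x3_cpp(const NumericMatrix& m) {
  const int h = m.nrow(), w = m.ncol();
  NumericMatrix out(h, w);
  double v[9];
  for (int j = 0; j < w; ++j) {
    const int jm = j > 0 ? j - 1 : 0;
    const int jp = j < w - 1 ? j + 1 : w - 1;
    for (int i = 0; i < h; ++i) {
      const int im = i > 0 ? i - 1 : 0;
      const int ip = i < h - 1 ? i + 1 : h - 1;
      v[0] = m(im, jm); v[1] = m(im, j); v[2] = m(im, jp);
      v[3] = m(i, jm);  v[4] = m(i, j);  v[5] = m(i, jp);
      v[6] = m(ip, jm); v[7] = m(ip, j); v[8] = m(ip, jp);
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  }
  return out;
}
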