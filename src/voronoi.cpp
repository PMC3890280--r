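#include <Rcpp.h>
using namespace Rcpp;

// Nearest and second-nearest seed for every pixel of an h x w raster
// (column-major), squared Euclidean distances. The workhorse behind the
// Voronoi fiber tessellation; the interstitial border is carved where the
// two distances nearly tie.
// [[Rcpp::export(name = ".voronoi_nearest2")]]
List voronoi_nearest2(NumericVector cx, NumericVector cy, int w, int h) {
  const int n = cx.size();
  const R_xlen_t npx = (R_xlen_t)w * h;
  IntegerVector lab(npx);
  NumericVector d1(npx), d2(npx);
  for (int x = 0; x < w; ++x) {
    const double px = x + 1.0;
    for (int y = 0; y < h; ++y) {
      const double py = y + 1.0;
      double b1 = R_PosInf, b2 = R_PosInf;
      int bl = 0;
      for (int k = 0; k < n; ++k) {
        const double dx = px - cx[k], dy = py - cy[k];
        const double d = dx * dx + dy * dy;
        if (d < b1) {
          b2 = b1; b1 = d; bl = k + 1;
        } else if (d < b2) {
          b2 = d;
        }
      }
      const R_xlen_t i = (R_xlen_t)x * h + y;
      lab[i] = bl; d1[i] = b1; d2[i] = b2;
    }
  }
  return List::create(_["label"] = lab, _["d1"] = d1, _["d2"] = d2);
}
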