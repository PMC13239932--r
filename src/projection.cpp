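#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of img at fractional (row, col), 0-based; outside -> 0.
static inline double bilinear0(const NumericMatrix& img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return 0.0;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : nr - 1;
  int c1 = c0 + 1 < nc ? c0 + 1 : nc - 1;
  double fr = r - r0, fc = c - c0;
  return img(r0, c0) * (1.0 - fr) * (1.0 - fc) + img(r1, c0) * fr * (1.0 - fc) +
         img(r0, c1) * (1.0 - fr) * fc        + img(r1, c1) * fr * fc;
}

// Parallel-beam forward projection (Radon transform) of one slice.
// angles in radians over [0, pi); detector spacing equals pixel spacing;
// rotation centre is the image centre; line integrals in units of
// attenuation * mm (spacing is mm/voxel).
// [[Rcpp::export]]
NumericMatrix cppForwardProject(NumericMatrix img, NumericVector angles,
                                double spacing, int nDet, double step) {
  const int nAng = angles.size();
  NumericMatrix sino(nDet, nAng);
  const double cr = (img.nrow() - 1) / 2.0;
  const double cc = (img.ncol() - 1) / 2.0;
  const double half = 0.5 * std::sqrt((double)img.nrow() * img.nrow() +
                                      (double)img.ncol() * img.ncol()) * spacing;
  const int nStep = (int)std::ceil(2.0 * half / step);
  const double dOff = (nDet - 1) / 2.0;
  for (int a = 0; a < nAng; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int d = 0; d < nDet; ++d) {
      const double t = (d - dOff) * spacing;
      double acc = 0.0;
      for (int s = 0; s <= nStep; ++s) {
        const double l = -half + s * step;
        // physical axes: x along +col, y along +row
        const double x = t * ct - l * st;
        const double y = t * st + l * ct;
        acc += bilinear0(img, cr + y / spacing, cc + x / spacing);
      }
      sino(d, a) = acc * step;
    }
  }
  return sino;
}

// Backprojection of a (ramp-filtered) sinogram onto an nRow x nCol grid,
// scaled by pi / nAngles so that filter + backprojection inverts
// cppForwardProject.
// [[Rcpp::export]]
NumericMatrix cppBackProject(NumericMatrix sino, NumericVector angles,
                             int nRow, int nCol, double spacing) {
  const int nDet = sino.nrow(), nAng = angles.size();
  NumericMatrix img(nRow, nCol);
  const double cr = (nRow - 1) / 2.0, cc = (nCol - 1) / 2.0;
  const double dOff = (nDet - 1) / 2.0;
  for (int a = 0; a < nAng; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < nCol; ++j) {
      const double x = (j - cc) * spacing;
      for (int i = 0; i < nRow; ++i) {
        const double y = (i - cr) * spacing;
        const double d = (x * ct + y * st) / spacing + dOff;
        if (d < 0.0 || d > nDet - 1.0) continue;
        const int d0 = (int)std::floor(d);
        const int d1 = d0 + 1 < nDet ? d0 + 1 : nDet - 1;
        const double f = d - d0;
        img(i, j) += sino(d0, a) * (1.0 - f) + sino(d1, a) * f;
      }
    }
  }
  const double scale = M_PI / nAng;
  for (R_xlen_t k = 0; k < (R_xlen_t)nRow * nCol; ++k) img[k] *= scale;
  return img;
}
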