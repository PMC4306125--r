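#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline basis, index m in 0..3, local fraction u in [0,1).
static inline double bsp(int m, double u) {
  switch (m) {
  case 0: { double w = 1.0 - u; return w * w * w / 6.0; }
  case 1: return (3.0 * u * u * u - 6.0 * u * u + 4.0) / 6.0;
  case 2: return (-3.0 * u * u * u + 3.0 * u * u + 3.0 * u + 1.0) / 6.0;
  default: return u * u * u / 6.0;
  }
}

// Mirror (reflect-without-repeat) index into 0..n-1.
static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// In-place interpolating B-spline prefilter along one line (Unser 1993),
// pole z = sqrt(3) - 2, mirror boundaries.
static void prefilter_line(double *c, int n) {
  if (n < 2) return;
  const double z = std::sqrt(3.0) - 2.0;
  const double gain = 6.0; // (1-z)(1-1/z)
  for (int k = 0; k < n; ++k) c[k] *= gain;
  // causal init: truncated sum of z^k * c[mirror(k)]
  double sum = c[0];
  double zk = z;
  const double tol = 1e-17;
  int horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
  if (horizon > 2 * n) horizon = 2 * n;
  for (int k = 1; k < horizon; ++k) {
    sum += zk * c[mirror_idx(k, n)];
    zk *= z;
  }
  c[0] = sum;
  for (int k = 1; k < n; ++k) c[k] += z * c[k - 1];
  // anticausal
  c[n - 1] = (z / (z * z - 1.0)) * (c[n - 1] + z * c[n - 2]);
  for (int k = n - 2; k >= 0; --k) c[k] = z * (c[k + 1] - c[k]);
}

// Prefilter an image (rows then columns) into B-spline coefficients.
// img(row, col): row indexes y, col indexes x.
// [[Rcpp::export(name = ".cpp_spline_coef")]]
NumericMatrix cpp_spline_coef(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(clone(img));
  std::vector<double> line(std::max(nr, nc));
  for (int r = 0; r < nr; ++r) { // along x
    for (int c = 0; c < nc; ++c) line[c] = out(r, c);
    prefilter_line(line.data(), nc);
    for (int c = 0; c < nc; ++c) out(r, c) = line[c];
  }
  for (int c = 0; c < nc; ++c) { // along y
    for (int r = 0; r < nr; ++r) line[r] = out(r, c);
    prefilter_line(line.data(), nr);
    for (int r = 0; r < nr; ++r) out(r, c) = line[r];
  }
  return out;
}

static inline double eval_spline(const NumericMatrix &coef, double x, double y) {
  const int nr = coef.nrow(), nc = coef.ncol();
  const double fx = std::floor(x), fy = std::floor(y);
  const double u = x - fx, v = y - fy;
  const int ix = (int)fx - 1, iy = (int)fy - 1;
  double wx[4], wy[4];
  for (int m = 0; m < 4; ++m) { wx[m] = bsp(m, u); wy[m] = bsp(m, v); }
  double acc = 0.0;
  for (int n = 0; n < 4; ++n) {
    const int rr = mirror_idx(iy + n, nr);
    double rowacc = 0.0;
    for (int m = 0; m < 4; ++m)
      rowacc += wx[m] * coef(rr, mirror_idx(ix + m, nc));
    acc += wy[n] * rowacc;
  }
  return acc;
}

// Evaluate the spline model at arbitrary (x, y), 0-based pixel coords
// (x along columns, y along rows). Coordinates outside the image are
// clamped to the border before evaluation; the caller masks them.
// [[Rcpp::export(name = ".cpp_spline_eval")]]
NumericVector cpp_spline_eval(NumericMatrix coef, NumericVector x, NumericVector y) {
  const int nr = coef.nrow(), nc = coef.ncol();
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    double xx = x[k], yy = y[k];
    if (xx < 0) xx = 0; else if (xx > nc - 1) xx = nc - 1;
    if (yy < 0) yy = 0; else if (yy > nr - 1) yy = nr - 1;
    out[k] = eval_spline(coef, xx, yy);
  }
  return out;
}

// Tensor-product cubic B-spline FFD displacement at (x, y).
// phi_x, phi_y: nx-by-ny control displacement lattices (row = x index).
// Out-of-support points yield NaN; the R wrapper raises the error.
// [[Rcpp::export(name = ".cpp_ffd_disp")]]
NumericMatrix cpp_ffd_disp(NumericMatrix phi_x, NumericMatrix phi_y,
                           NumericVector delta, NumericVector origin,
                           NumericVector x, NumericVector y) {
  const int nx = phi_x.nrow(), ny = phi_x.ncol();
  const R_xlen_t n = x.size();
  NumericMatrix out(n, 2);
  for (R_xlen_t k = 0; k < n; ++k) {
    const double sx = (x[k] - origin[0]) / delta[0];
    const double sy = (y[k] - origin[1]) / delta[1];
    const int i0 = (int)std::floor(sx) - 1;
    const int j0 = (int)std::floor(sy) - 1;
    if (i0 < 0 || j0 < 0 || i0 + 3 >= nx || j0 + 3 >= ny) {
      out(k, 0) = NA_REAL; out(k, 1) = NA_REAL; continue;
    }
    const double u = sx - std::floor(sx), v = sy - std::floor(sy);
    double wx[4], wy[4];
    for (int m = 0; m < 4; ++m) { wx[m] = bsp(m, u); wy[m] = bsp(m, v); }
    double dx = 0.0, dy = 0.0;
    for (int nn = 0; nn < 4; ++nn)
      for (int mm = 0; mm < 4; ++mm) {
        const double w = wx[mm] * wy[nn];
        dx += w * phi_x(i0 + mm, j0 + nn);
        dy += w * phi_y(i0 + mm, j0 + nn);
      }
    out(k, 0) = dx; out(k, 1) = dy;
  }
  return out;
}

// Central finite-difference gradient of the mean-SSD similarity with
// respect to every FFD control-point displacement.  For each pixel the
// warped coordinate is base (affine) + FFD displacement; perturbing a
// control point by +-h moves the coordinate by +-h * w where w is that
// pixel's tensor B-spline weight for the control point, so only target
// re-interpolation is needed (locality of the B-spline support).
// ref: reference image; coef: target spline coefficients;
// bx, by: affine-warped coordinates per pixel (same shape as ref).
// Returns nx*ny*2 gradient (x-lattice, y-lattice, axis).
// [[Rcpp::export(name = ".cpp_ffd_ssd_grad")]]
NumericVector cpp_ffd_ssd_grad(NumericMatrix ref, NumericMatrix coef,
                               NumericMatrix bx, NumericMatrix by,
                               NumericMatrix phi_x, NumericMatrix phi_y,
                               NumericVector delta, NumericVector origin,
                               double h) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const int nx = phi_x.nrow(), ny = phi_x.ncol();
  const int tnr = coef.nrow(), tnc = coef.ncol();
  NumericVector grad(nx * ny * 2);
  const double N = (double)(nr * nc);
  for (int c = 0; c < nc; ++c) {
    const double xpix = (double)c;
    for (int r = 0; r < nr; ++r) {
      const double ypix = (double)r;
      const double sx = (xpix - origin[0]) / delta[0];
      const double sy = (ypix - origin[1]) / delta[1];
      const int i0 = (int)std::floor(sx) - 1;
      const int j0 = (int)std::floor(sy) - 1;
      if (i0 < 0 || j0 < 0 || i0 + 3 >= nx || j0 + 3 >= ny) continue;
      const double u = sx - std::floor(sx), v = sy - std::floor(sy);
      double wx[4], wy[4];
      for (int m = 0; m < 4; ++m) { wx[m] = bsp(m, u); wy[m] = bsp(m, v); }
      double dx = 0.0, dy = 0.0;
      for (int nn = 0; nn < 4; ++nn)
        for (int mm = 0; mm < 4; ++mm) {
          const double w = wx[mm] * wy[nn];
          dx += w * phi_x(i0 + mm, j0 + nn);
          dy += w * phi_y(i0 + mm, j0 + nn);
        }
      const double wxc = bx(r, c) + dx;
      const double wyc = by(r, c) + dy;
      const double a = ref(r, c);
      for (int nn = 0; nn < 4; ++nn)
        for (int mm = 0; mm < 4; ++mm) {
          const double w = wx[mm] * wy[nn];
          if (w == 0.0) continue;
          const int ci = i0 + mm, cj = j0 + nn;
          // x axis
          double xp = wxc + h * w, xm = wxc - h * w, yy = wyc;
          double cx;
          {
            double x1 = xp < 0 ? 0 : (xp > tnc - 1 ? tnc - 1 : xp);
            double x2 = xm < 0 ? 0 : (xm > tnc - 1 ? tnc - 1 : xm);
            double y1 = yy < 0 ? 0 : (yy > tnr - 1 ? tnr - 1 : yy);
            double rp = a - eval_spline(coef, x1, y1);
            double rm = a - eval_spline(coef, x2, y1);
            cx = (rp * rp - rm * rm) / (2.0 * h);
          }
          grad[ci + nx * cj] += cx / N;
          // y axis
          double yp = wyc + h * w, ym = wyc - h * w;
          double cy;
          {
            double y1 = yp < 0 ? 0 : (yp > tnr - 1 ? tnr - 1 : yp);
            double y2 = ym < 0 ? 0 : (ym > tnr - 1 ? tnr - 1 : ym);
            double x1 = wxc < 0 ? 0 : (wxc > tnc - 1 ? tnc - 1 : wxc);
            double rp = a - eval_spline(coef, x1, y1);
            double rm = a - eval_spline(coef, x1, y2);
            cy = (rp * rp - rm * rm) / (2.0 * h);
          }
          grad[nx * ny + ci + nx * cj] += cy / N;
        }
    }
  }
  return grad;
}
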