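// Kaiser-Bessel gridding kernels for the non-Cartesian (3D-cones)
// acquisition model: type-2 interpolation (Cartesian spectrum -> arbitrary
// k-space samples) and its exact adjoint type-1 spreading, plus a separable
// Gaussian blur used for optional B1-map smoothing.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// modified Bessel function I0 (Abramowitz & Stegun 9.8.1/9.8.2)
static double bessel_i0(double x) {
  double ax = std::fabs(x);
  if (ax < 3.75) {
    double t = x / 3.75, y = t * t;
    return 1.0 + y * (3.5156229 + y * (3.0899424 + y * (1.2067492 +
           y * (0.2659732 + y * (0.0360768 + y * 0.0045813)))));
  }
  double t = 3.75 / ax;
  return (std::exp(ax) / std::sqrt(ax)) *
         (0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
          t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
          t * (-0.01647633 + t * 0.00392377))))))));
}

static inline double kb(double t, double halfw, double beta) {
  double u = t / halfw;
  double s = 1.0 - u * u;
  if (s < 0) return 0.0;
  return bessel_i0(beta * std::sqrt(s));
}

// Interpolate complex oversampled spectrum (G x G x G, DC at G/2, 0-based)
// at continuous grid positions u (n x 3) with periodic (wraparound)
// indexing, the natural topology of the oversampled FFT grid. width =
// kernel full width in grid samples.
// [[Rcpp::export(name = ".kbInterp")]]
ComplexVector kbInterp(ComplexVector grid, int G, NumericMatrix u,
                       double width, double beta) {
  int n = u.nrow();
  ComplexVector out(n);
  double halfw = width / 2.0;
  int w = (int)std::ceil(halfw);
  for (int s = 0; s < n; ++s) {
    double re = 0.0, im = 0.0;
    double ux = u(s, 0), uy = u(s, 1), uz = u(s, 2);
    int x0 = (int)std::floor(ux) - w, x1 = (int)std::floor(ux) + w + 1;
    int y0 = (int)std::floor(uy) - w, y1 = (int)std::floor(uy) + w + 1;
    int z0 = (int)std::floor(uz) - w, z1 = (int)std::floor(uz) + w + 1;
    for (int z = z0; z <= z1; ++z) {
      double wz = kb(z - uz, halfw, beta);
      if (wz == 0.0) continue;
      int zi = ((z % G) + G) % G;
      for (int y = y0; y <= y1; ++y) {
        double wy = kb(y - uy, halfw, beta) * wz;
        if (wy == 0.0) continue;
        int yi = ((y % G) + G) % G;
        R_xlen_t base = (R_xlen_t)zi * G * G + (R_xlen_t)yi * G;
        for (int x = x0; x <= x1; ++x) {
          double wx = kb(x - ux, halfw, beta) * wy;
          if (wx == 0.0) continue;
          int xi = ((x % G) + G) % G;
          Rcomplex g = grid[base + xi];
          re += wx * g.r;
          im += wx * g.i;
        }
      }
    }
    out[s].r = re;
    out[s].i = im;
  }
  return out;
}

// Exact adjoint of kbInterp: spread weighted samples onto the grid.
// [[Rcpp::export(name = ".kbSpread")]]
ComplexVector kbSpread(ComplexVector samples, int G, NumericMatrix u,
                       double width, double beta) {
  int n = u.nrow();
  ComplexVector grid((R_xlen_t)G * G * G);
  double halfw = width / 2.0;
  int w = (int)std::ceil(halfw);
  for (int s = 0; s < n; ++s) {
    double vr = samples[s].r, vi = samples[s].i;
    double ux = u(s, 0), uy = u(s, 1), uz = u(s, 2);
    int x0 = (int)std::floor(ux) - w, x1 = (int)std::floor(ux) + w + 1;
    int y0 = (int)std::floor(uy) - w, y1 = (int)std::floor(uy) + w + 1;
    int z0 = (int)std::floor(uz) - w, z1 = (int)std::floor(uz) + w + 1;
    for (int z = z0; z <= z1; ++z) {
      double wz = kb(z - uz, halfw, beta);
      if (wz == 0.0) continue;
      int zi = ((z % G) + G) % G;
      for (int y = y0; y <= y1; ++y) {
        double wy = kb(y - uy, halfw, beta) * wz;
        if (wy == 0.0) continue;
        int yi = ((y % G) + G) % G;
        R_xlen_t base = (R_xlen_t)zi * G * G + (R_xlen_t)yi * G;
        for (int x = x0; x <= x1; ++x) {
          double wx = kb(x - ux, halfw, beta) * wy;
          if (wx == 0.0) continue;
          int xi = ((x % G) + G) % G;
          grid[base + xi].r += wx * vr;
          grid[base + xi].i += wx * vi;
        }
      }
    }
  }
  return grid;
}

// Separable Gaussian blur of a 3D array (zero-padded borders handled by
// kernel renormalisation at the edges).
// [[Rcpp::export(name = ".gaussBlur3D")]]
NumericVector gaussBlur3D(NumericVector vol, IntegerVector dims, double sd) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = (int)std::ceil(3.0 * sd);
  std::vector<double> k(2 * r + 1);
  double ks = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sd * sd)); ks += k[i + r]; }
  for (double &v : k) v /= ks;
  NumericVector a = clone(vol), b((R_xlen_t)nx * ny * nz);
  // pass along each axis in turn
  for (int axis = 0; axis < 3; ++axis) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0, wacc = 0.0;
          for (int i = -r; i <= r; ++i) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx += i; else if (axis == 1) yy += i; else zz += i;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            double w = k[i + r];
            acc += w * a[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
            wacc += w;
          }
          b[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = wacc > 0 ? acc / wacc : 0.0;
        }
    std::swap(a, b);
  }
  return a;
}
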