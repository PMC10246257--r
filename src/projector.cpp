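#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joseph-style ray-driven projector over a stack of independent 2-D slices.
//
// Image layout: column-major (nx, ny, nz); voxel (i,j) centre sits at world
// (x0 + i*dx, y0 + j*dy). Sinogram layout: (n_angles, n_radial, n_slices).
// A ray for (angle th, radial offset S) passes through (S cos th, S sin th)
// with direction (-sin th, cos th); the axis of rotation is the world
// origin. Stepping is along the axis most orthogonal to the ray, with linear
// interpolation in the other coordinate; the per-step path length is
// dx/|ux| (resp. dy/|uy|), so each bin approximates the line integral in
// value * mm. The backprojector spreads with the identical weights, making
// the pair an exact adjoint up to floating-point rounding.

// [[Rcpp::export]]
NumericVector joseph_forward_cpp(NumericVector img, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector angles, int n_radial,
                                 double radial_spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1];
  const double x0 = origin[0], y0 = origin[1];
  const int na = angles.size(), nr = n_radial;
  NumericVector out(static_cast<R_xlen_t>(na) * nr * nz);
  const double s_first = -(nr - 1) / 2.0 * radial_spacing;

  for (int a = 0; a < na; ++a) {
    const double th = angles[a];
    const double c = std::cos(th), s = std::sin(th);
    const double ux = -s, uy = c;
    const bool drive_x = std::fabs(ux) >= std::fabs(uy);
    const double step = drive_x ? dx / std::fabs(ux) : dy / std::fabs(uy);
    for (int r = 0; r < nr; ++r) {
      const double S = s_first + r * radial_spacing;
      const double px = S * c, py = S * s;
      for (int z = 0; z < nz; ++z) {
        const double *im = &img[0] + static_cast<R_xlen_t>(nx) * ny * z;
        double acc = 0.0;
        if (drive_x) {
          for (int ix = 0; ix < nx; ++ix) {
            const double x = x0 + ix * dx;
            const double t = (x - px) / ux;
            const double fy = (py + t * uy - y0) / dy;
            const int j = static_cast<int>(std::floor(fy));
            const double w = fy - j;
            if (j >= 0 && j <= ny - 2)
              acc += im[ix + nx * j] * (1.0 - w) + im[ix + nx * (j + 1)] * w;
            else if (j == -1)
              acc += im[ix] * w;
            else if (j == ny - 1)
              acc += im[ix + nx * j] * (1.0 - w);
          }
        } else {
          for (int jy = 0; jy < ny; ++jy) {
            const double y = y0 + jy * dy;
            const double t = (y - py) / uy;
            const double fx = (px + t * ux - x0) / dx;
            const int i = static_cast<int>(std::floor(fx));
            const double w = fx - i;
            if (i >= 0 && i <= nx - 2)
              acc += im[i + nx * jy] * (1.0 - w) + im[i + 1 + nx * jy] * w;
            else if (i == -1)
              acc += im[nx * jy] * w;
            else if (i == nx - 1)
              acc += im[i + nx * jy] * (1.0 - w);
          }
        }
        out[a + static_cast<R_xlen_t>(na) * r +
            static_cast<R_xlen_t>(na) * nr * z] = acc * step;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector joseph_backward_cpp(NumericVector sino, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector angles, int n_radial,
                                  double radial_spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1];
  const double x0 = origin[0], y0 = origin[1];
  const int na = angles.size(), nr = n_radial;
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double s_first = -(nr - 1) / 2.0 * radial_spacing;

  for (int a = 0; a < na; ++a) {
    const double th = angles[a];
    const double c = std::cos(th), s = std::sin(th);
    const double ux = -s, uy = c;
    const bool drive_x = std::fabs(ux) >= std::fabs(uy);
    const double step = drive_x ? dx / std::fabs(ux) : dy / std::fabs(uy);
    for (int r = 0; r < nr; ++r) {
      const double S = s_first + r * radial_spacing;
      const double px = S * c, py = S * s;
      for (int z = 0; z < nz; ++z) {
        const double v = sino[a + static_cast<R_xlen_t>(na) * r +
                              static_cast<R_xlen_t>(na) * nr * z] * step;
        if (v == 0.0) continue;
        double *im = &out[0] + static_cast<R_xlen_t>(nx) * ny * z;
        if (drive_x) {
          for (int ix = 0; ix < nx; ++ix) {
            const double x = x0 + ix * dx;
            const double t = (x - px) / ux;
            const double fy = (py + t * uy - y0) / dy;
            const int j = static_cast<int>(std::floor(fy));
            const double w = fy - j;
            if (j >= 0 && j <= ny - 2) {
              im[ix + nx * j] += v * (1.0 - w);
              im[ix + nx * (j + 1)] += v * w;
            } else if (j == -1) {
              im[ix] += v * w;
            } else if (j == ny - 1) {
              im[ix + nx * j] += v * (1.0 - w);
            }
          }
        } else {
          for (int jy = 0; jy < ny; ++jy) {
            const double y = y0 + jy * dy;
            const double t = (y - py) / uy;
            const double fx = (px + t * ux - x0) / dx;
            const int i = static_cast<int>(std::floor(fx));
            const double w = fx - i;
            if (i >= 0 && i <= nx - 2) {
              im[i + nx * jy] += v * (1.0 - w);
              im[i + 1 + nx * jy] += v * w;
            } else if (i == -1) {
              im[nx * jy] += v * w;
            } else if (i == nx - 1) {
              im[i + nx * jy] += v * (1.0 - w);
            }
          }
        }
      }
    }
  }
  return out;
}
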