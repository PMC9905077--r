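#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Parallel-beam slice-wise projector pair. Rays are sampled at unit (voxel)
// steps with bilinear interpolation (Joseph-style); the backprojector uses
// the identical rays and weights, so the pair is an exact adjoint up to
// floating-point rounding. Lengths are in voxel units; the R wrappers apply
// the voxel size.

static inline void ray_setup(int nx, int ny, int ndet, double angle,
                             double& cx, double& cy, double& ux, double& uy,
                             double& dx, double& dy, double& tmax) {
  cx = (nx - 1) / 2.0;
  cy = (ny - 1) / 2.0;
  ux = std::cos(angle);
  uy = std::sin(angle); // detector axis
  dx = -uy;
  dy = ux; // ray direction
  tmax = std::sqrt((double)nx * nx + (double)ny * ny) / 2.0 + 1.0;
}

// volume: nx*ny*nz (x fastest); returns sinogram ndet x nangles x nz
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, int nx, int ny, int nz,
                                  NumericVector angles, int ndet,
                                  double step) {
  int na = angles.size();
  NumericVector out((R_xlen_t)ndet * na * nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    const double* sl = REAL(vol) + (R_xlen_t)z * nxy;
    for (int a = 0; a < na; ++a) {
      double cx, cy, ux, uy, dx, dy, tmax;
      ray_setup(nx, ny, ndet, angles[a], cx, cy, ux, uy, dx, dy, tmax);
      for (int idet = 0; idet < ndet; ++idet) {
        double s = idet - (ndet - 1) / 2.0;
        double px = cx + s * ux, py = cy + s * uy;
        double acc = 0.0;
        for (double t = -tmax; t <= tmax; t += step) {
          double x = px + t * dx, y = py + t * dy;
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
          if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) continue;
          double fx = x - x0, fy = y - y0;
          double v00 = (x0 >= 0 && y0 >= 0) ? sl[(R_xlen_t)y0 * nx + x0] : 0.0;
          double v10 = (x0 + 1 < nx && y0 >= 0) ? sl[(R_xlen_t)y0 * nx + x0 + 1] : 0.0;
          double v01 = (x0 >= 0 && y0 + 1 < ny) ? sl[(R_xlen_t)(y0 + 1) * nx + x0] : 0.0;
          double v11 = (x0 + 1 < nx && y0 + 1 < ny) ? sl[(R_xlen_t)(y0 + 1) * nx + x0 + 1] : 0.0;
          acc += (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                 (1 - fx) * fy * v01 + fx * fy * v11;
        }
        out[(R_xlen_t)z * ndet * na + (R_xlen_t)a * ndet + idet] = acc * step;
      }
    }
  }
  return out;
}

// sinogram: ndet x nangles x nz; returns volume nx*ny*nz
// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector sino, int nx, int ny, int nz,
                               NumericVector angles, int ndet, double step) {
  int na = angles.size();
  NumericVector out((R_xlen_t)nx * ny * nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    double* sl = REAL(out) + (R_xlen_t)z * nxy;
    for (int a = 0; a < na; ++a) {
      double cx, cy, ux, uy, dx, dy, tmax;
      ray_setup(nx, ny, ndet, angles[a], cx, cy, ux, uy, dx, dy, tmax);
      for (int idet = 0; idet < ndet; ++idet) {
        double val =
            sino[(R_xlen_t)z * ndet * na + (R_xlen_t)a * ndet + idet] * step;
        if (val == 0.0) continue;
        double s = idet - (ndet - 1) / 2.0;
        double px = cx + s * ux, py = cy + s * uy;
        for (double t = -tmax; t <= tmax; t += step) {
          double x = px + t * dx, y = py + t * dy;
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
          if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) continue;
          double fx = x - x0, fy = y - y0;
          if (x0 >= 0 && y0 >= 0) sl[(R_xlen_t)y0 * nx + x0] += (1 - fx) * (1 - fy) * val;
          if (x0 + 1 < nx && y0 >= 0) sl[(R_xlen_t)y0 * nx + x0 + 1] += fx * (1 - fy) * val;
          if (x0 >= 0 && y0 + 1 < ny) sl[(R_xlen_t)(y0 + 1) * nx + x0] += (1 - fx) * fy * val;
          if (x0 + 1 < nx && y0 + 1 < ny) sl[(R_xlen_t)(y0 + 1) * nx + x0 + 1] += fx * fy * val;
        }
      }
    }
  }
  return out;
}
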