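#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize a set of straight centreline segments into a voxel mask: a voxel
// is foreground iff its centre lies within `radius` (um) of any segment.
// Segments are rows (x0, y0, z0, x1, y1, z1) in um; the voxel (iz, iy, ix)
// has its centre at ((ix + 0.5) dx, (iy + 0.5) dy, (iz + 0.5) dz).
// Returns the mask with attribute "clipped" = TRUE if any segment endpoint
// fell outside the physical extent.

// [[Rcpp::export(name = ".rasterize_segments_cpp")]]
IntegerVector rasterize_segments_cpp(NumericMatrix segs, double radius,
                                     IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  IntegerVector out((R_xlen_t)nz * ny * nx);
  bool clipped = false;
  const double ext_x = nx * dx, ext_y = ny * dy, ext_z = nz * dz;
  for (int s = 0; s < segs.nrow(); ++s) {
    const double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    const double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    if (ax < 0 || ay < 0 || az < 0 || bx < 0 || by < 0 || bz < 0 ||
        ax > ext_x || ay > ext_y || az > ext_z ||
        bx > ext_x || by > ext_y || bz > ext_z)
      clipped = true;
    const double vx = bx - ax, vy = by - ay, vz = bz - az;
    const double vv = vx * vx + vy * vy + vz * vz;
    int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - radius) / dx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + radius) / dx));
    int y0 = std::max(0, (int)std::floor((std::min(ay, by) - radius) / dy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + radius) / dy));
    int z0 = std::max(0, (int)std::floor((std::min(az, bz) - radius) / dz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + radius) / dz));
    const double r2 = radius * radius;
    for (int ix = x0; ix <= x1; ++ix) {
      const double px = (ix + 0.5) * dx - ax;
      for (int iy = y0; iy <= y1; ++iy) {
        const double py = (iy + 0.5) * dy - ay;
        for (int iz = z0; iz <= z1; ++iz) {
          const double pz = (iz + 0.5) * dz - az;
          double t = vv > 0 ? (px * vx + py * vy + pz * vz) / vv : 0.0;
          t = std::max(0.0, std::min(1.0, t));
          const double ex = px - t * vx, ey = py - t * vy, ez = pz - t * vz;
          if (ex * ex + ey * ey + ez * ez <= r2)
            out[(R_xlen_t)iz + (R_xlen_t)nz * ((R_xlen_t)iy + (R_xlen_t)ny * ix)] = 1;
        }
      }
    }
  }
  out.attr("dim") = dims;
  out.attr("clipped") = clipped;
  return out;
}
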