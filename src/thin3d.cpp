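#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Voxel grids are R arrays with dim = c(nz, ny, nx): element (iz, iy, ix)
// lives at iz + nz * (iy + ny * ix), all indices 0-based.

namespace {

struct Grid {
  const int nz, ny, nx;
  std::vector<unsigned char> v;
  Grid(const IntegerVector &mask, const IntegerVector &dims)
      : nz(dims[0]), ny(dims[1]), nx(dims[2]), v(mask.size()) {
    for (R_xlen_t i = 0; i < mask.size(); ++i) v[i] = mask[i] != 0;
  }
  inline long idx(int z, int y, int x) const {
    return (long)z + (long)nz * ((long)y + (long)ny * (long)x);
  }
  inline bool at(int z, int y, int x) const {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return false;
    return v[idx(z, y, x)] != 0;
  }
};

// 3x3x3 neighbourhood as a flat length-27 cube, index = (dz+1) + 3*(dy+1) + 9*(dx+1).
inline int cidx(int dz, int dy, int dx) { return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1); }

void fill_cube(const Grid &g, int z, int y, int x, bool cube[27]) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz)
        cube[cidx(dz, dy, dx)] = g.at(z + dz, y + dy, x + dx);
}

inline void decode(int c, int &dz, int &dy, int &dx) {
  dz = c % 3 - 1; dy = (c / 3) % 3 - 1; dx = c / 9 - 1;
}

// Number of 26-connected components of foreground within N26 (centre excluded).
int fg_components26(const bool cube[27]) {
  bool seen[27] = {false};
  int comp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !cube[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int c = stack[--top];
      int dz, dy, dx; decode(c, dz, dy, dx);
      for (int c2 = 0; c2 < 27; ++c2) {
        if (c2 == 13 || seen[c2] || !cube[c2]) continue;
        int dz2, dy2, dx2; decode(c2, dz2, dy2, dx2);
        if (abs(dz - dz2) <= 1 && abs(dy - dy2) <= 1 && abs(dx - dx2) <= 1) {
          seen[c2] = true; stack[top++] = c2;
        }
      }
    }
  }
  return comp;
}

// Number of 6-connected components of background within N18 that touch a
// 6-neighbour of the centre (Malandain–Bertrand characterisation).
int bg_components6(const bool cube[27]) {
  bool in18[27], seen[27] = {false};
  for (int c = 0; c < 27; ++c) {
    int dz, dy, dx; decode(c, dz, dy, dx);
    in18[c] = (c != 13) && (abs(dz) + abs(dy) + abs(dx) <= 2);
  }
  static const int face[6] = {cidx(-1, 0, 0), cidx(1, 0, 0), cidx(0, -1, 0),
                              cidx(0, 1, 0),  cidx(0, 0, -1), cidx(0, 0, 1)};
  int comp = 0;
  int stack[27];
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (cube[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int c = stack[--top];
      int dz, dy, dx; decode(c, dz, dy, dx);
      for (int c2 = 0; c2 < 27; ++c2) {
        if (seen[c2] || !in18[c2] || cube[c2]) continue;
        int dz2, dy2, dx2; decode(c2, dz2, dy2, dx2);
        if (abs(dz - dz2) + abs(dy - dy2) + abs(dx - dx2) == 1) {
          seen[c2] = true; stack[top++] = c2;
        }
      }
    }
  }
  return comp;
}

inline int n26_count(const bool cube[27]) {
  int n = 0;
  for (int c = 0; c < 27; ++c)
    if (c != 13 && cube[c]) ++n;
  return n;
}

// A border point is simple iff its deletion preserves topology: exactly one
// 26-component of foreground in N26 and exactly one 6-component of background
// in N18 touching a face neighbour.
inline bool is_simple(const bool cube[27]) {
  return fg_components26(cube) == 1 && bg_components6(cube) == 1;
}

// Curve endpoints (<= 1 foreground neighbour) are never deleted, so line ends
// and isolated voxels survive.
inline bool is_endpoint(const bool cube[27]) { return n26_count(cube) <= 1; }

} // namespace

// [[Rcpp::export(name = ".thin3d_cpp")]]
IntegerVector thin3d_cpp(IntegerVector mask, IntegerVector dims) {
  Grid g(mask, dims);
  // Direction vectors (dz, dy, dx): the subiteration deletes voxels whose
  // neighbour in that direction is background (U, D, N, S, E, W sweeps).
  static const int dir[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                                {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  std::vector<long> cand;
  bool cube[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < g.nx; ++x)
        for (int y = 0; y < g.ny; ++y)
          for (int z = 0; z < g.nz; ++z) {
            if (!g.v[g.idx(z, y, x)]) continue;
            if (g.at(z + dir[d][0], y + dir[d][1], x + dir[d][2])) continue;
            fill_cube(g, z, y, x, cube);
            if (is_endpoint(cube) || !is_simple(cube)) continue;
            cand.push_back(g.idx(z, y, x));
          }
      // Sequential deletion with re-checking: each voxel is re-tested against
      // the current image, so every single deletion is topology-preserving.
      for (size_t i = 0; i < cand.size(); ++i) {
        long id = cand[i];
        int z = (int)(id % g.nz);
        int y = (int)((id / g.nz) % g.ny);
        int x = (int)(id / ((long)g.nz * g.ny));
        fill_cube(g, z, y, x, cube);
        if (is_endpoint(cube) || !is_simple(cube)) continue;
        g.v[id] = 0;
        changed = true;
      }
    }
  }
  IntegerVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = g.v[i];
  out.attr("dim") = dims;
  return out;
}
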