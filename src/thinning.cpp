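// 3D topology-preserving thinning to a curve skeleton.
//
// A voxel is "simple" (deletable without changing topology) iff
//  (A) its 26-neighborhood foreground, center excluded, forms exactly one
//      26-connected component, and
//  (B) the background voxels of its 18-neighborhood form exactly one
//      6-connected component that is 6-adjacent to the center
// (Bertrand & Malandain characterization). Thinning repeatedly deletes
// simple border points from the six cardinal directions in turn,
// re-checking simplicity sequentially within each sweep so deletions can
// never disconnect the object. Curve end points (exactly one foreground
// neighbor) are preserved.

#include <Rcpp.h>
using namespace Rcpp;

static inline int nidx(int dz, int dy, int dx) {
  return (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
}

// foreground 26-connectivity check within the 3x3x3 neighborhood
static bool cond_A(const bool nb[27]) {
  int labels[27];
  for (int i = 0; i < 27; ++i) labels[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || labels[i] >= 0) continue;
    // BFS over 26-adjacent foreground cells
    int top = 0;
    stack[top++] = i;
    labels[i] = ncomp;
    while (top > 0) {
      int c = stack[--top];
      int cz = c / 9 - 1, cy = (c / 3) % 3 - 1, cx = c % 3 - 1;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !nb[j] || labels[j] >= 0) continue;
        int jz = j / 9 - 1, jy = (j / 3) % 3 - 1, jx = j % 3 - 1;
        if (std::abs(jz - cz) <= 1 && std::abs(jy - cy) <= 1 && std::abs(jx - cx) <= 1) {
          labels[j] = ncomp;
          stack[top++] = j;
        }
      }
    }
    ++ncomp;
  }
  return ncomp == 1;
}

// background 6-connectivity within the 18-neighborhood, components must
// touch the center through a face
static bool cond_B(const bool nb[27]) {
  // cells of the 18-neighborhood: at most two non-zero offsets
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int z = i / 9 - 1, y = (i / 3) % 3 - 1, x = i % 3 - 1;
    in18[i] = (std::abs(z) + std::abs(y) + std::abs(x) <= 2) && i != 13;
  }
  int labels[27];
  for (int i = 0; i < 27; ++i) labels[i] = -1;
  int ncomp_touching = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || labels[i] >= 0) continue;
    bool touches = false;
    int top = 0;
    stack[top++] = i;
    labels[i] = 1;
    while (top > 0) {
      int c = stack[--top];
      int cz = c / 9 - 1, cy = (c / 3) % 3 - 1, cx = c % 3 - 1;
      if (std::abs(cz) + std::abs(cy) + std::abs(cx) == 1) touches = true;
      for (int j = 0; j < 27; ++j) {
        if (!in18[j] || nb[j] || labels[j] >= 0) continue;
        int jz = j / 9 - 1, jy = (j / 3) % 3 - 1, jx = j % 3 - 1;
        if (std::abs(jz - cz) + std::abs(jy - cy) + std::abs(jx - cx) == 1) {
          labels[j] = 1;
          stack[top++] = j;
        }
      }
    }
    if (touches) ++ncomp_touching;
  }
  return ncomp_touching == 1;
}

struct Vol {
  const int nz, ny, nx;
  std::vector<char> v;
  Vol(int nz_, int ny_, int nx_) : nz(nz_), ny(ny_), nx(nx_), v((size_t)nz_ * ny_ * nx_) {}
  inline bool at(int z, int y, int x) const {
    if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx) return false;
    return v[(size_t)z + (size_t)nz * y + (size_t)nz * ny * x] != 0;
  }
  inline void set(int z, int y, int x, bool val) {
    v[(size_t)z + (size_t)nz * y + (size_t)nz * ny * x] = val ? 1 : 0;
  }
};

static void neighborhood(const Vol& V, int z, int y, int x, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[nidx(dz, dy, dx)] = V.at(z + dz, y + dy, x + dx);
}

static int count_fg_neighbors(const bool nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++n;
  return n;
}

static bool is_simple(const bool nb[27]) {
  return cond_A(nb) && cond_B(nb);
}

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector vol, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  Vol V(nz, ny, nx);
  for (R_xlen_t i = 0; i < vol.size(); ++i) V.v[i] = vol[i] ? 1 : 0;

  const int dirs[6][3] = { {-1,0,0}, {1,0,0}, {0,-1,0}, {0,1,0}, {0,0,-1}, {0,0,1} };
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // candidates: border points in direction d, simple, not endpoints
      std::vector<std::array<int, 3>> cand;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            if (!V.at(z, y, x)) continue;
            if (V.at(z + dirs[d][0], y + dirs[d][1], x + dirs[d][2])) continue;
            neighborhood(V, z, y, x, nb);
            int nfg = count_fg_neighbors(nb);
            if (nfg <= 1) continue;  // end point or isolated: keep
            if (is_simple(nb)) cand.push_back({z, y, x});
          }
      // sequential deletion with re-check
      for (const auto& c : cand) {
        neighborhood(V, c[0], c[1], c[2], nb);
        int nfg = count_fg_neighbors(nb);
        if (nfg <= 1) continue;
        if (is_simple(nb)) {
          V.set(c[0], c[1], c[2], false);
          changed = true;
        }
      }
    }
  }
  LogicalVector out(vol.size());
  for (R_xlen_t i = 0; i < vol.size(); ++i) out[i] = V.v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
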