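// 3D image primitives used by puncta segmentation and neuropil masking.
// Volumes are passed as numeric/logical vectors with a dim attribute,
// dimension order (x, y, z), x fastest (R column-major layout).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void get_dims(SEXP v, int& nx, int& ny, int& nz) {
  IntegerVector d = Rf_getAttrib(v, R_DimSymbol);
  if (d.size() != 3) stop("expected a 3D array");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// offsets of the ellipsoidal neighborhood (excluding the centre)
static std::vector<std::array<int,3>> ellipsoid_offsets(int rx, int ry, int rz) {
  std::vector<std::array<int,3>> off;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        double m = (double)dx*dx/((double)rx*rx) +
                   (double)dy*dy/((double)ry*ry) +
                   (double)dz*dz/((double)rz*rz);
        if (m <= 1.0) off.push_back({dx, dy, dz});
      }
  return off;
}

// Strict local maxima within an ellipsoidal neighborhood of radii
// (rx, ry, rz) voxels, above `floor_val`. A voxel on a plateau counts only
// if no equal-valued neighbor has a lower linear index (deterministic
// tie-break). Returns 1-based (x, y, z) coordinates ordered by linear index.
// [[Rcpp::export(name = ".local_maxima_3d")]]
IntegerMatrix local_maxima_3d(NumericVector vol, int rx, int ry, int rz,
                              double floor_val) {
  int nx, ny, nz; get_dims(vol, nx, ny, nz);
  if (rx < 1 || ry < 1 || rz < 1) stop("radii must be >= 1");
  std::vector<std::array<int,3>> off = ellipsoid_offsets(rx, ry, rz);
  std::vector<int> hits;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z*nx*ny + (R_xlen_t)y*nx + x;
        double v = vol[i];
        if (!(v > floor_val)) continue;
        bool is_max = true;
        for (size_t k = 0; k < off.size() && is_max; ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t j = (R_xlen_t)zz*nx*ny + (R_xlen_t)yy*nx + xx;
          double w = vol[j];
          if (w > v) is_max = false;
          else if (w == v && j < i) is_max = false;
        }
        if (is_max) hits.push_back((int)i);
      }
  IntegerMatrix out(hits.size(), 3);
  for (size_t k = 0; k < hits.size(); ++k) {
    int i = hits[k];
    out(k, 0) = i % nx + 1;
    out(k, 1) = (i / nx) % ny + 1;
    out(k, 2) = i / (nx * ny) + 1;
  }
  return out;
}

struct PQItem {
  double val; long order; int idx; int label;
};
struct PQCmp {
  bool operator()(const PQItem& a, const PQItem& b) const {
    if (a.val != b.val) return a.val < b.val;   // max-heap on intensity
    return a.order > b.order;                   // FIFO on ties
  }
};

// Marker-controlled watershed on inverted intensity: flood from the seeds
// in order of decreasing intensity, restricted to voxels whose value
// exceeds `floor_val`; 6-connectivity. `seeds` are 1-based (x, y, z) rows;
// seed k receives label k. Returns an integer label array (0 = unassigned).
// [[Rcpp::export(name = ".marker_watershed_3d")]]
IntegerVector marker_watershed_3d(NumericVector vol, IntegerMatrix seeds,
                                  double floor_val) {
  int nx, ny, nz; get_dims(vol, nx, ny, nz);
  R_xlen_t n = (R_xlen_t)nx*ny*nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  if (seeds.nrow() == 0) return lab;
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  long order = 0;
  for (int k = 0; k < seeds.nrow(); ++k) {
    int x = seeds(k,0) - 1, y = seeds(k,1) - 1, z = seeds(k,2) - 1;
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
      stop("seed outside volume");
    R_xlen_t i = (R_xlen_t)z*nx*ny + (R_xlen_t)y*nx + x;
    if (!(vol[i] > floor_val)) continue;  // caller warns on skipped seeds
    pq.push({vol[i], order++, (int)i, k + 1});
  }
  const int dx[6] = {1,-1,0,0,0,0};
  const int dy[6] = {0,0,1,-1,0,0};
  const int dz[6] = {0,0,0,0,1,-1};
  while (!pq.empty()) {
    PQItem it = pq.top(); pq.pop();
    if (lab[it.idx] != 0) continue;
    lab[it.idx] = it.label;
    int x = it.idx % nx, y = (it.idx / nx) % ny, z = it.idx / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = (R_xlen_t)zz*nx*ny + (R_xlen_t)yy*nx + xx;
      if (lab[j] == 0 && vol[j] > floor_val)
        pq.push({vol[j], order++, (int)j, it.label});
    }
  }
  return lab;
}

// Binary dilation with an ellipsoidal structuring element of radii
// (rx, ry, rz) voxels; radii of 0 are allowed (identity along that axis).
// [[Rcpp::export(name = ".dilate_ellipsoid_3d")]]
LogicalVector dilate_ellipsoid_3d(LogicalVector mask, int rx, int ry, int rz) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  LogicalVector out(mask.size(), false);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  int ex = std::max(rx,1), ey = std::max(ry,1), ez = std::max(rz,1);
  std::vector<std::array<int,3>> off;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double m = (double)dx*dx/((double)ex*ex) +
                   (double)dy*dy/((double)ey*ey) +
                   (double)dz*dz/((double)ez*ez);
        if (rx == 0 && dx != 0) continue;
        if (ry == 0 && dy != 0) continue;
        if (rz == 0 && dz != 0) continue;
        if (m <= 1.0) off.push_back({dx, dy, dz});
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z*nx*ny + (R_xlen_t)y*nx + x;
        if (!mask[i]) continue;
        for (size_t k = 0; k < off.size(); ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          out[(R_xlen_t)zz*nx*ny + (R_xlen_t)yy*nx + xx] = true;
        }
      }
  return out;
}

// 6-connected component labelling of a 3D boolean mask.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  R_xlen_t n = (R_xlen_t)nx*ny*nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  const int dx[6] = {1,-1,0,0,0,0};
  const int dy[6] = {0,0,1,-1,0,0};
  const int dz[6] = {0,0,0,0,1,-1};
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0] != 0) continue;
    ++next;
    stack.push_back((int)i0);
    lab[i0] = next;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz*nx*ny + (R_xlen_t)yy*nx + xx;
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back((int)j); }
      }
    }
  }
  return lab;
}
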