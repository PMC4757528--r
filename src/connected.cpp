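#include <Rcpp.h>
#include <vector>

// 3D connected-component labeling of a logical mask by union-find.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Labels are positive integers, 0 for background; label order follows the
// first-encountered voxel in column-major scan order (after relabeling,
// labels are dense 1..k).

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label_components_3d")]]
Rcpp::IntegerVector label_components_3d(Rcpp::LogicalVector mask,
                                        Rcpp::IntegerVector dims,
                                        int connectivity) {
  if (dims.size() != 3) Rcpp::stop("mask must be a 3D array");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    Rcpp::stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) Rcpp::stop("mask length does not match dims");

  // neighbor offsets with strictly negative scan order (backward half of the
  // neighborhood) so each voxel is merged with already-visited neighbors
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        // backward in column-major order: z < 0, or z==0 && y < 0, or
        // z==0 && y==0 && x < 0
        if (cz < 0 || (cz == 0 && (cy < 0 || (cy == 0 && cx < 0)))) {
          dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
        }
      }

  Rcpp::IntegerVector labels(n, 0);
  std::vector<int> parent;
  parent.push_back(0);  // dummy so labels index parent directly

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (mask[idx] != TRUE) continue;
        int cur = 0;
        for (size_t k = 0; k < dx.size(); ++k) {
          int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
          int nl = labels[nidx];
          if (nl > 0) {
            if (cur == 0) cur = uf_find(parent, nl);
            else uf_union(parent, cur, nl);
          }
        }
        if (cur == 0) {
          cur = (int)parent.size();
          parent.push_back(cur);
        }
        labels[idx] = cur;
      }

  // flatten and densify labels
  std::vector<int> dense(parent.size(), 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] == 0) continue;
    int r = uf_find(parent, labels[i]);
    if (dense[r] == 0) dense[r] = ++next;
    labels[i] = dense[r];
  }
  labels.attr("dim") = dims;
  return labels;
}
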