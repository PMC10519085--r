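// Performance kernels: grid block matching (exhaustive NCC with top-k
// peaks), 3D connected-component labelling, and deterministic ordered
// flooding used by the watershed stage.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exhaustive normalised cross-correlation of one reference block against a
// search window in the moving image, returning the NCC surface.
// Images are column-major [y, x] matrices; coordinates are 0-based.
// [[Rcpp::export(name = ".ncc_surface")]]
NumericMatrix ncc_surface_cpp(const NumericMatrix& ref, const NumericMatrix& mov,
                              int cx, int cy, int block, int search) {
  int h = ref.nrow(), w = ref.ncol();
  int half = block / 2;
  int x0 = cx - half, y0 = cy - half; // block top-left in ref
  int side = 2 * search + 1;
  NumericMatrix out(side, side); // [dy + search, dx + search]
  std::fill(out.begin(), out.end(), NA_REAL);
  if (x0 < 0 || y0 < 0 || x0 + block > w || y0 + block > h) return out;

  // reference block statistics
  double rsum = 0, rsum2 = 0;
  for (int bx = 0; bx < block; ++bx)
    for (int by = 0; by < block; ++by) {
      double v = ref(y0 + by, x0 + bx);
      rsum += v; rsum2 += v * v;
    }
  int n = block * block;
  double rmean = rsum / n;
  double rvar = rsum2 / n - rmean * rmean;
  if (rvar <= 1e-12) {
    out.attr("textureless") = true;
    return out;
  }
  double rsd = std::sqrt(rvar);

  int mh = mov.nrow(), mw = mov.ncol();
  for (int dy = -search; dy <= search; ++dy) {
    for (int dx = -search; dx <= search; ++dx) {
      int mx0 = x0 + dx, my0 = y0 + dy;
      if (mx0 < 0 || my0 < 0 || mx0 + block > mw || my0 + block > mh) continue;
      double msum = 0, msum2 = 0, cross = 0;
      for (int bx = 0; bx < block; ++bx) {
        for (int by = 0; by < block; ++by) {
          double a = ref(y0 + by, x0 + bx);
          double b = mov(my0 + by, mx0 + bx);
          msum += b; msum2 += b * b; cross += a * b;
        }
      }
      double mmean = msum / n;
      double mvar = msum2 / n - mmean * mmean;
      if (mvar <= 1e-12) continue;
      double ncc = (cross / n - rmean * mmean) / (rsd * std::sqrt(mvar));
      out(dy + search, dx + search) = ncc;
    }
  }
  out.attr("textureless") = false;
  return out;
}

// 6- or 26-connected component labelling of a 3D mask laid out as an R
// array [z, y, x] (z fastest). Labels are assigned in scan order, so ids
// are deterministic and contiguous from 1.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d_cpp(const LogicalVector& mask, const IntegerVector& dims,
                              int connectivity = 6) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (manh == 0) continue;
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  auto idx = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
  };

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    stack.push_back(i);
    labels[i] = next_label;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((R_xlen_t)nz * ny);
      for (auto& o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = idx(zz, yy, xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}

// Assign unlabelled (contour) voxels to adjacent basins by breadth-first
// flooding. Round r assigns every unlabelled voxel 6-adjacent to a voxel
// labelled in round < r; ties between neighbouring basins resolve to the
// smallest label id. Voxels unreachable from any basin stay 0.
// [[Rcpp::export(name = ".flood_assign")]]
IntegerVector flood_assign_cpp(IntegerVector labels, const IntegerVector& dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector out = clone(labels);

  const int offz[6] = {-1, 1, 0, 0, 0, 0};
  const int offy[6] = {0, 0, -1, 1, 0, 0};
  const int offx[6] = {0, 0, 0, 0, -1, 1};

  std::vector<R_xlen_t> frontier;
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] > 0) frontier.push_back(i);

  std::vector<R_xlen_t> next_ids;
  std::vector<int> next_lab;
  while (!frontier.empty()) {
    next_ids.clear();
    next_lab.clear();
    for (R_xlen_t cur : frontier) {
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((R_xlen_t)nz * ny);
      int lab = out[cur];
      for (int k = 0; k < 6; ++k) {
        int zz = z + offz[k], yy = y + offy[k], xx = x + offx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (out[j] == 0) {
          next_ids.push_back(j);
          next_lab.push_back(lab);
        }
      }
    }
    // resolve ties deterministically: smallest label wins per voxel
    frontier.clear();
    std::vector<std::pair<R_xlen_t, int>> pairs(next_ids.size());
    for (size_t k = 0; k < next_ids.size(); ++k)
      pairs[k] = {next_ids[k], next_lab[k]};
    std::sort(pairs.begin(), pairs.end());
    for (size_t k = 0; k < pairs.size(); ++k) {
      R_xlen_t j = pairs[k].first;
      if (out[j] == 0) {
        out[j] = pairs[k].second;
        frontier.push_back(j);
      }
    }
  }
  return out;
}
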