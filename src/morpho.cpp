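#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// dims are (nz, ny, nx); arrays are R column-major, index = z + nz*(y + ny*x)
static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// 3D connected-component labelling of the foreground (labels > 0) by BFS.
// Components never cross different input labels: two touching voxels belong to
// the same object only if they carry the same semantic label.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector labels, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out(labels.size(), 0);

  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }

  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = vidx(z, y, x, nz, ny);
        if (labels[i] <= 0 || out[i] != 0) continue;
        int sem = labels[i];
        ++next;
        out[i] = next;
        q.push({z, y, x});
        while (!q.empty()) {
          auto v = q.front(); q.pop();
          for (const auto &d : nb) {
            int zz = v[0] + d[0], yy = v[1] + d[1], xx = v[2] + d[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            R_xlen_t j = vidx(zz, yy, xx, nz, ny);
            if (labels[j] == sem && out[j] == 0) {
              out[j] = next;
              q.push({zz, yy, xx});
            }
          }
        }
      }
  out.attr("n") = next;
  return out;
}

// Per-node spherical sampling: for each scan node (physical zyx position),
// count voxels whose center lies within `radius`, split into occupied and
// total-in-bounds, plus the full (unclipped) kernel voxel count at that node.
// spacing is (sz, sy, sx); node positions are rows of `nodes` (z, y, x).
// [[Rcpp::export(name = ".density_scan")]]
List density_scan(IntegerVector mask, IntegerVector dims, NumericVector spacing,
                  NumericMatrix nodes, double radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const int n = nodes.nrow();
  NumericVector occ(n), inb(n), full(n);
  const double r2 = radius * radius;

  for (int k = 0; k < n; ++k) {
    const double pz = nodes(k, 0), py = nodes(k, 1), px = nodes(k, 2);
    // voxel center c_i = (i + 0.5) * s; sweep the index bbox of the sphere
    int z0 = (int)std::floor((pz - radius) / sz - 0.5), z1 = (int)std::ceil((pz + radius) / sz - 0.5);
    int y0 = (int)std::floor((py - radius) / sy - 0.5), y1 = (int)std::ceil((py + radius) / sy - 0.5);
    int x0 = (int)std::floor((px - radius) / sx - 0.5), x1 = (int)std::ceil((px + radius) / sx - 0.5);
    double nocc = 0, nin = 0, nfull = 0;
    for (int x = x0; x <= x1; ++x) {
      double ddx = (x + 0.5) * sx - px;
      for (int y = y0; y <= y1; ++y) {
        double ddy = (y + 0.5) * sy - py;
        double dxy = ddx * ddx + ddy * ddy;
        if (dxy > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double ddz = (z + 0.5) * sz - pz;
          if (dxy + ddz * ddz > r2) continue;
          nfull += 1;
          if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
          nin += 1;
          if (mask[vidx(z, y, x, nz, ny)] > 0) nocc += 1;
        }
      }
    }
    occ[k] = nocc; inb[k] = nin; full[k] = nfull;
  }
  return List::create(_["occupied"] = occ, _["in_bounds"] = inb, _["full_kernel"] = full);
}

// Sequential hard-core thinning: accept candidate points (rows of phys coords,
// already in preference order) whose distance to every previously accepted
// point is >= rmin. Stops after n_target acceptances (or all candidates).
// Uses a uniform grid hash of cell size rmin.
// [[Rcpp::export(name = ".hardcore_sample")]]
IntegerVector hardcore_sample(NumericMatrix pts, double rmin, int n_target) {
  const int n = pts.nrow();
  std::vector<int> keep;
  keep.reserve(n_target > 0 ? n_target : n);
  if (rmin <= 0) {
    for (int i = 0; i < n && (n_target <= 0 || (int)keep.size() < n_target); ++i)
      keep.push_back(i + 1);
    return wrap(keep);
  }
  const double cell = rmin;
  const double r2 = rmin * rmin;
  std::unordered_map<std::uint64_t, std::vector<int>> grid;
  auto key = [cell](double z, double y, double x) {
    std::int64_t kz = (std::int64_t)std::floor(z / cell) + 1048576;
    std::int64_t ky = (std::int64_t)std::floor(y / cell) + 1048576;
    std::int64_t kx = (std::int64_t)std::floor(x / cell) + 1048576;
    return (std::uint64_t)kz | ((std::uint64_t)ky << 21) | ((std::uint64_t)kx << 42);
  };
  for (int i = 0; i < n; ++i) {
    if (n_target > 0 && (int)keep.size() >= n_target) break;
    double z = pts(i, 0), y = pts(i, 1), x = pts(i, 2);
    bool ok = true;
    for (int dz = -1; dz <= 1 && ok; ++dz)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          auto it = grid.find(key(z + dz * cell, y + dy * cell, x + dx * cell));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double az = pts(j, 0) - z, ay = pts(j, 1) - y, ax = pts(j, 2) - x;
            if (az * az + ay * ay + ax * ax < r2) { ok = false; break; }
          }
        }
    if (ok) {
      grid[key(z, y, x)].push_back(i);
      keep.push_back(i + 1);
    }
  }
  return wrap(keep);
}

// Minimum physical voxel-center distance between every pair of distinct
// objects that come closer than max_gap. Returns a matrix with columns
// (label_i, label_j, gap). Grid-hash over foreground voxels.
// [[Rcpp::export(name = ".close_pairs")]]
NumericMatrix close_pairs(IntegerVector labels, IntegerVector dims,
                          NumericVector spacing, double max_gap) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  struct Vox { double z, y, x; int lab; };
  std::vector<Vox> fg;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int l = labels[vidx(z, y, x, nz, ny)];
        if (l > 0) fg.push_back({(z + 0.5) * sz, (y + 0.5) * sy, (x + 0.5) * sx, l});
      }
  const double cell = max_gap > 0 ? max_gap : 1.0;
  const double g2 = max_gap * max_gap;
  std::unordered_map<std::uint64_t, std::vector<int>> grid;
  auto key = [cell](double z, double y, double x) {
    std::int64_t kz = (std::int64_t)std::floor(z / cell) + 1048576;
    std::int64_t ky = (std::int64_t)std::floor(y / cell) + 1048576;
    std::int64_t kx = (std::int64_t)std::floor(x / cell) + 1048576;
    return (std::uint64_t)kz | ((std::uint64_t)ky << 21) | ((std::uint64_t)kx << 42);
  };
  for (int i = 0; i < (int)fg.size(); ++i)
    grid[key(fg[i].z, fg[i].y, fg[i].x)].push_back(i);

  std::unordered_map<std::uint64_t, double> best;  // (lo,hi) pair -> min dist
  for (int i = 0; i < (int)fg.size(); ++i) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          auto it = grid.find(key(fg[i].z + dz * cell, fg[i].y + dy * cell, fg[i].x + dx * cell));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i || fg[j].lab == fg[i].lab) continue;
            double az = fg[j].z - fg[i].z, ay = fg[j].y - fg[i].y, ax = fg[j].x - fg[i].x;
            double d2 = az * az + ay * ay + ax * ax;
            if (d2 >= g2) continue;
            int lo = std::min(fg[i].lab, fg[j].lab), hi = std::max(fg[i].lab, fg[j].lab);
            std::uint64_t pk = ((std::uint64_t)lo << 32) | (std::uint64_t)hi;
            auto b = best.find(pk);
            if (b == best.end() || d2 < b->second) best[pk] = d2;
          }
        }
  }
  NumericMatrix out(best.size(), 3);
  int r = 0;
  for (const auto &kv : best) {
    out(r, 0) = (double)(kv.first >> 32);
    out(r, 1) = (double)(kv.first & 0xffffffffULL);
    out(r, 2) = std::sqrt(kv.second);
    ++r;
  }
  return out;
}

// Exact nearest neighbour by full O(n^2) scan over physical coordinates.
// Returns 1-based index of the nearest other point and the distance.
// [[Rcpp::export(name = ".nn_scan")]]
List nn_scan(NumericMatrix pts) {
  const int n = pts.nrow();
  IntegerVector nn_id(n, NA_INTEGER);
  NumericVector nn_d(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double bz = pts(i, 0), by = pts(i, 1), bx = pts(i, 2);
    double bd = R_PosInf; int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double az = pts(j, 0) - bz, ay = pts(j, 1) - by, ax = pts(j, 2) - bx;
      double d2 = az * az + ay * ay + ax * ax;
      if (d2 < bd) { bd = d2; bj = j; }
    }
    nn_d[i] = std::sqrt(bd);
    nn_id[i] = bj + 1;
  }
  return List::create(_["nn_distance"] = nn_d, _["nn_id"] = nn_id);
}

// Tabulate 2x2x2 voxel configurations over all cells of the (padded) mask.
// Bit b of the configuration is corner (dz,dy,dx) with b = 4*dz + 2*dy + dx.
// Returns counts of configurations 0..255.
// [[Rcpp::export(name = ".config_counts")]]
NumericVector config_counts(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector counts(256);
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        int cfg = 0;
        for (int b = 0; b < 8; ++b) {
          int dz = (b >> 2) & 1, dy = (b >> 1) & 1, dx = b & 1;
          if (mask[vidx(z + dz, y + dy, x + dx, nz, ny)] > 0) cfg |= (1 << b);
        }
        counts[cfg] += 1;
      }
  return counts;
}

// Per-object bounding boxes, voxel counts and centroid sums in index space.
// labels: instance labels 1..n. Returns an n x 11 matrix:
// (count, zmin, zmax, ymin, ymax, xmin, xmax, zsum, ysum, xsum, border)
// [[Rcpp::export(name = ".object_stats")]]
NumericMatrix object_stats(IntegerVector labels, IntegerVector dims, int n) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericMatrix st(n, 11);
  for (int i = 0; i < n; ++i) {
    st(i, 1) = nz; st(i, 2) = -1; st(i, 3) = ny; st(i, 4) = -1; st(i, 5) = nx; st(i, 6) = -1;
  }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int l = labels[vidx(z, y, x, nz, ny)];
        if (l <= 0) continue;
        int i = l - 1;
        st(i, 0) += 1;
        if (z < st(i, 1)) st(i, 1) = z;
        if (z > st(i, 2)) st(i, 2) = z;
        if (y < st(i, 3)) st(i, 3) = y;
        if (y > st(i, 4)) st(i, 4) = y;
        if (x < st(i, 5)) st(i, 5) = x;
        if (x > st(i, 6)) st(i, 6) = x;
        st(i, 7) += z; st(i, 8) += y; st(i, 9) += x;
        if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1)
          st(i, 10) = 1;
      }
  return st;
}
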