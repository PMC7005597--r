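// Hot paths of the docking engine: cell-list accelerated pair-potential
// scoring (single pose and glowworm batches), restraint satisfaction and
// residue-residue contact detection.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

// cell list over a fixed point set, cell size = cutoff
struct CellGrid {
  double cell, ox, oy, oz;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;

  CellGrid(const NumericMatrix& xyz, double cutoff) {
    cell = cutoff;
    double mx = xyz(0, 0), my = xyz(0, 1), mz = xyz(0, 2);
    double Mx = mx, My = my, Mz = mz;
    for (int i = 1; i < xyz.nrow(); ++i) {
      mx = std::min(mx, xyz(i, 0)); Mx = std::max(Mx, xyz(i, 0));
      my = std::min(my, xyz(i, 1)); My = std::max(My, xyz(i, 1));
      mz = std::min(mz, xyz(i, 2)); Mz = std::max(Mz, xyz(i, 2));
    }
    ox = mx; oy = my; oz = mz;
    nx = (int)std::floor((Mx - ox) / cell) + 1;
    ny = (int)std::floor((My - oy) / cell) + 1;
    nz = (int)std::floor((Mz - oz) / cell) + 1;
    cells.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < xyz.nrow(); ++i) {
      cells[index(xyz(i, 0), xyz(i, 1), xyz(i, 2))].push_back(i);
    }
  }
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  inline size_t index(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - ox) / cell), nx);
    int iy = clampi((int)std::floor((y - oy) / cell), ny);
    int iz = clampi((int)std::floor((z - oz) / cell), nz);
    return ((size_t)iz * ny + iy) * nx + ix;
  }
  // visit grid points within cutoff of (x,y,z); f(i) per candidate index
  template <typename F> void neighbors(double x, double y, double z, F f) const {
    int ix = (int)std::floor((x - ox) / cell);
    int iy = (int)std::floor((y - oy) / cell);
    int iz = (int)std::floor((z - oz) / cell);
    for (int dz = -1; dz <= 1; ++dz) {
      int cz = iz + dz; if (cz < 0 || cz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int cy = iy + dy; if (cy < 0 || cy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int cx = ix + dx; if (cx < 0 || cx >= nx) continue;
          const std::vector<int>& c = cells[((size_t)cz * ny + cy) * nx + cx];
          for (size_t k = 0; k < c.size(); ++k) f(c[k]);
        }
      }
    }
  }
};

inline int binOf(double d, const NumericVector& edges) {
  // bin k (0-based) covers [edges[k-1], edges[k]), implicit lower edge 0
  for (int k = 0; k < edges.size(); ++k) if (d < edges[k]) return k;
  return -1;
}

double scoreAgainstGrid(const CellGrid& grid, const NumericMatrix& rec_xyz,
                        const IntegerVector& rec_type,
                        const std::vector<double>& lx,
                        const std::vector<double>& ly,
                        const std::vector<double>& lz,
                        const IntegerVector& lig_type,
                        const NumericVector& energies, int ntype,
                        const NumericVector& edges) {
  double cutoff = edges[edges.size() - 1];
  double cut2 = cutoff * cutoff;
  double total = 0.0;
  for (size_t j = 0; j < lx.size(); ++j) {
    int tj = lig_type[j];
    if (tj < 0) continue;  // untyped atom, skipped
    grid.neighbors(lx[j], ly[j], lz[j], [&](int i) {
      int ti = rec_type[i];
      if (ti < 0) return;
      double dx = rec_xyz(i, 0) - lx[j];
      double dy = rec_xyz(i, 1) - ly[j];
      double dz = rec_xyz(i, 2) - lz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= cut2) return;
      int k = binOf(std::sqrt(d2), edges);
      if (k >= 0) total += energies[((size_t)k * ntype + tj) * ntype + ti];
    });
  }
  return total;
}

}  // namespace

// Score one pose: receptor fixed, ligand coordinates already posed.
// types are 0-based indices into the table alphabet, -1 = untyped (skip).
// energies is the [ntype, ntype, nbin] array flattened in R column-major
// order (i fastest), symmetric in (i, j).
// [[Rcpp::export]]
double cpp_score_coords(NumericMatrix rec_xyz, IntegerVector rec_type,
                        NumericMatrix lig_xyz, IntegerVector lig_type,
                        NumericVector energies, int ntype,
                        NumericVector bin_edges) {
  double cutoff = bin_edges[bin_edges.size() - 1];
  CellGrid grid(rec_xyz, cutoff);
  std::vector<double> lx(lig_xyz.nrow()), ly(lig_xyz.nrow()), lz(lig_xyz.nrow());
  for (int j = 0; j < lig_xyz.nrow(); ++j) {
    lx[j] = lig_xyz(j, 0); ly[j] = lig_xyz(j, 1); lz[j] = lig_xyz(j, 2);
  }
  return scoreAgainstGrid(grid, rec_xyz, rec_type, lx, ly, lz, lig_type,
                          energies, ntype, bin_edges);
}

// Score a batch of glowworm poses. lig_xyz is the ligand in its original
// frame; each pose rotates about the ligand centroid by quaternion
// (w,x,y,z) in row p of quat, then translates by row p of trans.
// [[Rcpp::export]]
NumericVector cpp_score_poses(NumericMatrix rec_xyz, IntegerVector rec_type,
                              NumericMatrix lig_xyz, IntegerVector lig_type,
                              NumericMatrix quat, NumericMatrix trans,
                              NumericVector energies, int ntype,
                              NumericVector bin_edges) {
  double cutoff = bin_edges[bin_edges.size() - 1];
  CellGrid grid(rec_xyz, cutoff);
  int nl = lig_xyz.nrow(), np = quat.nrow();
  double cx = 0, cy = 0, cz = 0;
  for (int j = 0; j < nl; ++j) { cx += lig_xyz(j, 0); cy += lig_xyz(j, 1); cz += lig_xyz(j, 2); }
  cx /= nl; cy /= nl; cz /= nl;
  NumericVector out(np);
  std::vector<double> lx(nl), ly(nl), lz(nl);
  for (int p = 0; p < np; ++p) {
    double w = quat(p, 0), x = quat(p, 1), y = quat(p, 2), z = quat(p, 3);
    double R[9] = {
      1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)};
    double tx = cx + trans(p, 0), ty = cy + trans(p, 1), tz = cz + trans(p, 2);
    for (int j = 0; j < nl; ++j) {
      double vx = lig_xyz(j, 0) - cx, vy = lig_xyz(j, 1) - cy, vz = lig_xyz(j, 2) - cz;
      lx[j] = R[0] * vx + R[1] * vy + R[2] * vz + tx;
      ly[j] = R[3] * vx + R[4] * vy + R[5] * vz + ty;
      lz[j] = R[6] * vx + R[7] * vy + R[8] * vz + tz;
    }
    out[p] = scoreAgainstGrid(grid, rec_xyz, rec_type, lx, ly, lz, lig_type,
                              energies, ntype, bin_edges);
  }
  return out;
}

// Fraction of restraint groups satisfied: group g (1-based atom indices
// into its own molecule, side 0 = receptor / 1 = ligand) is satisfied iff
// any of its atoms is within cutoff of any partner atom.
// [[Rcpp::export]]
double cpp_satisfied_fraction(NumericMatrix rec_xyz, NumericMatrix lig_xyz,
                              List groups, IntegerVector sides,
                              double cutoff) {
  int ng = groups.size();
  if (ng == 0) return 1.0;
  double cut2 = cutoff * cutoff;
  CellGrid recGrid(rec_xyz, cutoff);
  CellGrid ligGrid(lig_xyz, cutoff);
  int sat = 0;
  for (int g = 0; g < ng; ++g) {
    IntegerVector idx = groups[g];
    const NumericMatrix& own = sides[g] == 0 ? rec_xyz : lig_xyz;
    const NumericMatrix& other = sides[g] == 0 ? lig_xyz : rec_xyz;
    const CellGrid& grid = sides[g] == 0 ? ligGrid : recGrid;
    bool hit = false;
    for (int k = 0; k < idx.size() && !hit; ++k) {
      int i = idx[k] - 1;
      double x = own(i, 0), y = own(i, 1), z = own(i, 2);
      grid.neighbors(x, y, z, [&](int j) {
        if (hit) return;
        double dx = other(j, 0) - x, dy = other(j, 1) - y, dz = other(j, 2) - z;
        if (dx * dx + dy * dy + dz * dz <= cut2) hit = true;
      });
    }
    if (hit) ++sat;
  }
  return (double)sat / ng;
}

// Satisfaction fractions for a batch of ligand poses (same pose
// parameterization as cpp_score_poses).
// [[Rcpp::export]]
NumericVector cpp_satisfied_poses(NumericMatrix rec_xyz, NumericMatrix lig_xyz,
                                  NumericMatrix quat, NumericMatrix trans,
                                  List groups, IntegerVector sides,
                                  double cutoff) {
  int np = quat.nrow(), nl = lig_xyz.nrow();
  NumericVector out(np);
  if (groups.size() == 0) { std::fill(out.begin(), out.end(), 1.0); return out; }
  double cx = 0, cy = 0, cz = 0;
  for (int j = 0; j < nl; ++j) { cx += lig_xyz(j, 0); cy += lig_xyz(j, 1); cz += lig_xyz(j, 2); }
  cx /= nl; cy /= nl; cz /= nl;
  NumericMatrix posed(nl, 3);
  for (int p = 0; p < np; ++p) {
    double w = quat(p, 0), x = quat(p, 1), y = quat(p, 2), z = quat(p, 3);
    double R[9] = {
      1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)};
    double tx = cx + trans(p, 0), ty = cy + trans(p, 1), tz = cz + trans(p, 2);
    for (int j = 0; j < nl; ++j) {
      double vx = lig_xyz(j, 0) - cx, vy = lig_xyz(j, 1) - cy, vz = lig_xyz(j, 2) - cz;
      posed(j, 0) = R[0] * vx + R[1] * vy + R[2] * vz + tx;
      posed(j, 1) = R[3] * vx + R[4] * vy + R[5] * vz + ty;
      posed(j, 2) = R[6] * vx + R[7] * vy + R[8] * vz + tz;
    }
    out[p] = cpp_satisfied_fraction(rec_xyz, posed, groups, sides, cutoff);
  }
  return out;
}

// Residue pairs in contact: any-atom distance < cutoff. res ids are
// 1-based contiguous residue indices per molecule. Returns a matrix with
// columns (receptor residue, ligand residue, min distance).
// [[Rcpp::export]]
NumericMatrix cpp_residue_contacts(NumericMatrix rec_xyz, IntegerVector rec_res,
                                   NumericMatrix lig_xyz, IntegerVector lig_res,
                                   double cutoff) {
  double cut2 = cutoff * cutoff;
  CellGrid grid(rec_xyz, cutoff);
  std::map<std::pair<int, int>, double> best;
  for (int j = 0; j < lig_xyz.nrow(); ++j) {
    double x = lig_xyz(j, 0), y = lig_xyz(j, 1), z = lig_xyz(j, 2);
    grid.neighbors(x, y, z, [&](int i) {
      double dx = rec_xyz(i, 0) - x, dy = rec_xyz(i, 1) - y, dz = rec_xyz(i, 2) - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= cut2) return;
      std::pair<int, int> key(rec_res[i], lig_res[j]);
      auto it = best.find(key);
      double d = std::sqrt(d2);
      if (it == best.end() || d < it->second) best[key] = d;
    });
  }
  NumericMatrix out(best.size(), 3);
  int r = 0;
  for (auto& kv : best) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}

// Minimum inter-molecular atom distance (clash / contact checks).
// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix a_xyz, NumericMatrix b_xyz) {
  double best = R_PosInf;
  for (int i = 0; i < a_xyz.nrow(); ++i) {
    for (int j = 0; j < b_xyz.nrow(); ++j) {
      double dx = a_xyz(i, 0) - b_xyz(j, 0);
      double dy = a_xyz(i, 1) - b_xyz(j, 1);
      double dz = a_xyz(i, 2) - b_xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
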