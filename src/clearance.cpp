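// Nearest-atom-surface (clearance) queries on a uniform cell grid, and
// Voronoi-edge annotation (length, minimum clearance, integrated cost).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct AtomGrid {
  std::vector<double> ax, ay, az, ar;
  double maxr = 0.0;
  double lo[3], cell;
  int dim[3];
  std::vector<int> cell_start;  // CSR layout
  std::vector<int> cell_atom;

  void build(const NumericMatrix& atoms, const NumericVector& radii,
             double cell_size) {
    const int n = atoms.nrow();
    ax.resize(n); ay.resize(n); az.resize(n); ar.resize(n);
    double hi[3];
    for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
    for (int i = 0; i < n; ++i) {
      ax[i] = atoms(i, 0); ay[i] = atoms(i, 1); az[i] = atoms(i, 2);
      ar[i] = radii[i];
      maxr = std::max(maxr, ar[i]);
      lo[0] = std::min(lo[0], ax[i]); hi[0] = std::max(hi[0], ax[i]);
      lo[1] = std::min(lo[1], ay[i]); hi[1] = std::max(hi[1], ay[i]);
      lo[2] = std::min(lo[2], az[i]); hi[2] = std::max(hi[2], az[i]);
    }
    cell = cell_size;
    long ncell = 1;
    for (int j = 0; j < 3; ++j) {
      dim[j] = std::max(1, (int)std::floor((hi[j] - lo[j]) / cell) + 1);
      ncell *= dim[j];
    }
    std::vector<int> count((size_t)ncell + 1, 0);
    std::vector<int> ci(n);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(dim[0] - 1, (int)((ax[i] - lo[0]) / cell));
      int cy = std::min(dim[1] - 1, (int)((ay[i] - lo[1]) / cell));
      int cz = std::min(dim[2] - 1, (int)((az[i] - lo[2]) / cell));
      ci[i] = (cx * dim[1] + cy) * dim[2] + cz;
      ++count[(size_t)ci[i] + 1];
    }
    for (long c = 0; c < ncell; ++c) count[(size_t)c + 1] += count[(size_t)c];
    cell_start = count;
    cell_atom.resize(n);
    std::vector<int> cursor(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < n; ++i) cell_atom[(size_t)cursor[(size_t)ci[i]]++] = i;
  }

  // distance from p to nearest atom *surface* (may be negative inside an atom)
  double clearance(const double* p) const {
    int q[3];
    for (int j = 0; j < 3; ++j) q[j] = (int)std::floor((p[j] - lo[j]) / cell);
    double best = R_PosInf;
    int rho_cap = 0;
    for (int j = 0; j < 3; ++j)
      rho_cap = std::max(rho_cap,
                         std::max(std::abs(q[j] - 0), std::abs(dim[j] - 1 - q[j])));
    for (int rho = 0; rho <= rho_cap; ++rho) {
      if (rho >= 1 && (rho - 1) * cell - maxr > best) break;
      int x0 = std::max(0, q[0] - rho), x1 = std::min(dim[0] - 1, q[0] + rho);
      int y0 = std::max(0, q[1] - rho), y1 = std::min(dim[1] - 1, q[1] + rho);
      int z0 = std::max(0, q[2] - rho), z1 = std::min(dim[2] - 1, q[2] + rho);
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y)
          for (int z = z0; z <= z1; ++z) {
            int ring = std::max({std::abs(x - q[0]), std::abs(y - q[1]),
                                 std::abs(z - q[2])});
            if (ring != rho) continue;
            // prune: closest possible surface in this cell cannot beat best
            double bd2 = 0.0;
            const int cc_[3] = {x, y, z};
            for (int j = 0; j < 3; ++j) {
              double clo = lo[j] + cc_[j] * cell, chi = clo + cell;
              double dj = (p[j] < clo) ? clo - p[j] : (p[j] > chi ? p[j] - chi : 0.0);
              bd2 += dj * dj;
            }
            if (std::sqrt(bd2) - maxr >= best) continue;
            int c = (x * dim[1] + y) * dim[2] + z;
            for (int k = cell_start[(size_t)c]; k < cell_start[(size_t)c + 1]; ++k) {
              int i = cell_atom[(size_t)k];
              double dx = p[0] - ax[i], dy = p[1] - ay[i], dz = p[2] - az[i];
              double d = std::sqrt(dx * dx + dy * dy + dz * dz) - ar[i];
              if (d < best) best = d;
            }
          }
    }
    return best;
  }
};

}  // namespace

// [[Rcpp::export(name = ".clearance_query")]]
NumericVector clearance_query(NumericMatrix points, NumericMatrix atoms,
                              NumericVector radii) {
  AtomGrid G;
  G.build(atoms, radii, 1.5);
  const int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    out[i] = G.clearance(p);
  }
  return out;
}

// For each edge (pair of Voronoi vertices) sample `edge_samples` interior
// points plus the endpoints, then accumulate cost = sum(seg_len / c_mid^2)
// over the segments between consecutive samples, with the clearance taken at
// each segment midpoint.  Segments with non-positive midpoint clearance make
// the edge impassable (cost = +Inf).
// [[Rcpp::export(name = ".annotate_edges")]]
List annotate_edges(NumericMatrix vcoords, IntegerMatrix edges,
                    NumericMatrix atoms, NumericVector radii,
                    int edge_samples) {
  AtomGrid G;
  G.build(atoms, radii, 1.5);
  const int ne = edges.nrow();
  NumericVector len(ne), minc(ne), cost(ne);
  for (int e = 0; e < ne; ++e) {
    const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    double pa[3] = {vcoords(a, 0), vcoords(a, 1), vcoords(a, 2)};
    double pb[3] = {vcoords(b, 0), vcoords(b, 1), vcoords(b, 2)};
    double L = std::sqrt((pb[0]-pa[0])*(pb[0]-pa[0]) +
                         (pb[1]-pa[1])*(pb[1]-pa[1]) +
                         (pb[2]-pa[2])*(pb[2]-pa[2]));
    len[e] = L;
    // long edges get extra samples (one per ~0.5 A, capped) so that narrow
    // passages inside an edge cannot hide from the probe filter
    int ni = std::max(edge_samples, std::min(64, (int)std::ceil(L / 0.5) - 1));
    const int ns = ni + 2;  // endpoints included
    double cmin = R_PosInf, csum = 0.0;
    bool blocked = false;
    for (int s = 0; s < ns; ++s) {
      double t = (double)s / (ns - 1);
      double p[3] = {pa[0] + t * (pb[0] - pa[0]), pa[1] + t * (pb[1] - pa[1]),
                     pa[2] + t * (pb[2] - pa[2])};
      double c = G.clearance(p);
      if (c < cmin) cmin = c;
    }
    const double seg = L / (ns - 1);
    for (int s = 0; s < ns - 1; ++s) {
      double tm = (s + 0.5) / (ns - 1);
      double p[3] = {pa[0] + tm * (pb[0] - pa[0]), pa[1] + tm * (pb[1] - pa[1]),
                     pa[2] + tm * (pb[2] - pa[2])};
      double c = G.clearance(p);
      if (c < cmin) cmin = c;
      if (c <= 0.0) { blocked = true; continue; }
      csum += seg / (c * c);
    }
    minc[e] = cmin;
    cost[e] = blocked ? R_PosInf : csum;
    if ((e & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["length"] = len, _["min_clearance"] = minc,
                      _["cost"] = cost);
}
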