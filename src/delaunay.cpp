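// Incremental Bowyer-Watson Delaunay tessellation in 3D.
// Voronoi vertices are circumcenters of finite tetrahedra; Voronoi edges join
// circumcenters of facet-adjacent tetrahedra.  Input points are perturbed by a
// deterministic hash jitter (~1e-9 of the bounding-box diagonal) so that exact
// cosphericity cannot occur with double-precision predicates.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];      // vertex indices (point ids; >= npts means super vertex)
  int adj[4];    // adj[i] = tet sharing the face opposite v[i], -1 if none
  std::uint32_t stamp;
  bool alive;
};

// faces[i] = vertex index order of the face opposite corner i such that for a
// positively oriented tet the face normal points away from corner i
const int FACES[4][3] = {{1, 3, 2}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2}};

inline double orient3d(const double* a, const double* b, const double* c,
                       const double* d) {
  const double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  const double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  const double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// p strictly inside circumsphere of positively oriented tet (a,b,c,d)
inline bool insphere(const double* a, const double* b, const double* c,
                     const double* d, const double* p) {
  const double aex = a[0] - p[0], aey = a[1] - p[1], aez = a[2] - p[2];
  const double bex = b[0] - p[0], bey = b[1] - p[1], bez = b[2] - p[2];
  const double cex = c[0] - p[0], cey = c[1] - p[1], cez = c[2] - p[2];
  const double dex = d[0] - p[0], dey = d[1] - p[1], dez = d[2] - p[2];
  const double ae2 = aex * aex + aey * aey + aez * aez;
  const double be2 = bex * bex + bey * bey + bez * bez;
  const double ce2 = cex * cex + cey * cey + cez * cez;
  const double de2 = dex * dex + dey * dey + dez * dez;
  // 4x4 determinant expanded along the lifted column
  const double ab = aex * bey - bex * aey;
  const double bc = bex * cey - cex * bey;
  const double cd = cex * dey - dex * cey;
  const double da = dex * aey - aex * dey;
  const double ac = aex * cey - cex * aey;
  const double bd = bex * dey - dex * bey;
  const double abc = aez * bc - bez * ac + cez * ab;
  const double bcd = bez * cd - cez * bd + dez * bc;
  const double cda = cez * da + dez * ac + aez * cd;
  const double dab = dez * ab + aez * bd + bez * da;
  const double det = de2 * abc - ce2 * dab + be2 * cda - ae2 * bcd;
  return det > 0.0;
}

struct Delaunay {
  std::vector<std::array<double, 3>> pts;  // npts real + 4 super
  int npts;
  std::vector<Tet> tets;
  std::vector<int> freelist;
  std::uint32_t stamp = 0;
  int last_tet = 0;
  int skipped = 0;

  const double* P(int i) const { return pts[(size_t)i].data(); }

  int new_tet() {
    if (!freelist.empty()) {
      int id = freelist.back();
      freelist.pop_back();
      tets[id].alive = true;
      tets[id].stamp = 0;
      return id;
    }
    tets.push_back(Tet());
    tets.back().alive = true;
    tets.back().stamp = 0;
    return (int)tets.size() - 1;
  }

  bool tet_insphere(int t, const double* p) const {
    const Tet& T = tets[t];
    return insphere(P(T.v[0]), P(T.v[1]), P(T.v[2]), P(T.v[3]), p);
  }

  // walk from last_tet toward the tet containing p
  int locate(const double* p) {
    int cur = last_tet;
    if (cur < 0 || cur >= (int)tets.size() || !tets[cur].alive) {
      cur = -1;
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive) { cur = i; break; }
    }
    int guard = (int)tets.size() * 4 + 1000;
    while (guard-- > 0) {
      const Tet& T = tets[cur];
      int next = -1;
      for (int f = 0; f < 4; ++f) {
        const double* fa = P(T.v[FACES[f][0]]);
        const double* fb = P(T.v[FACES[f][1]]);
        const double* fc = P(T.v[FACES[f][2]]);
        if (orient3d(fa, fb, fc, p) < 0.0) {  // p outside this face
          next = T.adj[f];
          break;
        }
      }
      if (next < 0) return cur;  // inside (or on) all faces
      cur = next;
    }
    // fallback: scan for any tet whose circumsphere holds p
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && tet_insphere(i, p)) return i;
    return -1;
  }

  bool insert(int pid) {
    const double* p = P(pid);
    int t0 = locate(p);
    if (t0 < 0) return false;
    if (!tet_insphere(t0, p)) {
      // walk stopped at a tet not violated by p (boundary slop); search its
      // neighborhood for a violated tet
      bool found = false;
      for (int f = 0; f < 4 && !found; ++f) {
        int u = tets[t0].adj[f];
        if (u >= 0 && tets[u].alive && tet_insphere(u, p)) { t0 = u; found = true; }
      }
      if (!found) {
        for (int i = 0; i < (int)tets.size(); ++i)
          if (tets[i].alive && tet_insphere(i, p)) { t0 = i; found = true; break; }
      }
      if (!found) return false;
    }
    // BFS for the cavity
    ++stamp;
    std::vector<int> bad;
    std::vector<int> queue_;
    queue_.push_back(t0);
    tets[t0].stamp = stamp;
    while (!queue_.empty()) {
      int t = queue_.back();
      queue_.pop_back();
      bad.push_back(t);
      for (int f = 0; f < 4; ++f) {
        int u = tets[t].adj[f];
        if (u < 0 || tets[u].stamp == stamp || !tets[u].alive) continue;
        if (tet_insphere(u, p)) {
          tets[u].stamp = stamp;
          queue_.push_back(u);
        }
      }
    }
    // boundary faces of the cavity
    struct BFace { int a, b, c, outside, out_face; };
    std::vector<BFace> bf;
    bf.reserve(bad.size() * 2 + 4);
    for (int t : bad) {
      for (int f = 0; f < 4; ++f) {
        int u = tets[t].adj[f];
        if (u >= 0 && tets[u].alive && tets[u].stamp == stamp) continue;  // internal
        BFace F;
        F.a = tets[t].v[FACES[f][0]];
        F.b = tets[t].v[FACES[f][1]];
        F.c = tets[t].v[FACES[f][2]];
        F.outside = u;
        F.out_face = -1;
        if (u >= 0) {
          for (int g = 0; g < 4; ++g)
            if (tets[u].adj[g] == t) { F.out_face = g; break; }
        }
        bf.push_back(F);
      }
    }
    if (bf.size() < 4) return false;
    // validate: every new tet must be positively oriented
    for (const BFace& F : bf) {
      double o = orient3d(P(F.a), P(F.b), P(F.c), p);
      if (!(o > 0.0)) return false;  // degenerate; caller skips the point
    }
    // build new tets (stored as {a,b,c,p}: p has corner index 3)
    std::vector<int> fresh(bf.size());
    for (size_t i = 0; i < bf.size(); ++i) {
      int nt = new_tet();
      fresh[i] = nt;
      Tet& T = tets[nt];
      T.v[0] = bf[i].a; T.v[1] = bf[i].b; T.v[2] = bf[i].c; T.v[3] = pid;
      T.adj[0] = T.adj[1] = T.adj[2] = -1;
      T.adj[3] = bf[i].outside;
      if (bf[i].outside >= 0) tets[bf[i].outside].adj[bf[i].out_face] = nt;
    }
    // stitch new tets to each other across the cavity-boundary edges.
    // face opposite corner k (k<3) of tet {a,b,c,p} contains p and the edge
    // made of the other two of {a,b,c}.
    std::unordered_map<std::uint64_t, std::pair<int,int>> open_face;
    open_face.reserve(bf.size() * 3);
    auto key = [](int x, int y) {
      if (x > y) std::swap(x, y);
      return ((std::uint64_t)(std::uint32_t)x << 32) | (std::uint32_t)y;
    };
    for (size_t i = 0; i < bf.size(); ++i) {
      int nt = fresh[i];
      Tet& T = tets[nt];
      const int edge[3][2] = {{T.v[1], T.v[2]}, {T.v[0], T.v[2]}, {T.v[0], T.v[1]}};
      for (int k = 0; k < 3; ++k) {
        std::uint64_t K = key(edge[k][0], edge[k][1]);
        auto it = open_face.find(K);
        if (it == open_face.end()) {
          open_face[K] = std::make_pair(nt, k);
        } else {
          T.adj[k] = it->second.first;
          tets[it->second.first].adj[it->second.second] = nt;
          open_face.erase(it);
        }
      }
    }
    if (!open_face.empty()) {
      // cavity boundary was not watertight -> roll back is impractical;
      // leave adjacency holes (-1): affects only the hull neighborhood.
    }
    for (int t : bad) {
      tets[t].alive = false;
      freelist.push_back(t);
    }
    last_tet = fresh[0];
    return true;
  }
};

// deterministic hash in [-0.5, 0.5)
inline double hash_unit(std::uint64_t x) {
  x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return (double)(x >> 11) / 9007199254740992.0 - 0.5;
}

inline bool circumcenter(const double* a, const double* b, const double* c,
                         const double* d, double* cc) {
  double A[3][3], rhs[3];
  for (int i = 0; i < 3; ++i) {
    const double* q = (i == 0) ? b : (i == 1) ? c : d;
    for (int j = 0; j < 3; ++j) A[i][j] = 2.0 * (q[j] - a[j]);
    rhs[i] = q[0]*q[0]+q[1]*q[1]+q[2]*q[2] - (a[0]*a[0]+a[1]*a[1]+a[2]*a[2]);
  }
  // Cramer's rule
  double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
             - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
             + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  double scale = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(A[i][j]));
  if (std::fabs(det) < 1e-12 * scale * scale * scale) return false;
  for (int k = 0; k < 3; ++k) {
    double M[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) M[i][j] = (j == k) ? rhs[i] : A[i][j];
    double dk = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
              - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
              + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
    cc[k] = dk / det;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".delaunay3d")]]
List delaunay3d(NumericMatrix coords) {
  const int n = coords.nrow();
  if (n < 5) stop("need at least 5 points for a 3D tessellation");
  Delaunay D;
  D.npts = n;
  D.pts.resize((size_t)n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = coords(i, j);
      if (!R_finite(v)) stop("non-finite coordinate");
      lo[j] = std::min(lo[j], v);
      hi[j] = std::max(hi[j], v);
    }
  double diag = 0.0;
  for (int j = 0; j < 3; ++j) diag += (hi[j] - lo[j]) * (hi[j] - lo[j]);
  diag = std::sqrt(std::max(diag, 1e-6));
  const double jit = 1e-9 * diag;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j)
      D.pts[i][j] = coords(i, j) +
                    jit * hash_unit(((std::uint64_t)i << 2) | (std::uint64_t)j);
  // enclosing super tetrahedron
  double c0[3], K = 300.0 * diag + 1.0;
  for (int j = 0; j < 3; ++j) c0[j] = 0.5 * (lo[j] + hi[j]);
  const double sv[4][3] = {{K, K, K}, {K, -K, -K}, {-K, K, -K}, {-K, -K, K}};
  for (int s = 0; s < 4; ++s)
    for (int j = 0; j < 3; ++j) D.pts[(size_t)n + s][j] = c0[j] + sv[s][j];
  {
    int a = n, b = n + 1, c = n + 2, d = n + 3;
    if (orient3d(D.P(a), D.P(b), D.P(c), D.P(d)) < 0.0) std::swap(c, d);
    int t = D.new_tet();
    Tet& T = D.tets[t];
    T.v[0] = a; T.v[1] = b; T.v[2] = c; T.v[3] = d;
    for (int f = 0; f < 4; ++f) T.adj[f] = -1;
  }
  // insertion order: grid-bucketed for walk locality, deterministic
  std::vector<int> order(n);
  {
    const int G = 24;
    std::vector<std::pair<std::uint64_t, int>> keyed(n);
    for (int i = 0; i < n; ++i) {
      std::uint64_t kx = 0, ky = 0, kz = 0;
      if (hi[0] > lo[0]) kx = (std::uint64_t)((D.pts[i][0] - lo[0]) / (hi[0] - lo[0] + 1e-9) * G);
      if (hi[1] > lo[1]) ky = (std::uint64_t)((D.pts[i][1] - lo[1]) / (hi[1] - lo[1] + 1e-9) * G);
      if (hi[2] > lo[2]) kz = (std::uint64_t)((D.pts[i][2] - lo[2]) / (hi[2] - lo[2] + 1e-9) * G);
      keyed[i] = std::make_pair((kx << 42) | (ky << 21) | kz, i);
    }
    std::sort(keyed.begin(), keyed.end());
    for (int i = 0; i < n; ++i) order[i] = keyed[i].second;
  }
  for (int i = 0; i < n; ++i) {
    if (!D.insert(order[i])) ++D.skipped;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  // collect finite tets
  std::vector<int> fin;
  fin.reserve(D.tets.size());
  std::vector<int> tet_id(D.tets.size(), -1);
  for (int t = 0; t < (int)D.tets.size(); ++t) {
    if (!D.tets[t].alive) continue;
    bool finite_tet = true;
    for (int k = 0; k < 4; ++k)
      if (D.tets[t].v[k] >= n) { finite_tet = false; break; }
    if (finite_tet) {
      tet_id[t] = (int)fin.size();
      fin.push_back(t);
    }
  }
  const int nv = (int)fin.size();
  NumericMatrix vcoords(nv, 3);
  IntegerMatrix tetv(nv, 4);
  LogicalVector on_hull(nv);
  for (int i = 0; i < nv; ++i) {
    const Tet& T = D.tets[fin[i]];
    double cc[3];
    if (!circumcenter(D.P(T.v[0]), D.P(T.v[1]), D.P(T.v[2]), D.P(T.v[3]), cc)) {
      // sliver: fall back to the centroid (clearance computed honestly later)
      for (int j = 0; j < 3; ++j)
        cc[j] = 0.25 * (D.pts[T.v[0]][j] + D.pts[T.v[1]][j] +
                        D.pts[T.v[2]][j] + D.pts[T.v[3]][j]);
    }
    for (int j = 0; j < 3; ++j) vcoords(i, j) = cc[j];
    bool hull = false;
    for (int k = 0; k < 4; ++k) {
      tetv(i, k) = T.v[k] + 1;
      int u = T.adj[k];
      if (u < 0 || tet_id[u] < 0) hull = true;  // borders infinite region
    }
    on_hull[i] = hull;
  }
  // Voronoi edges: one per internal facet between finite tets
  std::vector<int> efrom, eto;
  efrom.reserve(nv * 2);
  eto.reserve(nv * 2);
  for (int i = 0; i < nv; ++i) {
    const Tet& T = D.tets[fin[i]];
    for (int k = 0; k < 4; ++k) {
      int u = T.adj[k];
      if (u < 0) continue;
      int j = tet_id[u];
      if (j > i) {
        efrom.push_back(i + 1);
        eto.push_back(j + 1);
      }
    }
  }
  IntegerMatrix edges((int)efrom.size(), 2);
  for (int e = 0; e < (int)efrom.size(); ++e) {
    edges(e, 0) = efrom[e];
    edges(e, 1) = eto[e];
  }
  return List::create(_["vertices"] = vcoords, _["tets"] = tetv,
                      _["edges"] = edges, _["on_hull"] = on_hull,
                      _["skipped"] = D.skipped);
}
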