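// Steric scoring of rigid ligand poses and restrained on-disc pose
// optimization.  The score is a capped 12-6 potential over ligand/receptor
// atom pairs within a fixed cutoff; pose search minimizes over 5 degrees of
// freedom (2 in-plane anchor coordinates, 3 rotation-vector components) with
// Nelder-Mead restarts supplied by the caller.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Quat {
  double w, x, y, z;
};

inline Quat quat_mul(const Quat& a, const Quat& b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}

inline Quat quat_from_rotvec(double rx, double ry, double rz) {
  double a = std::sqrt(rx * rx + ry * ry + rz * rz);
  if (a < 1e-12) return {1.0, 0.5 * rx, 0.5 * ry, 0.5 * rz};
  double s = std::sin(0.5 * a) / a;
  return {std::cos(0.5 * a), s * rx, s * ry, s * rz};
}

inline void quat_rotate(const Quat& q, const double* v, double* out) {
  // R(q) v via q * (0,v) * conj(q)
  double tx = 2.0 * (q.y * v[2] - q.z * v[1]);
  double ty = 2.0 * (q.z * v[0] - q.x * v[2]);
  double tz = 2.0 * (q.x * v[1] - q.y * v[0]);
  out[0] = v[0] + q.w * tx + (q.y * tz - q.z * ty);
  out[1] = v[1] + q.w * ty + (q.z * tx - q.x * tz);
  out[2] = v[2] + q.w * tz + (q.x * ty - q.y * tx);
}

// angular distance between two unit quaternions, radians in [0, pi]
inline double quat_angle(const Quat& a, const Quat& b) {
  double dot = std::fabs(a.w * b.w + a.x * b.x + a.y * b.y + a.z * b.z);
  dot = std::min(1.0, dot);
  return 2.0 * std::acos(dot);
}

struct Scorer {
  const double* lx;  // ligand local coords (anchor at origin), nl x 3 col-major
  int nl;
  const double* lr;
  const double* rx;  // receptor coords, nr x 3 col-major
  int nr;
  const double* rr;
  double cutoff2, eps, cap;

  double score(const Quat& q, const double* t) const {
    double e = 0.0;
    for (int i = 0; i < nl; ++i) {
      double loc[3] = {lx[i], lx[i + nl], lx[i + 2 * nl]};
      double g[3];
      quat_rotate(q, loc, g);
      g[0] += t[0]; g[1] += t[1]; g[2] += t[2];
      for (int j = 0; j < nr; ++j) {
        double dx = g[0] - rx[j], dy = g[1] - rx[j + nr], dz = g[2] - rx[j + 2 * nr];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > cutoff2) continue;
        double s = lr[i] + rr[j];
        double sd2 = (s * s) / std::max(d2, 1e-12);
        double sd6 = sd2 * sd2 * sd2;
        double pe = eps * (sd6 * sd6 - 2.0 * sd6);
        e += (pe > cap) ? cap : pe;
      }
    }
    return e;
  }
};

struct DiscFrame {
  double c[3], n[3], e1[3], e2[3], radius;
};

struct Objective {
  const Scorer* sc;
  const DiscFrame* disc;
  Quat q0;              // base rotation (chained init or identity)
  double max_rot;       // radians; <0 means unconstrained
  double penalty = 1e4;

  double operator()(const double* par) const {
    double u = par[0], v = par[1];
    Quat q = quat_mul(q0, quat_from_rotvec(par[2], par[3], par[4]));
    double nq = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
    q.w /= nq; q.x /= nq; q.y /= nq; q.z /= nq;
    double t[3];
    for (int j = 0; j < 3; ++j)
      t[j] = disc->c[j] + u * disc->e1[j] + v * disc->e2[j];
    double e = sc->score(q, t);
    double rad = std::sqrt(u * u + v * v);
    if (rad > disc->radius) {
      double ex = rad - disc->radius;
      e += penalty * ex * ex;
    }
    if (max_rot >= 0.0) {
      double ang = std::sqrt(par[2] * par[2] + par[3] * par[3] + par[4] * par[4]);
      if (ang > max_rot) {
        double ex = ang - max_rot;
        e += penalty * ex * ex;
      }
    }
    return e;
  }
};

const int NP = 5;

// deterministic Nelder-Mead over 5 parameters
double nelder_mead(const Objective& f, double* x, const double* step, int maxit) {
  double simplex[NP + 1][NP];
  double fv[NP + 1];
  for (int i = 0; i <= NP; ++i) {
    for (int j = 0; j < NP; ++j) simplex[i][j] = x[j];
    if (i > 0) simplex[i][i - 1] += step[i - 1];
    fv[i] = f(simplex[i]);
  }
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  for (int it = 0; it < maxit; ++it) {
    int order[NP + 1];
    for (int i = 0; i <= NP; ++i) order[i] = i;
    std::sort(order, order + NP + 1,
              [&](int a, int b) { return fv[a] < fv[b]; });
    double tmp[NP + 1][NP], tf[NP + 1];
    for (int i = 0; i <= NP; ++i) {
      for (int j = 0; j < NP; ++j) tmp[i][j] = simplex[order[i]][j];
      tf[i] = fv[order[i]];
    }
    for (int i = 0; i <= NP; ++i) {
      for (int j = 0; j < NP; ++j) simplex[i][j] = tmp[i][j];
      fv[i] = tf[i];
    }
    if (fv[NP] - fv[0] < 1e-10 * (std::fabs(fv[0]) + 1e-8)) break;
    double cen[NP] = {0, 0, 0, 0, 0};
    for (int i = 0; i < NP; ++i)
      for (int j = 0; j < NP; ++j) cen[j] += simplex[i][j] / NP;
    double xr[NP];
    for (int j = 0; j < NP; ++j) xr[j] = cen[j] + alpha * (cen[j] - simplex[NP][j]);
    double fr = f(xr);
    if (fr < fv[0]) {
      double xe[NP];
      for (int j = 0; j < NP; ++j) xe[j] = cen[j] + gamma * (xr[j] - cen[j]);
      double fe = f(xe);
      if (fe < fr) {
        for (int j = 0; j < NP; ++j) simplex[NP][j] = xe[j];
        fv[NP] = fe;
      } else {
        for (int j = 0; j < NP; ++j) simplex[NP][j] = xr[j];
        fv[NP] = fr;
      }
    } else if (fr < fv[NP - 1]) {
      for (int j = 0; j < NP; ++j) simplex[NP][j] = xr[j];
      fv[NP] = fr;
    } else {
      double xc[NP];
      bool outside = fr < fv[NP];
      const double* base = outside ? xr : simplex[NP];
      for (int j = 0; j < NP; ++j) xc[j] = cen[j] + rho * (base[j] - cen[j]);
      double fc = f(xc);
      if (fc < std::min(fr, fv[NP])) {
        for (int j = 0; j < NP; ++j) simplex[NP][j] = xc[j];
        fv[NP] = fc;
      } else {
        for (int i = 1; i <= NP; ++i) {
          for (int j = 0; j < NP; ++j)
            simplex[i][j] = simplex[0][j] + sigma * (simplex[i][j] - simplex[0][j]);
          fv[i] = f(simplex[i]);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i <= NP; ++i)
    if (fv[i] < fv[best]) best = i;
  for (int j = 0; j < NP; ++j) x[j] = simplex[best][j];
  return fv[best];
}

}  // namespace

// [[Rcpp::export(name = ".lj_score")]]
double lj_score(NumericMatrix lig_xyz, NumericVector lig_r,
                NumericMatrix rec_xyz, NumericVector rec_r, double cutoff,
                double eps, double cap) {
  if (rec_xyz.nrow() == 0 || lig_xyz.nrow() == 0) return 0.0;
  Scorer sc{REAL(lig_xyz), (int)lig_xyz.nrow(), REAL(lig_r),
            REAL(rec_xyz), (int)rec_xyz.nrow(), REAL(rec_r),
            cutoff * cutoff, eps, cap};
  Quat id{1, 0, 0, 0};
  double t[3] = {0, 0, 0};
  // lig_xyz is used as-is (pose already applied): rotate by identity about 0
  return sc.score(id, t);
}

// starts: n_starts x 5 matrix of initial (u, v, rx, ry, rz); an all-zero row
// continues from the base pose.  Returns the best pose after local refinement
// of every start.
// [[Rcpp::export(name = ".optimize_disc")]]
List optimize_disc(NumericMatrix lig_local, NumericVector lig_r,
                   NumericMatrix rec_xyz, NumericVector rec_r,
                   NumericVector disc_center, NumericVector disc_normal,
                   NumericVector disc_e1, NumericVector disc_e2,
                   double disc_radius, NumericMatrix starts,
                   NumericVector init_quat, double max_rotation_deg,
                   double cutoff, double eps, double cap, int maxit) {
  Scorer sc{REAL(lig_local), (int)lig_local.nrow(), REAL(lig_r),
            REAL(rec_xyz), (int)rec_xyz.nrow(), REAL(rec_r),
            cutoff * cutoff, eps, cap};
  DiscFrame disc;
  for (int j = 0; j < 3; ++j) {
    disc.c[j] = disc_center[j];
    disc.n[j] = disc_normal[j];
    disc.e1[j] = disc_e1[j];
    disc.e2[j] = disc_e2[j];
  }
  disc.radius = disc_radius;
  Objective obj;
  obj.sc = &sc;
  obj.disc = &disc;
  obj.q0 = {init_quat[0], init_quat[1], init_quat[2], init_quat[3]};
  obj.max_rot = max_rotation_deg >= 0 ? max_rotation_deg * M_PI / 180.0 : -1.0;
  const double step[NP] = {0.5, 0.5, 0.3, 0.3, 0.3};
  double best_par[NP] = {0, 0, 0, 0, 0};
  double best_f = R_PosInf;
  for (int s = 0; s < starts.nrow(); ++s) {
    double x[NP];
    for (int j = 0; j < NP; ++j) x[j] = starts(s, j);
    double fx = nelder_mead(obj, x, step, maxit);
    if (fx < best_f) {
      best_f = fx;
      for (int j = 0; j < NP; ++j) best_par[j] = x[j];
    }
  }
  // project into the feasible set and report the pure (unpenalized) score
  double rad = std::sqrt(best_par[0] * best_par[0] + best_par[1] * best_par[1]);
  if (rad > disc.radius && rad > 0) {
    best_par[0] *= disc.radius / rad;
    best_par[1] *= disc.radius / rad;
  }
  double ang = std::sqrt(best_par[2] * best_par[2] + best_par[3] * best_par[3] +
                         best_par[4] * best_par[4]);
  if (obj.max_rot >= 0 && ang > obj.max_rot && ang > 0) {
    double f = obj.max_rot / ang;
    best_par[2] *= f; best_par[3] *= f; best_par[4] *= f;
  }
  Quat q = quat_mul(obj.q0,
                    quat_from_rotvec(best_par[2], best_par[3], best_par[4]));
  double nq = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  q.w /= nq; q.x /= nq; q.y /= nq; q.z /= nq;
  if (q.w < 0) { q.w = -q.w; q.x = -q.x; q.y = -q.y; q.z = -q.z; }
  double t[3];
  for (int j = 0; j < 3; ++j)
    t[j] = disc.c[j] + best_par[0] * disc.e1[j] + best_par[1] * disc.e2[j];
  double energy = sc.score(q, t);
  return List::create(
      _["energy"] = energy,
      _["anchor"] = NumericVector::create(t[0], t[1], t[2]),
      _["quat"] = NumericVector::create(q.w, q.x, q.y, q.z),
      _["par"] = NumericVector::create(best_par[0], best_par[1], best_par[2],
                                       best_par[3], best_par[4]));
}

// [[Rcpp::export(name = ".quat_angle_deg")]]
double quat_angle_deg(NumericVector a, NumericVector b) {
  Quat qa{a[0], a[1], a[2], a[3]}, qb{b[0], b[1], b[2], b[3]};
  return quat_angle(qa, qb) * 180.0 / M_PI;
}

// apply pose (quaternion + anchor translation) to local coords
// [[Rcpp::export(name = ".apply_pose")]]
NumericMatrix apply_pose(NumericMatrix lig_local, NumericVector quat,
                         NumericVector anchor) {
  Quat q{quat[0], quat[1], quat[2], quat[3]};
  const int n = lig_local.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double loc[3] = {lig_local(i, 0), lig_local(i, 1), lig_local(i, 2)};
    double g[3];
    quat_rotate(q, loc, g);
    for (int j = 0; j < 3; ++j) out(i, j) = g[j] + anchor[j];
  }
  return out;
}
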