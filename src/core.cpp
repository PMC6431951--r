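// Compiled kernels: pairwise forces/energies for the Kremer-Grest chain,
// underdamped Langevin integration, zero-temperature relaxation, KMT chain
// reduction, planar crossing-diagram extraction and the Gauss-integral writhe.
// Positions are N x 3 matrices in reduced (sigma) units; bead 0 and bead N-1
// are tethered and never move.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double eps, sigma, kfene, R0, kb, L, wall_eps, wall_sigma;
};

Params unpack(const List& p) {
  Params q;
  q.eps = as<double>(p["epsilon"]);
  q.sigma = as<double>(p["sigma"]);
  q.kfene = as<double>(p["kappa_fene"]);
  q.R0 = as<double>(p["R0"]);
  q.kb = as<double>(p["kappa_b"]);
  q.L = as<double>(p["L_wall"]);
  q.wall_eps = as<double>(p["wall_eps"]);
  q.wall_sigma = as<double>(p["wall_sigma"]);
  return q;
}

// status codes for force evaluation / integration
const int OK = 0, BOND_OVERSTRETCH = 1, WALL_PENETRATION = 2, NOT_FINITE = 3,
          ZERO_BOND = 4;

// Repulsive-only LJ 9-3 wall, truncated and shifted at its minimum
// d_cut = (2/5)^(1/6) sw, shift sqrt(10)/3 so U and dU/dd vanish at d_cut.
inline double wall_u(double d, double ew, double sw, double* fmag) {
  const double dcut = std::pow(0.4, 1.0 / 6.0) * sw;
  if (d >= dcut) { if (fmag) *fmag = 0.0; return 0.0; }
  double t3 = sw / d; t3 = t3 * t3 * t3;
  double t9 = t3 * t3 * t3;
  if (fmag) *fmag = ew * (1.2 * t9 - 3.0 * t3) / d;  // -dU/dd (repulsive > 0)
  return ew * ((2.0 / 15.0) * t9 - t3 + std::sqrt(10.0) / 3.0);
}

// Consolidated energy/force evaluation. F may be null (energy only).
// Returns status; on failure *bad_index holds the offending bead/bond.
int eval_system(const double* x, int N, const Params& q, double* F,
                double* e_wca, double* e_fene, double* e_bend, double* e_wall,
                int* bad_index) {
  const double rc2 = std::pow(2.0, 1.0 / 3.0) * q.sigma * q.sigma;
  const double s2 = q.sigma * q.sigma;
  const double R02 = q.R0 * q.R0;
  double Ewca = 0, Efene = 0, Ebend = 0, Ewall = 0;
  if (F) std::fill(F, F + 3 * N, 0.0);

  // WCA over all distinct pairs (bonded pairs included)
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (r2 <= 0) { if (bad_index) *bad_index = i; return ZERO_BOND; }
      double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      Ewca += 4.0 * q.eps * (sr12 - sr6 + 0.25);
      if (F) {
        double fr = 24.0 * q.eps * (2.0 * sr12 - sr6) / r2;
        F[3 * i] += fr * dx;     F[3 * j] -= fr * dx;
        F[3 * i + 1] += fr * dy; F[3 * j + 1] -= fr * dy;
        F[3 * i + 2] += fr * dz; F[3 * j + 2] -= fr * dz;
      }
    }
  }

  // FENE bonds
  for (int i = 0; i < N - 1; ++i) {
    double dx = x[3 * (i + 1)] - x[3 * i];
    double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
    double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
    double b2 = dx * dx + dy * dy + dz * dz;
    if (b2 >= R02) { if (bad_index) *bad_index = i; return BOND_OVERSTRETCH; }
    if (b2 <= 0) { if (bad_index) *bad_index = i; return ZERO_BOND; }
    double om = 1.0 - b2 / R02;
    Efene += -0.5 * q.kfene * R02 * std::log(om);
    if (F) {
      double fr = -q.kfene / om;  // force/|b| on bead i+1 along +bond is fr*b
      F[3 * (i + 1)] += fr * dx;     F[3 * i] -= fr * dx;
      F[3 * (i + 1) + 1] += fr * dy; F[3 * i + 1] -= fr * dy;
      F[3 * (i + 1) + 2] += fr * dz; F[3 * i + 2] -= fr * dz;
    }
  }

  // Bending: kb * (1 - cos(phi_i)) at interior joints
  for (int i = 1; i < N - 1; ++i) {
    double A[3] = { x[3 * i] - x[3 * (i - 1)],
                    x[3 * i + 1] - x[3 * (i - 1) + 1],
                    x[3 * i + 2] - x[3 * (i - 1) + 2] };
    double B[3] = { x[3 * (i + 1)] - x[3 * i],
                    x[3 * (i + 1) + 1] - x[3 * i + 1],
                    x[3 * (i + 1) + 2] - x[3 * i + 2] };
    double a2 = A[0] * A[0] + A[1] * A[1] + A[2] * A[2];
    double b2 = B[0] * B[0] + B[1] * B[1] + B[2] * B[2];
    if (a2 <= 0 || b2 <= 0) { if (bad_index) *bad_index = i; return ZERO_BOND; }
    double a = std::sqrt(a2), b = std::sqrt(b2);
    double dot = A[0] * B[0] + A[1] * B[1] + A[2] * B[2];
    double c = dot / (a * b);
    Ebend += q.kb * (1.0 - c);
    if (F) {
      double dA[3], dB[3];  // d(cos)/dA, d(cos)/dB
      for (int k = 0; k < 3; ++k) {
        dA[k] = B[k] / (a * b) - c * A[k] / a2;
        dB[k] = A[k] / (a * b) - c * B[k] / b2;
      }
      for (int k = 0; k < 3; ++k) {
        F[3 * (i - 1) + k] += -q.kb * dA[k];
        F[3 * (i + 1) + k] += q.kb * dB[k];
        F[3 * i + k] += q.kb * (dA[k] - dB[k]);
      }
    }
  }

  // Walls at x = 0 and x = L, interior beads only
  for (int i = 1; i < N - 1; ++i) {
    double d1 = x[3 * i], d2 = q.L - x[3 * i];
    if (d1 <= 0 || d2 <= 0) { if (bad_index) *bad_index = i; return WALL_PENETRATION; }
    double f1, f2;
    Ewall += wall_u(d1, q.wall_eps, q.wall_sigma, &f1);
    Ewall += wall_u(d2, q.wall_eps, q.wall_sigma, &f2);
    if (F) F[3 * i] += f1 - f2;
  }

  if (!std::isfinite(Ewca + Efene + Ebend + Ewall)) return NOT_FINITE;
  *e_wca = Ewca; *e_fene = Efene; *e_bend = Ebend; *e_wall = Ewall;
  return OK;
}

}  // namespace

// [[Rcpp::export(name = ".energy_cpp")]]
List energy_cpp(NumericMatrix pos, List params) {
  Params q = unpack(params);
  int N = pos.nrow(), bad = -1;
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  double ew, ef, eb, ewl;
  int st = eval_system(x.data(), N, q, nullptr, &ew, &ef, &eb, &ewl, &bad);
  return List::create(_["status"] = st, _["bad_index"] = bad + 1,
                      _["wca"] = ew, _["fene"] = ef, _["bending"] = eb,
                      _["walls"] = ewl);
}

// [[Rcpp::export(name = ".forces_cpp")]]
List forces_cpp(NumericMatrix pos, List params) {
  Params q = unpack(params);
  int N = pos.nrow(), bad = -1;
  std::vector<double> x(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  double ew, ef, eb, ewl;
  int st = eval_system(x.data(), N, q, F.data(), &ew, &ef, &eb, &ewl, &bad);
  NumericMatrix Fout(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) Fout(i, k) = F[3 * i + k];
  return List::create(_["status"] = st, _["bad_index"] = bad + 1,
                      _["forces"] = Fout);
}

// Underdamped Langevin dynamics (velocity-Verlet with LAMMPS-style
// friction + Gaussian kick entering the force). gamma = m / tau_frict;
// gamma = 0 and kT = 0 gives plain symplectic velocity Verlet.
// [[Rcpp::export(name = ".langevin_cpp")]]
List langevin_cpp(NumericMatrix pos, NumericMatrix vel, List params,
                  int n_equil, int n_steps, int sample_every, double dt,
                  double mass, double gamma, double kT, int seed,
                  bool store_velocities, bool thermostat) {
  Params q = unpack(params);
  int N = pos.nrow(), bad = -1;
  std::vector<double> x(3 * N), v(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = pos(i, k);
      v[3 * i + k] = vel(i, k);
    }
  // tethered termini never move
  for (int k = 0; k < 3; ++k) { v[k] = 0.0; v[3 * (N - 1) + k] = 0.0; }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double noise_sd =
      thermostat ? std::sqrt(2.0 * gamma * mass * kT / dt) : 0.0;

  int n_frames = sample_every > 0 ? n_steps / sample_every : 0;
  NumericVector frames(Dimension(n_frames, N, 3));
  NumericVector vels(store_velocities ? Dimension(n_frames, N, 3)
                                      : Dimension(0, 0, 0));
  NumericVector pe(n_frames), ke(n_frames);

  double ew, ef, eb, ewl;
  int st = eval_system(x.data(), N, q, F.data(), &ew, &ef, &eb, &ewl, &bad);
  if (st != OK)
    return List::create(_["status"] = st, _["bad_index"] = bad + 1,
                        _["step"] = 0);
  auto add_langevin = [&]() {
    if (!thermostat) return;
    for (int i = 1; i < N - 1; ++i)
      for (int k = 0; k < 3; ++k)
        F[3 * i + k] += -gamma * mass * v[3 * i + k] + noise_sd * gauss(rng);
  };
  add_langevin();

  long total = static_cast<long>(n_equil) + n_steps;
  int frame = 0;
  for (long step = 1; step <= total; ++step) {
    for (int i = 1; i < N - 1; ++i)
      for (int k = 0; k < 3; ++k) {
        v[3 * i + k] += 0.5 * dt * F[3 * i + k] / mass;
        x[3 * i + k] += dt * v[3 * i + k];
      }
    st = eval_system(x.data(), N, q, F.data(), &ew, &ef, &eb, &ewl, &bad);
    if (st != OK)
      return List::create(_["status"] = st, _["bad_index"] = bad + 1,
                          _["step"] = (double)step);
    add_langevin();
    for (int i = 1; i < N - 1; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] += 0.5 * dt * F[3 * i + k] / mass;

    long prod = step - n_equil;
    if (prod > 0 && sample_every > 0 && prod % sample_every == 0 &&
        frame < n_frames) {
      double kin = 0;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k) {
          frames[frame + n_frames * (i + (long)N * k)] = x[3 * i + k];
          if (store_velocities)
            vels[frame + n_frames * (i + (long)N * k)] = v[3 * i + k];
          kin += 0.5 * mass * v[3 * i + k] * v[3 * i + k];
        }
      pe[frame] = ew + ef + eb + ewl;
      ke[frame] = kin;
      ++frame;
    }
  }

  NumericMatrix xout(N, 3), vout(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      xout(i, k) = x[3 * i + k];
      vout(i, k) = v[3 * i + k];
    }
  return List::create(_["status"] = OK, _["frames"] = frames,
                      _["velocities"] = vels, _["pe"] = pe, _["ke"] = ke,
                      _["final_pos"] = xout, _["final_vel"] = vout,
                      _["n_frames"] = frame);
}

// Zero-temperature relaxation: steepest descent with backtracking line
// search; termini frozen; step capped so no bond can jump past R0.
// [[Rcpp::export(name = ".minimize_cpp")]]
List minimize_cpp(NumericMatrix pos, List params, int max_iter, double ftol) {
  Params q = unpack(params);
  int N = pos.nrow(), bad = -1;
  std::vector<double> x(3 * N), F(3 * N), xt(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  double ew, ef, eb, ewl;
  int st = eval_system(x.data(), N, q, F.data(), &ew, &ef, &eb, &ewl, &bad);
  if (st != OK)
    return List::create(_["status"] = st, _["bad_index"] = bad + 1);
  double E = ew + ef + eb + ewl;
  double alpha = 1e-4;
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    double fmax = 0;
    for (int i = 1; i < N - 1; ++i)
      for (int k = 0; k < 3; ++k)
        fmax = std::max(fmax, std::fabs(F[3 * i + k]));
    if (fmax < ftol) break;
    // cap displacement at 0.05 sigma
    double amax = 0.05 * q.sigma / std::max(fmax, 1e-12);
    double a = std::min(alpha, amax);
    bool accepted = false;
    for (int bt = 0; bt < 30; ++bt) {
      xt = x;
      for (int i = 1; i < N - 1; ++i)
        for (int k = 0; k < 3; ++k) xt[3 * i + k] += a * F[3 * i + k];
      double ew2, ef2, eb2, ewl2;
      std::vector<double> F2(3 * N);
      int st2 = eval_system(xt.data(), N, q, F2.data(), &ew2, &ef2, &eb2,
                            &ewl2, &bad);
      double E2 = ew2 + ef2 + eb2 + ewl2;
      if (st2 == OK && E2 <= E) {
        x.swap(xt); F.swap(F2); E = E2;
        alpha = a * 1.2; accepted = true;
        break;
      }
      a *= 0.5;
    }
    ++iters;
    if (!accepted) break;
  }
  NumericMatrix xout(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) xout(i, k) = x[3 * i + k];
  return List::create(_["status"] = OK, _["pos"] = xout, _["energy"] = E,
                      _["iterations"] = iters);
}

namespace {

// does segment (p,q) intersect triangle (a,b,c)? Tolerant Moller-Trumbore;
// near-touching counts as intersecting (conservative for KMT removal).
bool seg_hits_tri(const double* p, const double* r, const double* a,
                  const double* b, const double* c) {
  double e1[3], e2[3], d[3], h[3], s[3], qv[3];
  for (int k = 0; k < 3; ++k) {
    e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; d[k] = r[k] - p[k];
  }
  h[0] = d[1] * e2[2] - d[2] * e2[1];
  h[1] = d[2] * e2[0] - d[0] * e2[2];
  h[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * h[0] + e1[1] * h[1] + e1[2] * h[2];
  if (std::fabs(det) < 1e-12) return false;  // parallel: generic configs ok
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) s[k] = p[k] - a[k];
  double u = (s[0] * h[0] + s[1] * h[1] + s[2] * h[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return false;
  qv[0] = s[1] * e1[2] - s[2] * e1[1];
  qv[1] = s[2] * e1[0] - s[0] * e1[2];
  qv[2] = s[0] * e1[1] - s[1] * e1[0];
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return false;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return t > -1e-9 && t < 1.0 + 1e-9;
}

}  // namespace

// Koniaris-Muthukumar-Taylor reduction: repeatedly delete a vertex whose
// elimination triangle is not pierced by any other segment. Preserves the
// (closure) topology; endpoints of open chains are kept.
// [[Rcpp::export(name = ".kmt_cpp")]]
NumericMatrix kmt_cpp(NumericMatrix verts, bool closed) {
  int n = verts.nrow();
  std::vector<std::array<double, 3>> v(n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) v[i][k] = verts(i, k);

  bool changed = true;
  while (changed && (int)v.size() > (closed ? 3 : 3)) {
    changed = false;
    int m = v.size();
    int lo = closed ? 0 : 1;
    int hi = closed ? m : m - 1;
    for (int i = lo; i < hi && (int)v.size() > 3; ++i) {
      m = v.size();
      if (i >= m || (!closed && (i == 0 || i == m - 1))) continue;
      int ip = (i - 1 + m) % m, in = (i + 1) % m;
      if (!closed && (i == 0 || i == m - 1)) continue;
      const double *a = v[ip].data(), *b = v[i].data(), *c = v[in].data();
      bool blocked = false;
      int nseg = closed ? m : m - 1;
      for (int s = 0; s < nseg && !blocked; ++s) {
        int s2 = (s + 1) % m;
        // skip segments adjacent to the triangle
        if (s == ip || s == i || s2 == ip || s2 == i || s2 == in || s == in)
          continue;
        if (seg_hits_tri(v[s].data(), v[s2].data(), a, b, c)) blocked = true;
      }
      if (!blocked) {
        v.erase(v.begin() + i);
        --i;
        changed = true;
      }
    }
  }
  NumericMatrix out(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = v[i][k];
  return out;
}

// Crossing diagram of a closed polygon under projection with rotation R:
// project rotated coords, find strict interior intersections of non-adjacent
// segments. Returns matrix with rows (s_over, s_under, sign) where s = curve
// position (segment index + parameter, 0-based), or a 1x1 matrix of NA if the
// projection is degenerate and must be retried.
// [[Rcpp::export(name = ".crossings_cpp")]]
NumericMatrix crossings_cpp(NumericMatrix verts, NumericMatrix rot) {
  int n = verts.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    double a = verts(i, 0), b = verts(i, 1), c = verts(i, 2);
    px[i] = a * rot(0, 0) + b * rot(1, 0) + c * rot(2, 0);
    py[i] = a * rot(0, 1) + b * rot(1, 1) + c * rot(2, 1);
    pz[i] = a * rot(0, 2) + b * rot(1, 2) + c * rot(2, 2);
  }
  const double tol = 1e-9;
  std::vector<std::array<double, 3>> rows;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double ax = px[i], ay = py[i];
    double bx = px[i2] - ax, by = py[i2] - ay;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue;  // adjacent
      double cx = px[j], cy = py[j];
      double dx = px[j2] - cx, dy = py[j2] - cy;
      double den = bx * dy - by * dx;
      double ex = cx - ax, ey = cy - ay;
      if (std::fabs(den) < tol * (std::fabs(bx * dy) + std::fabs(by * dx) + tol)) {
        // parallel in projection: only a problem if they overlap; check
        // whether endpoints of one are near the other's line
        double cross1 = bx * ey - by * ex;
        double n2 = bx * bx + by * by;
        if (cross1 * cross1 < 1e-18 * n2) {
          NumericMatrix bad(1, 1); bad(0, 0) = NA_REAL; return bad;
        }
        continue;
      }
      double t = (ex * dy - ey * dx) / den;
      double u = (ex * by - ey * bx) / den;
      if (t <= tol || t >= 1 - tol || u <= tol || u >= 1 - tol) {
        if ((t > -tol && t < 1 + tol) && (u > -tol && u < 1 + tol)) {
          // grazing intersection: degenerate projection
          if (!(t <= -tol || t >= 1 + tol || u <= -tol || u >= 1 + tol)) {
            NumericMatrix bad(1, 1); bad(0, 0) = NA_REAL; return bad;
          }
        }
        continue;
      }
      double zi = pz[i] + t * (pz[i2] - pz[i]);
      double zj = pz[j] + u * (pz[j2] - pz[j]);
      if (std::fabs(zi - zj) < 1e-9) {
        NumericMatrix bad(1, 1); bad(0, 0) = NA_REAL; return bad;
      }
      // sign from 2D cross of (over direction) x (under direction)
      double cr = bx * dy - by * dx;  // dir_i x dir_j
      double s_i = i + t, s_j = j + u;
      double sgn, s_over, s_under;
      if (zi > zj) {  // segment i passes over
        s_over = s_i; s_under = s_j;
        sgn = cr > 0 ? 1.0 : -1.0;
      } else {
        s_over = s_j; s_under = s_i;
        sgn = cr > 0 ? -1.0 : 1.0;  // cross(dj, di) = -cross(di, dj)
      }
      rows.push_back({s_over, s_under, sgn});
    }
  }
  NumericMatrix out(rows.size(), 3);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int k = 0; k < 3; ++k) out(r, k) = rows[r][k];
  return out;
}

// Gauss-integral writhe of a closed polygon (Levitt's exact segment-pair
// solid-angle formula). Sign convention: right-handed trefoil -> +3.4.
// [[Rcpp::export(name = ".writhe_cpp")]]
double writhe_cpp(NumericMatrix verts) {
  int n = verts.nrow();
  auto P = [&](int i, int k) { return verts(i % n, k); };
  double wr = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent through wrap
      double p1[3], p2[3], p3[3], p4[3];
      for (int k = 0; k < 3; ++k) {
        p1[k] = P(i, k); p2[k] = P(i + 1, k);
        p3[k] = P(j, k); p4[k] = P(j + 1, k);
      }
      double r13[3], r14[3], r23[3], r24[3], r34[3], r12[3];
      for (int k = 0; k < 3; ++k) {
        r13[k] = p3[k] - p1[k]; r14[k] = p4[k] - p1[k];
        r23[k] = p3[k] - p2[k]; r24[k] = p4[k] - p2[k];
        r34[k] = p4[k] - p3[k]; r12[k] = p2[k] - p1[k];
      }
      auto cross = [](const double* a, const double* b, double* c) {
        c[0] = a[1] * b[2] - a[2] * b[1];
        c[1] = a[2] * b[0] - a[0] * b[2];
        c[2] = a[0] * b[1] - a[1] * b[0];
      };
      auto norm3 = [](double* a) {
        double s = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
        if (s > 1e-14) { a[0] /= s; a[1] /= s; a[2] /= s; }
        else { a[0] = a[1] = a[2] = 0; }
      };
      double n1[3], n2[3], n3[3], n4[3];
      cross(r13, r14, n1); norm3(n1);
      cross(r14, r24, n2); norm3(n2);
      cross(r24, r23, n3); norm3(n3);
      cross(r23, r13, n4); norm3(n4);
      auto dotc = [](const double* a, const double* b) {
        double d = a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
        return std::max(-1.0, std::min(1.0, d));
      };
      double omega = std::asin(dotc(n1, n2)) + std::asin(dotc(n2, n3)) +
                     std::asin(dotc(n3, n4)) + std::asin(dotc(n4, n1));
      double cr[3];
      cross(r34, r12, cr);
      double sgn = cr[0] * r13[0] + cr[1] * r13[1] + cr[2] * r13[2];
      wr += omega * (sgn >= 0 ? 1.0 : -1.0) / (4.0 * M_PI) * 2.0;
    }
  }
  return wr;
}
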