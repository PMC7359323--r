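// Soft-sphere DEM core: Hertz-Mindlin contacts with simplified-JKR cohesion,
// velocity-Verlet integration, cell-list neighbour search, kinematic walls
// (flat-bottomed cylinder + rotating flat blades).
//
// Deterministic: no random numbers are drawn here; identical inputs give
// identical trajectories.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstdio>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};

inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
inline V3 operator+(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator-(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator*(double s, V3 a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

inline uint64_t pair_key(int i, int j) {
  if (i > j) std::swap(i, j);
  return (static_cast<uint64_t>(i) << 32) | static_cast<uint32_t>(j);
}

struct TangHist {
  V3 xi;        // accumulated tangential spring displacement
  long last;    // last step this contact was active
};

struct Model {
  double Estar;      // effective Young's modulus (identical materials both sides)
  double Gstar;      // effective shear modulus
  double beta;       // damping ratio from restitution
  double mu;         // Coulomb friction coefficient
  double gamma_coh;  // cohesive energy density (J/m^3), SJKR
};

// Hertz-Mindlin force between a particle and a counterpart (particle or wall).
// n: unit normal pointing toward particle i; delta: overlap (>0);
// vrel: velocity of i relative to counterpart at the contact point (including spin);
// Rstar, mstar: effective radius/mass. Returns force on i; tangential part via hist.
inline V3 contact_force(const Model& M, V3 n, double delta, V3 vrel, double Rstar,
                        double mstar, double dt, TangHist& h, long step_now,
                        double* fn_out) {
  const double sqRd = std::sqrt(Rstar * delta);
  const double Sn = 2.0 * M.Estar * sqRd;
  const double St = 8.0 * M.Gstar * sqRd;
  const double kn_force = (4.0 / 3.0) * M.Estar * std::sqrt(Rstar) * delta * std::sqrt(delta);
  // beta = ln e / sqrt(ln^2 e + pi^2) is negative for e < 1; the dashpot
  // coefficient must be positive (dissipative)
  const double gam_n = -2.0 * std::sqrt(5.0 / 6.0) * M.beta * std::sqrt(Sn * mstar);
  const double gam_t = -2.0 * std::sqrt(5.0 / 6.0) * M.beta * std::sqrt(St * mstar);

  const double vn = dot(vrel, n);  // >0 means separating
  // the dashpot may briefly make the net normal force tensile at the end of a
  // collision; the beta calibration assumes this unclamped form
  const double fn = kn_force - gam_n * vn;

  // SJKR cohesion: attractive, proportional to contact area pi*delta*Rstar
  const double fcoh = M.gamma_coh * M_PI * delta * Rstar;

  // tangential: Mindlin spring with history, Coulomb-capped by the dry normal force
  V3 vt = vrel - vn * n;
  if (h.last != step_now - 1) h.xi = v3(0, 0, 0);  // stale contact: new spring
  h.xi = h.xi + dt * vt;
  h.xi = h.xi - dot(h.xi, n) * n;  // keep the spring in the tangent plane
  V3 ft = (-St) * h.xi - gam_t * vt;
  const double ftmag = norm(ft);
  const double fcap = M.mu * std::fabs(fn);
  if (ftmag > fcap && ftmag > 0.0) {
    ft = (fcap / ftmag) * ft;
    h.xi = (-1.0 / St) * ft;  // slip: spring relaxed onto the Coulomb cone
  }
  h.last = step_now;
  *fn_out = fn;
  return (fn - fcoh) * n + ft;
}

}  // namespace

// Runs nsteps of DEM and records a snapshot every snap_every steps (step 0
// included). Walls are skipped when vessel_radius is non-finite; blades when
// blade_count == 0. Blade angle at absolute time t is phase0 + omega*t.
// [[Rcpp::export(name = ".dem_run_cpp")]]
List dem_run_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericMatrix omega0,
                 NumericVector radius, NumericVector mass, double youngs, double poisson,
                 double restitution, double mu_f, double gamma_coh, double vessel_radius,
                 int blade_count, double blade_height, double rpm, double blade_phase0,
                 double gravity, double dt, int nsteps, int snap_every, double t0) {
  const int N = pos0.nrow();
  if (N < 1) stop("empty particle state");
  if (!(dt > 0)) stop("dt must be positive");
  if (snap_every < 1) snap_every = 1;

  Model M;
  M.Estar = youngs / (2.0 * (1.0 - poisson * poisson));
  const double G = youngs / (2.0 * (1.0 + poisson));
  M.Gstar = G / (2.0 * (2.0 - poisson));
  const double le = std::log(restitution);
  M.beta = (restitution >= 1.0) ? 0.0 : le / std::sqrt(le * le + M_PI * M_PI);
  M.mu = mu_f;
  M.gamma_coh = gamma_coh;

  std::vector<V3> x(N), v(N), w(N), f(N), tq(N);
  std::vector<double> r(N), m(N), inv_m(N), inv_I(N);
  double rmax = 0.0;
  for (int i = 0; i < N; ++i) {
    x[i] = v3(pos0(i, 0), pos0(i, 1), pos0(i, 2));
    v[i] = v3(vel0(i, 0), vel0(i, 1), vel0(i, 2));
    w[i] = v3(omega0(i, 0), omega0(i, 1), omega0(i, 2));
    r[i] = radius[i];
    m[i] = mass[i];
    inv_m[i] = 1.0 / m[i];
    inv_I[i] = 1.0 / (0.4 * m[i] * r[i] * r[i]);
    if (r[i] > rmax) rmax = r[i];
  }

  const bool walls = R_finite(vessel_radius);
  const double omega_blade = 2.0 * M_PI * rpm / 60.0;
  const double cell = 2.0 * rmax * 1.2;  // 2*Rmax*(1+skin), skin = 0.2

  std::unordered_map<uint64_t, TangHist> hist;
  hist.reserve(static_cast<size_t>(8 * N));

  // cell-list scratch
  std::vector<int> head, nxt(N), cix(N), ciy(N), ciz(N);
  double max_overlap_frac = 0.0;  // integration-failure monitor

  const int n_snap = nsteps / snap_every + 1;
  List snaps(n_snap);
  NumericVector snap_t(n_snap), snap_ke(n_snap), snap_pe(n_snap);

  auto compute_forces = [&](long step_now, double t_abs) {
    for (int i = 0; i < N; ++i) {
      f[i] = v3(0, 0, -m[i] * gravity);
      tq[i] = v3(0, 0, 0);
    }
    // --- cell list ---
    double xlo = x[0].x, xhi = x[0].x, ylo = x[0].y, yhi = x[0].y, zlo = x[0].z,
           zhi = x[0].z;
    for (int i = 1; i < N; ++i) {
      xlo = std::min(xlo, x[i].x); xhi = std::max(xhi, x[i].x);
      ylo = std::min(ylo, x[i].y); yhi = std::max(yhi, x[i].y);
      zlo = std::min(zlo, x[i].z); zhi = std::max(zhi, x[i].z);
    }
    const int nx = std::max(1, static_cast<int>((xhi - xlo) / cell) + 1);
    const int ny = std::max(1, static_cast<int>((yhi - ylo) / cell) + 1);
    const int nz = std::max(1, static_cast<int>((zhi - zlo) / cell) + 1);
    head.assign(static_cast<size_t>(nx) * ny * nz, -1);
    for (int i = 0; i < N; ++i) {
      int ix = std::min(nx - 1, static_cast<int>((x[i].x - xlo) / cell));
      int iy = std::min(ny - 1, static_cast<int>((x[i].y - ylo) / cell));
      int iz = std::min(nz - 1, static_cast<int>((x[i].z - zlo) / cell));
      cix[i] = ix; ciy[i] = iy; ciz[i] = iz;
      const int c = (iz * ny + iy) * nx + ix;
      nxt[i] = head[c];
      head[c] = i;
    }
    // --- particle-particle ---
    for (int i = 0; i < N; ++i) {
      for (int dz = -1; dz <= 1; ++dz) {
        const int iz = ciz[i] + dz;
        if (iz < 0 || iz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int iy = ciy[i] + dy;
          if (iy < 0 || iy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int ix = cix[i] + dx;
            if (ix < 0 || ix >= nx) continue;
            for (int j = head[(iz * ny + iy) * nx + ix]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              const V3 d = x[i] - x[j];
              const double rsum = r[i] + r[j];
              const double d2 = dot(d, d);
              if (d2 >= rsum * rsum || d2 <= 0.0) continue;
              const double dist = std::sqrt(d2);
              const double delta = rsum - dist;
              const double ofrac = delta / std::min(r[i], r[j]);
              if (ofrac > max_overlap_frac) max_overlap_frac = ofrac;
              const V3 n = (1.0 / dist) * d;  // from j toward i
              const double Rstar = r[i] * r[j] / rsum;
              const double mstar = m[i] * m[j] / (m[i] + m[j]);
              const double ai = r[i] - 0.5 * delta, aj = r[j] - 0.5 * delta;
              // contact-point relative velocity (translation + spin)
              const V3 vrel = v[i] - v[j] - cross(ai * w[i] + aj * w[j], n);
              TangHist& h = hist[pair_key(i, j)];
              double fn;
              const V3 F = contact_force(M, n, delta, vrel, Rstar, mstar, dt, h,
                                         step_now, &fn);
              f[i] = f[i] + F;
              f[j] = f[j] - F;
              const V3 Ft = F - dot(F, n) * n;
              tq[i] = tq[i] + cross((-ai) * n, Ft);
              tq[j] = tq[j] + cross(aj * n, (-1.0) * Ft);
            }
          }
        }
      }
    }
    // --- walls ---
    if (walls) {
      const double th = blade_phase0 + omega_blade * t_abs;
      for (int i = 0; i < N; ++i) {
        // floor z = 0
        double delta = r[i] - x[i].z;
        if (delta > 0.0) {
          const V3 n = v3(0, 0, 1);
          TangHist& h = hist[pair_key(i, N)];
          const V3 vrel = v[i] - cross((r[i] - 0.5 * delta) * w[i], n);
          double fn;
          const V3 F = contact_force(M, n, delta, vrel, r[i], m[i], dt, h, step_now, &fn);
          f[i] = f[i] + F;
          const V3 Ft = F - dot(F, n) * n;
          tq[i] = tq[i] + cross((-(r[i] - 0.5 * delta)) * n, Ft);
        }
        // cylindrical side wall
        const double rho = std::sqrt(x[i].x * x[i].x + x[i].y * x[i].y);
        delta = x[i].z >= 0.0 ? (rho + r[i] - vessel_radius) : -1.0;
        if (delta > 0.0 && rho > 1e-12) {
          const V3 n = v3(-x[i].x / rho, -x[i].y / rho, 0);  // inward
          TangHist& h = hist[pair_key(i, N + 1)];
          const V3 vrel = v[i] - cross((r[i] - 0.5 * delta) * w[i], n);
          double fn;
          const V3 F = contact_force(M, n, delta, vrel, r[i], m[i], dt, h, step_now, &fn);
          f[i] = f[i] + F;
          const V3 Ft = F - dot(F, n) * n;
          tq[i] = tq[i] + cross((-(r[i] - 0.5 * delta)) * n, Ft);
        }
        // blades: flat vertical half-planes through the axis, rotating at rpm
        for (int b = 0; b < blade_count; ++b) {
          const double thb = th + 2.0 * M_PI * b / std::max(1, blade_count);
          const double ct = std::cos(thb), st = std::sin(thb);
          // plane normal (-sin, cos, 0); radial direction (cos, sin, 0)
          const double s = -st * x[i].x + ct * x[i].y;       // signed distance
          const double proj = ct * x[i].x + st * x[i].y;      // radial coordinate
          if (std::fabs(s) >= r[i]) continue;
          if (proj < 0.0 || proj > vessel_radius) continue;
          if (x[i].z - r[i] > blade_height) continue;
          const double sgn = (s >= 0.0) ? 1.0 : -1.0;
          const V3 n = v3(-st * sgn, ct * sgn, 0);  // toward particle
          const double dlt = r[i] - std::fabs(s);
          // blade surface moves as a rigid body about the axis
          const V3 vw = cross(v3(0, 0, omega_blade), x[i]);
          TangHist& h = hist[pair_key(i, N + 2 + b)];
          const V3 vrel = v[i] - vw - cross((r[i] - 0.5 * dlt) * w[i], n);
          double fn;
          const V3 F = contact_force(M, n, dlt, vrel, r[i], m[i], dt, h, step_now, &fn);
          f[i] = f[i] + F;
          const V3 Ft = F - dot(F, n) * n;
          tq[i] = tq[i] + cross((-(r[i] - 0.5 * dlt)) * n, Ft);
        }
      }
    }
  };

  auto record = [&](int slot, long step) {
    NumericMatrix P(N, 3), Vm(N, 3), Wm(N, 3);
    double ke = 0.0, pe = 0.0;
    for (int i = 0; i < N; ++i) {
      P(i, 0) = x[i].x; P(i, 1) = x[i].y; P(i, 2) = x[i].z;
      Vm(i, 0) = v[i].x; Vm(i, 1) = v[i].y; Vm(i, 2) = v[i].z;
      Wm(i, 0) = w[i].x; Wm(i, 1) = w[i].y; Wm(i, 2) = w[i].z;
      ke += 0.5 * m[i] * dot(v[i], v[i]) + 0.5 * (0.4 * m[i] * r[i] * r[i]) * dot(w[i], w[i]);
      pe += m[i] * gravity * x[i].z;
    }
    snaps[slot] = List::create(_["pos"] = P, _["vel"] = Vm, _["omega"] = Wm);
    snap_t[slot] = t0 + step * dt;
    snap_ke[slot] = ke;
    snap_pe[slot] = pe;
  };

  compute_forces(0, t0);
  record(0, 0);

  std::string err;
  int slot = 1;
  for (long step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i) {
      v[i] = v[i] + (0.5 * dt * inv_m[i]) * f[i];
      w[i] = w[i] + (0.5 * dt * inv_I[i]) * tq[i];
      x[i] = x[i] + dt * v[i];
    }
    compute_forces(step, t0 + step * dt);
    double ke = 0.0;
    for (int i = 0; i < N; ++i) {
      v[i] = v[i] + (0.5 * dt * inv_m[i]) * f[i];
      w[i] = w[i] + (0.5 * dt * inv_I[i]) * tq[i];
      ke += 0.5 * m[i] * dot(v[i], v[i]);
    }
    // near-complete interpenetration or non-finite energy means the contact
    // integration has failed for this dt
    if (!R_finite(ke) || ke > 1e12 || max_overlap_frac > 0.9) {
      char buf[160];
      std::snprintf(buf, sizeof(buf),
                    "DEM instability: %s at step %ld (dt = %g s); reduce dt",
                    (R_finite(ke) && ke <= 1e12) ? "unresolved contact (overlap > 90% of radius)"
                                                 : "kinetic energy diverged",
                    step, dt);
      err = buf;
      break;  // partial trajectory (snapshots so far) is still returned
    }
    if (step % snap_every == 0) {
      record(slot, step);
      ++slot;
    }
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["times"] = snap_t, _["states"] = snaps, _["ke"] = snap_ke,
                          _["pe"] = snap_pe, _["n_steps"] = nsteps, _["dt"] = dt,
                          _["n_recorded"] = slot);
  if (!err.empty()) out["error"] = err;
  return out;
}

// All unordered particle pairs with gap distance <= (r_i+r_j)*(1+tol).
// Brute force O(N^2); fine at desk scale.
// [[Rcpp::export(name = ".contact_pairs_cpp")]]
IntegerMatrix contact_pairs_cpp(NumericMatrix pos, NumericVector radius, double tol) {
  const int N = pos.nrow();
  std::vector<int> ii, jj;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      const double dz = pos(i, 2) - pos(j, 2);
      const double cut = (radius[i] + radius[j]) * (1.0 + tol);
      if (dx * dx + dy * dy + dz * dz <= cut * cut) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(static_cast<int>(ii.size()), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(static_cast<int>(k), 0) = ii[k];
    out(static_cast<int>(k), 1) = jj[k];
  }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}
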