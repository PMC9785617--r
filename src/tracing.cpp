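// Lagrangian particle tracing in the dual-channel device.
//
// Each particle carries its own counter-based RNG stream derived from the
// master seed, so trajectories are bit-reproducible and independent of the
// order in which particles are processed. Integration is either overdamped
// (position Langevin: fluid velocity + settling drift + Brownian kick) or
// inertial (exact exponential update of the linear Stokes-drag ODE with
// Brownian/gravity treated as piecewise-constant over the step).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KB = 1.380649e-23;

// ---- counter-based RNG (splitmix64 finalizer, Box-Muller normals) ----------
static inline uint64_t sm64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double u01(uint64_t key, uint64_t ctr) {
  uint64_t x = sm64(key ^ sm64(ctr ^ 0xD1B54A32D192ED03ULL));
  return ((double)(x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
static inline double rnorm_ctr(uint64_t key, uint64_t ctr) {
  double a = u01(key, 2 * ctr), b = u01(key, 2 * ctr + 1);
  return std::sqrt(-2.0 * std::log(a)) * std::cos(2.0 * M_PI * b);
}
static inline uint64_t particle_key(uint64_t seed, uint64_t pid) {
  return sm64(seed * 0x9E3779B97F4A7C15ULL + sm64(pid + 1));
}

// ---- geometry --------------------------------------------------------------
struct Geom {
  double l, y_mem_bot, y_mem_top, y_top;
  double px0, pitch, d;  // pore tiling: start, period, slot width
  int n_pores;
};

// pore index containing x, or -1
static inline int pore_at(const Geom& g, double x) {
  if (g.n_pores <= 0 || g.d <= 0) return -1;
  double s = (x - g.px0) / g.pitch;
  int k = (int)std::floor(s);
  if (k < 0 || k >= g.n_pores) return -1;
  double x0 = g.px0 + k * g.pitch;
  return (x >= x0 && x <= x0 + g.d) ? k : -1;
}

enum Status { ACTIVE_AIR = 1, ACTIVE_MEDIA = 2, DEPOSITED = 3,
              EXITED_AIR = 4, EXITED_MEDIA = 5 };
enum Region { R_AIR = 0, R_BAND = 1, R_MEDIA = 2 };

struct PState {
  double x, y;
  int status;     // Status
  int region;     // Region
  int pore;       // slot index while in band
  double x_dep, y_exit;
};

// Resolve the motion (cx,cy) -> (tx,ty) against walls, pores, the sticky
// membrane top and the outlets. Mutates the state; returns final position.
static void resolve_motion(PState& s, const Geom& g, double tx, double ty) {
  double cx = s.x, cy = s.y;
  for (int guard = 0; guard < 64; ++guard) {
    if (s.region == R_AIR) {
      // candidate crossings (parameter along remaining segment)
      double sb = (ty < g.y_mem_top && cy > g.y_mem_top)
                    ? (cy - g.y_mem_top) / (cy - ty) : 2.0;
      if (ty < g.y_mem_top && cy <= g.y_mem_top) sb = 0.0;
      double st = (ty > g.y_top) ? (g.y_top - cy) / (ty - cy) : 2.0;
      double sl = (tx < 0.0) ? cx / (cx - tx) : 2.0;
      double sr = (tx > g.l) ? (g.l - cx) / (tx - cx) : 2.0;
      double smin = std::min(std::min(sb, st), std::min(sl, sr));
      if (smin > 1.0) break;
      if (smin == sr) {
        s.status = EXITED_AIR;
        s.x = g.l; s.y = cy + (ty - cy) * sr;
        return;
      } else if (smin == st) {
        cx = cx + (tx - cx) * st; cy = g.y_top;
        ty = 2.0 * g.y_top - ty;
      } else if (smin == sl) {
        cy = cy + (ty - cy) * sl; cx = 0.0;
        tx = -tx;
      } else { // membrane-top plane
        double xc = cx + (tx - cx) * sb;
        int k = pore_at(g, xc);
        if (k < 0) {
          s.status = DEPOSITED;
          s.x = xc; s.y = g.y_mem_top; s.x_dep = xc;
          return;
        }
        cx = xc; cy = g.y_mem_top;
        s.region = R_BAND; s.pore = k;
      }
    } else if (s.region == R_BAND) {
      double bx0 = g.px0 + s.pore * g.pitch, bx1 = bx0 + g.d;
      double sb = (ty < g.y_mem_bot && cy > g.y_mem_bot)
                    ? (cy - g.y_mem_bot) / (cy - ty) : 2.0;
      if (ty < g.y_mem_bot && cy <= g.y_mem_bot) sb = 0.0;
      double st = (ty > g.y_mem_top && cy < g.y_mem_top)
                    ? (g.y_mem_top - cy) / (ty - cy) : 2.0;
      if (ty > g.y_mem_top && cy >= g.y_mem_top) st = 0.0;
      double sl = (tx < bx0) ? (cx - bx0) / (cx - tx) : 2.0;
      double sr = (tx > bx1) ? (bx1 - cx) / (tx - cx) : 2.0;
      double smin = std::min(std::min(sb, st), std::min(sl, sr));
      if (smin > 1.0) break;
      if (smin == sl) {
        cy = cy + (ty - cy) * sl; cx = bx0;
        tx = 2.0 * bx0 - tx;
      } else if (smin == sr) {
        cy = cy + (ty - cy) * sr; cx = bx1;
        tx = 2.0 * bx1 - tx;
      } else if (smin == st) { // back up into the air channel
        cx = cx + (tx - cx) * st; cy = g.y_mem_top;
        s.region = R_AIR; s.pore = -1;
      } else {                 // down into the media channel: translocation
        cx = cx + (tx - cx) * sb; cy = g.y_mem_bot;
        s.region = R_MEDIA; s.pore = -1;
        if (s.status == ACTIVE_AIR) s.status = ACTIVE_MEDIA; // transfer flag set by caller
      }
    } else { // R_MEDIA
      double sb = (ty < 0.0) ? cy / (cy - ty) : 2.0;
      double st = (ty > g.y_mem_bot) ? (g.y_mem_bot - cy) / (ty - cy) : 2.0;
      double sl = (tx < 0.0) ? cx / (cx - tx) : 2.0;
      double sr = (tx > g.l) ? (g.l - cx) / (tx - cx) : 2.0;
      double smin = std::min(std::min(sb, st), std::min(sl, sr));
      if (smin > 1.0) break;
      if (smin == sr) {
        s.y_exit = cy + (ty - cy) * sr;
        s.status = EXITED_MEDIA;
        s.x = g.l; s.y = s.y_exit;
        return;
      } else if (smin == sb) {
        cx = cx + (tx - cx) * sb; cy = 0.0; ty = -ty;
      } else if (smin == st) { // membrane underside reflects (one-way transfer)
        cx = cx + (tx - cx) * st; cy = g.y_mem_bot;
        ty = 2.0 * g.y_mem_bot - ty;
      } else {
        cy = cy + (ty - cy) * sl; cx = 0.0; tx = -tx;
      }
    }
  }
  s.x = tx; s.y = ty;
}

// ---- MAC bilinear sampling on ghost-padded arrays --------------------------
static inline double sample_u(const NumericMatrix& up, double dx, double dy,
                              int nx, int ny, double x, double y) {
  double si = x / dx;                       // lattice x index (0-based faces)
  int i0 = (int)std::floor(si);
  if (i0 < 0) i0 = 0; if (i0 > nx - 1) i0 = nx - 1;
  double fx = si - i0;
  double sj = y / dy + 0.5;                 // pad row 0 at y = -dy/2
  int j0 = (int)std::floor(sj);
  if (j0 < 0) j0 = 0; if (j0 > ny) j0 = ny;
  double fy = sj - j0;
  return (1 - fx) * ((1 - fy) * up(i0, j0) + fy * up(i0, j0 + 1)) +
         fx * ((1 - fy) * up(i0 + 1, j0) + fy * up(i0 + 1, j0 + 1));
}
static inline double sample_v(const NumericMatrix& vp, double dx, double dy,
                              int nx, int ny, double x, double y) {
  double si = x / dx + 0.5;                 // pad col 0 at x = -dx/2
  int i0 = (int)std::floor(si);
  if (i0 < 0) i0 = 0; if (i0 > nx) i0 = nx;
  double fx = si - i0;
  double sj = y / dy;
  int j0 = (int)std::floor(sj);
  if (j0 < 0) j0 = 0; if (j0 > ny - 1) j0 = ny - 1;
  double fy = sj - j0;
  return (1 - fx) * ((1 - fy) * vp(i0, j0) + fy * vp(i0, j0 + 1)) +
         fx * ((1 - fy) * vp(i0 + 1, j0) + fy * vp(i0 + 1, j0 + 1));
}

// [[Rcpp::export]]
List sample_velocity_cpp(NumericMatrix u_pad, NumericMatrix v_pad,
                         double dx, double dy, int nx, int ny,
                         NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector u(n), v(n);
  for (int i = 0; i < n; ++i) {
    u[i] = sample_u(u_pad, dx, dy, nx, ny, x[i], y[i]);
    v[i] = sample_v(v_pad, dx, dy, nx, ny, x[i], y[i]);
  }
  return List::create(_["u"] = u, _["v"] = v);
}

// Standalone boundary resolution (unit-test surface for the event logic).
// [[Rcpp::export]]
List apply_boundaries_cpp(double x0, double y0, double x1, double y1,
                          int status, int region, int pore,
                          double l, double y_mem_bot, double y_mem_top,
                          double y_top, double px0, double pitch, double d,
                          int n_pores) {
  Geom g{l, y_mem_bot, y_mem_top, y_top, px0, pitch, d, n_pores};
  PState s{x0, y0, status, region, pore, NA_REAL, NA_REAL};
  int status_in = status;
  resolve_motion(s, g, x1, y1);
  bool transferred = (status_in == ACTIVE_AIR && s.status == ACTIVE_MEDIA);
  return List::create(_["x"] = s.x, _["y"] = s.y, _["status"] = s.status,
                      _["region"] = s.region, _["pore"] = s.pore,
                      _["x_deposit"] = s.x_dep, _["y_exit"] = s.y_exit,
                      _["transferred"] = transferred);
}

// ---- main tracer -----------------------------------------------------------
// fluid property vectors: [0] = top phase (air channel), [1] = bottom phase
// (pore slots + media channel).
// [[Rcpp::export]]
List trace_particles_cpp(NumericMatrix u_pad, NumericMatrix v_pad,
                         double dx, double dy, int nx, int ny,
                         double l, double y_mem_bot, double y_mem_top, double y_top,
                         double px0, double pitch, double dpore, int n_pores,
                         NumericVector rho_f, NumericVector mu_f, NumericVector T_f,
                         double dp, double rho_p,
                         int n_particles, double dt, double seed_d, double g_acc,
                         int inertial, int brownian, int gravity, int drag,
                         double max_time,
                         double inj_x, double inj_y0, double inj_y1,
                         int init_fluid,
                         int n_bands, int traj_stride, int traj_max) {
  Geom geom{l, y_mem_bot, y_mem_top, y_top, px0, pitch, dpore, n_pores};
  uint64_t seed = (uint64_t)seed_d;
  double mp = rho_p * M_PI * dp * dp * dp / 6.0;
  long max_steps = (long)std::ceil(max_time / dt);

  IntegerVector status(n_particles);
  NumericVector xf(n_particles), yf(n_particles), tf(n_particles);
  NumericVector t_transfer(n_particles, NA_REAL), t_exit(n_particles, NA_REAL);
  NumericVector y_exit(n_particles, NA_REAL), x_dep(n_particles, NA_REAL);
  NumericVector band_occ(std::max(n_bands, 1));
  std::vector<double> traj; // pid, t, x, y
  bool record = traj_stride > 0;

  for (int pid = 0; pid < n_particles; ++pid) {
    uint64_t key = particle_key(seed, (uint64_t)pid);
    PState s;
    s.x = inj_x;
    s.y = inj_y0 + u01(key, 0) * (inj_y1 - inj_y0);
    s.status = ACTIVE_AIR;
    s.region = (s.y > y_mem_top) ? R_AIR : ((s.y < y_mem_bot) ? R_MEDIA : R_BAND);
    if (s.region == R_MEDIA) s.status = ACTIVE_MEDIA; // direct media release
    s.pore = (s.region == R_BAND) ? pore_at(geom, s.x) : -1;
    s.x_dep = NA_REAL; s.y_exit = NA_REAL;
    double upx = 0, upy = 0;
    if (init_fluid) {
      upx = sample_u(u_pad, dx, dy, nx, ny, s.x, s.y);
      upy = sample_v(v_pad, dx, dy, nx, ny, s.x, s.y);
    }
    double t = 0;
    bool rec_this = record && pid < traj_max;
    if (rec_this) { traj.push_back(pid + 1); traj.push_back(t);
                    traj.push_back(s.x); traj.push_back(s.y); }

    for (long step = 1; step <= max_steps; ++step) {
      int ph = (s.region == R_AIR) ? 0 : 1;
      double rho = rho_f[ph], mu = mu_f[ph], Tt = T_f[ph];
      double uf = drag ? sample_u(u_pad, dx, dy, nx, ny, s.x, s.y) : 0.0;
      double vf = drag ? sample_v(v_pad, dx, dy, nx, ny, s.x, s.y) : 0.0;
      double zx = 0, zy = 0;
      if (brownian) {
        zx = rnorm_ctr(key, 2 * (uint64_t)step);
        zy = rnorm_ctr(key, 2 * (uint64_t)step + 1);
      }
      double txp, typ;
      if (!inertial) {
        double Dp = KB * Tt / (3.0 * M_PI * mu * dp);
        double vs = gravity ? (rho_p - rho) * g_acc * dp * dp / (18.0 * mu) : 0.0;
        double bstep = brownian ? std::sqrt(2.0 * Dp * dt) : 0.0;
        txp = s.x + uf * dt + bstep * zx;
        typ = s.y + (vf - vs) * dt + bstep * zy;
      } else if (drag) {
        double tau = rho_p * dp * dp / (18.0 * mu);
        double Famp = brownian ? std::sqrt(6.0 * M_PI * KB * mu * Tt * dp / dt) : 0.0;
        double abx = Famp * zx / mp, aby = Famp * zy / mp;
        double agy = gravity ? -(1.0 - rho / rho_p) * g_acc : 0.0;
        double Ux = uf + tau * abx, Uy = vf + tau * (aby + agy);
        double e = std::exp(-dt / tau), om = 1.0 - e;
        txp = s.x + Ux * dt + tau * (upx - Ux) * om;
        typ = s.y + Uy * dt + tau * (upy - Uy) * om;
        upx = Ux + (upx - Ux) * e;
        upy = Uy + (upy - Uy) * e;
      } else { // ballistic (no drag): velocity-Verlet style
        double Famp = brownian ? std::sqrt(6.0 * M_PI * KB * mu * Tt * dp / dt) : 0.0;
        double abx = Famp * zx / mp;
        double aby = Famp * zy / mp + (gravity ? -(1.0 - rho / rho_p) * g_acc : 0.0);
        txp = s.x + upx * dt + 0.5 * abx * dt * dt;
        typ = s.y + upy * dt + 0.5 * aby * dt * dt;
        upx += abx * dt; upy += aby * dt;
      }
      int status_before = s.status;
      resolve_motion(s, geom, txp, typ);
      t = step * dt;
      if (status_before == ACTIVE_AIR && (s.status == ACTIVE_MEDIA ||
                                          s.status == EXITED_MEDIA))
        t_transfer[pid] = t;
      if (n_bands > 0 && s.region == R_AIR &&
          (s.status == ACTIVE_AIR)) {
        int b = (int)std::floor(s.x / l * n_bands);
        if (b >= 0 && b < n_bands) band_occ[b] += dt;
      }
      if (rec_this && (step % traj_stride == 0 || s.status >= DEPOSITED)) {
        traj.push_back(pid + 1); traj.push_back(t);
        traj.push_back(s.x); traj.push_back(s.y);
      }
      if (s.status == DEPOSITED) { x_dep[pid] = s.x; break; }
      if (s.status == EXITED_AIR) break;
      if (s.status == EXITED_MEDIA) { t_exit[pid] = t; y_exit[pid] = s.y; break; }
    }
    status[pid] = s.status;
    xf[pid] = s.x; yf[pid] = s.y; tf[pid] = t;
  }

  NumericMatrix traj_m(traj.size() / 4, 4);
  for (size_t r = 0; r < traj.size() / 4; ++r)
    for (int c = 0; c < 4; ++c) traj_m(r, c) = traj[4 * r + c];

  return List::create(
    _["status"] = status, _["x"] = xf, _["y"] = yf, _["t"] = tf,
    _["t_transfer"] = t_transfer, _["t_exit"] = t_exit,
    _["y_exit"] = y_exit, _["x_deposit"] = x_dep,
    _["band_occupancy"] = band_occ, _["trajectory"] = traj_m);
}
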