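#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 propagation kernels for the wall-driven swimmer.
// These back the time-optimal solver and the policy seed generators,
// where many thousands of rollouts are needed; user-facing adaptive,
// event-located integration lives in R on top of deSolve.

struct Par {
  double v, k, om, B2, a;
  bool inter;
};

static inline void deriv(double t, const double *X, double u, const Par &p,
                         double *dX) {
  double x = X[0], z = X[1], th = X[2];
  // clamp the exponent so exploratory rollouts far outside the physical
  // domain stay finite instead of overflowing
  double zc = z;
  double lim = 60.0 / (p.k > 0 ? p.k : 1.0);
  if (zc > lim) zc = lim;
  if (zc < -lim) zc = -lim;
  double E = std::exp(-p.k * zc);
  double ph = p.k * x - p.om * t;
  double s = std::sin(ph), c = std::cos(ph);
  dX[0] = -p.v * std::sin(th) + u * E * (1.0 - p.k * z) * s;
  dX[1] = p.v * std::cos(th) - u * E * p.k * z * c;
  dX[2] = 0.5 * u * E * p.k * s;
  if (p.inter && p.B2 != 0.0) {
    double zz = z;
    if (zz < 0.02) zz = 0.02;  // far-field term is invalid at contact
    double a2 = p.a * p.a;
    double s2 = std::sin(2.0 * th), c2 = std::cos(2.0 * th);
    dX[0] += -3.0 * a2 * p.B2 / (40.0 * zz * zz) * s2;
    dX[1] += 9.0 * a2 * p.B2 / (16.0 * zz * zz) * c2;
    dX[2] += -3.0 * a2 * p.B2 / (40.0 * zz * zz * zz) * s2;
  }
}

static inline void rk4(double t, double *X, double u, double h, const Par &p) {
  double k1[3], k2[3], k3[3], k4[3], Y[3];
  deriv(t, X, u, p, k1);
  for (int i = 0; i < 3; ++i) Y[i] = X[i] + 0.5 * h * k1[i];
  deriv(t + 0.5 * h, Y, u, p, k2);
  for (int i = 0; i < 3; ++i) Y[i] = X[i] + 0.5 * h * k2[i];
  deriv(t + 0.5 * h, Y, u, p, k3);
  for (int i = 0; i < 3; ++i) Y[i] = X[i] + h * k3[i];
  deriv(t + h, Y, u, p, k4);
  for (int i = 0; i < 3; ++i)
    X[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static Par mkpar(const NumericVector &par) {
  Par p;
  p.v = par[0];
  p.k = par[1];
  p.om = par[2];
  p.B2 = par[3];
  p.a = par[4];
  p.inter = par[5] != 0.0;
  return p;
}

// event: ev_idx 0 none, 1 x, 2 z, 3 theta; crossing ev_val in direction ev_dir
static inline double evfun(const double *X, int idx, double val, double dir) {
  return dir * (X[idx - 1] - val);
}

// refine crossing time within (t, t+h] by bisection on a single RK4 substep
static double refine(double t, const double *X, double u, double h,
                     const Par &p, int idx, double val, double dir,
                     double *Xout) {
  double lo = 0.0, hi = h;
  double Y[3];
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    for (int i = 0; i < 3; ++i) Y[i] = X[i];
    rk4(t, Y, u, mid, p);
    if (evfun(Y, idx, val, dir) >= 0.0)
      hi = mid;
    else
      lo = mid;
  }
  for (int i = 0; i < 3; ++i) Xout[i] = X[i];
  rk4(t, Xout, u, hi, p);
  return t + hi;
}

// [[Rcpp::export(name = ".ws_rollout_bang")]]
List ws_rollout_bang(NumericVector X0, NumericVector durations, double s0,
                     double umax, NumericVector par, double h, int ev_idx,
                     double ev_val, double ev_dir, double t_cap,
                     double tail_period, bool record) {
  Par p = mkpar(par);
  double X[3] = {X0[0], X0[1], X0[2]};
  double t = 0.0, zmin = X[1], sgn = s0;
  bool crossed = false;
  std::vector<double> rec_t, rec_x, rec_z, rec_th, rec_u;
  std::vector<double> sw;
  if (record) {
    rec_t.push_back(t);
    rec_x.push_back(X[0]);
    rec_z.push_back(X[1]);
    rec_th.push_back(X[2]);
    rec_u.push_back(sgn * umax);
  }
  R_xlen_t iseg = 0;
  bool intail = false;
  while (t < t_cap - 1e-15) {
    double di;
    if (iseg < durations.size()) {
      di = durations[iseg++];
    } else {
      di = tail_period;
      intail = true;
      if (tail_period <= 0.0) break;
    }
    if (!R_finite(di)) {
      return List::create(_["ok"] = false);
    }
    if (di > 1e-13) {
      if (t + di > t_cap) di = t_cap - t;
      int n = (int)std::ceil(di / h);
      if (n < 2) n = 2;
      double hh = di / n;
      double u = sgn * umax;
      for (int j = 0; j < n; ++j) {
        double Xp[3] = {X[0], X[1], X[2]};
        rk4(t, X, u, hh, p);
        if (ev_idx > 0 && evfun(X, ev_idx, ev_val, ev_dir) >= 0.0 &&
            evfun(Xp, ev_idx, ev_val, ev_dir) < 0.0) {
          double Xc[3];
          double tc = refine(t, Xp, u, hh, p, ev_idx, ev_val, ev_dir, Xc);
          for (int i = 0; i < 3; ++i) X[i] = Xc[i];
          t = tc;
          crossed = true;
          if (X[1] < zmin) zmin = X[1];
          if (record) {
            rec_t.push_back(t);
            rec_x.push_back(X[0]);
            rec_z.push_back(X[1]);
            rec_th.push_back(X[2]);
            rec_u.push_back(u);
          }
          goto done;
        }
        t += hh;
        if (X[1] < zmin) zmin = X[1];
        if (record) {
          rec_t.push_back(t);
          rec_x.push_back(X[0]);
          rec_z.push_back(X[1]);
          rec_th.push_back(X[2]);
          rec_u.push_back(u);
        }
        if (!R_finite(X[0]) || !R_finite(X[1]) || !R_finite(X[2]))
          return List::create(_["ok"] = false);
      }
    }
    sgn = -sgn;
    if (t < t_cap - 1e-15) sw.push_back(t);
    if (intail && ev_idx == 0) break;
  }
done:
  List out = List::create(
      _["ok"] = true, _["state"] = NumericVector::create(X[0], X[1], X[2]),
      _["T"] = t, _["zmin"] = zmin, _["crossed"] = crossed,
      _["switch_times"] = wrap(sw));
  if (record) {
    NumericMatrix tr(rec_t.size(), 5);
    for (R_xlen_t i = 0; i < (R_xlen_t)rec_t.size(); ++i) {
      tr(i, 0) = rec_t[i];
      tr(i, 1) = rec_x[i];
      tr(i, 2) = rec_z[i];
      tr(i, 3) = rec_th[i];
      tr(i, 4) = rec_u[i];
    }
    out["traj"] = tr;
  }
  return out;
}

// Synchronised bang policy with a z-regulating phase offset, used to build
// solver seeds.  mode M in {-1, +1} multiplies the carrier sign;
// carrier 0: sgn(sin(phi + delta)) (cell-synchronised, horizontal/rotation
// authority), carrier 1: sgn(cos(phi + delta)) (vertical authority).
// delta = clamp(kappa * (z_target - z), +-dmax).
// [[Rcpp::export(name = ".ws_rollout_policy")]]
List ws_rollout_policy(NumericVector X0, double t0, double M, int carrier,
                       double kappa, double z_target, double dmax, double umax,
                       NumericVector par, double h, int ev_idx, double ev_val,
                       double ev_dir, double t_cap) {
  Par p = mkpar(par);
  double X[3] = {X0[0], X0[1], X0[2]};
  double t = t0, zmin = X[1];
  bool crossed = false;
  std::vector<double> sw;
  std::vector<double> swsgn;
  double prev_u = 0.0;
  while (t < t_cap - 1e-15) {
    double delta = kappa * (z_target - X[1]);
    if (delta > dmax) delta = dmax;
    if (delta < -dmax) delta = -dmax;
    double arg = p.k * X[0] - p.om * t + delta;
    double car = (carrier == 0) ? std::sin(arg) : std::cos(arg);
    double u = M * umax * (car > 0 ? 1.0 : (car < 0 ? -1.0 : 0.0));
    if (u != 0.0 && prev_u != 0.0 && u * prev_u < 0) {
      sw.push_back(t);
      swsgn.push_back(u > 0 ? 1.0 : -1.0);
    }
    if (u != 0.0) prev_u = u;
    double Xp[3] = {X[0], X[1], X[2]};
    double hh = (t + h > t_cap) ? (t_cap - t) : h;
    rk4(t, X, u, hh, p);
    if (ev_idx > 0 && evfun(X, ev_idx, ev_val, ev_dir) >= 0.0 &&
        evfun(Xp, ev_idx, ev_val, ev_dir) < 0.0) {
      double Xc[3];
      t = refine(t, Xp, u, hh, p, ev_idx, ev_val, ev_dir, Xc);
      for (int i = 0; i < 3; ++i) X[i] = Xc[i];
      crossed = true;
      if (X[1] < zmin) zmin = X[1];
      break;
    }
    t += hh;
    if (X[1] < zmin) zmin = X[1];
    if (!R_finite(X[0]) || !R_finite(X[1]) || !R_finite(X[2]))
      return List::create(_["ok"] = false);
  }
  return List::create(
      _["ok"] = true, _["state"] = NumericVector::create(X[0], X[1], X[2]),
      _["T"] = t, _["zmin"] = zmin, _["crossed"] = crossed,
      _["switch_times"] = wrap(sw), _["switch_signs"] = wrap(swsgn),
      _["last_u"] = prev_u);
}
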