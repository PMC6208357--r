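#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Built-in potential codes:
//   0 quartic        U(x) = sum_i x_i^4
//   1 double_well    U(x) = x^6 + 2 cos(5 (x + 1))          (1D only)
//   2 lj_cluster     pairwise Lennard-Jones (eps = sigma = 1) on dim/3
//                    particles plus harmonic restraint (k/2) sum |r_i|^2,
//                    params[0] = k
//  -1 user-supplied R functions (potential, gradient)

struct Potential {
  int code;
  std::vector<double> params;
  Function *pfun, *gfun;

  double U(const std::vector<double>& x) const {
    const int d = (int)x.size();
    switch (code) {
    case 0: {
      double u = 0.0;
      for (int i = 0; i < d; ++i) { double s = x[i] * x[i]; u += s * s; }
      return u;
    }
    case 1:
      return std::pow(x[0], 6) + 2.0 * std::cos(5.0 * (x[0] + 1.0));
    case 2: {
      const int np = d / 3;
      const double k = params[0];
      double u = 0.0;
      for (int i = 0; i < np; ++i) {
        for (int j = i + 1; j < np; ++j) {
          double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
                 dz = x[3*i+2] - x[3*j+2];
          double r2 = dx*dx + dy*dy + dz*dz;
          double ir6 = 1.0 / (r2 * r2 * r2);
          u += 4.0 * (ir6 * ir6 - ir6);
        }
      }
      for (int i = 0; i < d; ++i) u += 0.5 * k * x[i] * x[i];
      return u;
    }
    default: {
      NumericVector xv(x.begin(), x.end());
      return as<double>((*pfun)(xv));
    }
    }
  }

  void grad(const std::vector<double>& x, std::vector<double>& g) const {
    const int d = (int)x.size();
    switch (code) {
    case 0:
      for (int i = 0; i < d; ++i) g[i] = 4.0 * x[i] * x[i] * x[i];
      return;
    case 1:
      g[0] = 6.0 * std::pow(x[0], 5) - 10.0 * std::sin(5.0 * (x[0] + 1.0));
      return;
    case 2: {
      const int np = d / 3;
      const double k = params[0];
      for (int i = 0; i < d; ++i) g[i] = k * x[i];
      for (int i = 0; i < np; ++i) {
        for (int j = i + 1; j < np; ++j) {
          double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
                 dz = x[3*i+2] - x[3*j+2];
          double r2 = dx*dx + dy*dy + dz*dz;
          double ir2 = 1.0 / r2;
          double ir6 = ir2 * ir2 * ir2;
          // dU/dr2 = 4 * (-12 r^-14 + 6 r^-8) / 2 = (24 ir6 - 48 ir6^2) ir2 / 2
          double c = (24.0 * ir6 - 48.0 * ir6 * ir6) * ir2 * 0.5;
          g[3*i]   += 2.0 * c * dx; g[3*j]   -= 2.0 * c * dx;
          g[3*i+1] += 2.0 * c * dy; g[3*j+1] -= 2.0 * c * dy;
          g[3*i+2] += 2.0 * c * dz; g[3*j+2] -= 2.0 * c * dz;
        }
      }
      return;
    }
    default: {
      NumericVector xv(x.begin(), x.end());
      NumericVector gv = (*gfun)(xv);
      for (int i = 0; i < d; ++i) g[i] = gv[i];
      return;
    }
    }
  }
};

static Potential make_potential(int code, NumericVector params,
                                Function* pf, Function* gf) {
  Potential p;
  p.code = code;
  p.params = std::vector<double>(params.begin(), params.end());
  p.pfun = pf; p.gfun = gf;
  return p;
}

// reduced kinetic energy t(v) = beta * v' M v / 2
static inline double kin_red(const std::vector<double>& v,
                             const std::vector<double>& m, double beta) {
  double t = 0.0;
  for (size_t i = 0; i < v.size(); ++i) t += m[i] * v[i] * v[i];
  return 0.5 * beta * t;
}

static inline bool state_ok(const std::vector<double>& x,
                            const std::vector<double>& v) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (!std::isfinite(x[i]) || !std::isfinite(v[i]) ||
        std::fabs(x[i]) > 1e6) return false;
  }
  return true;
}

// One integrator cycle in scheme order; accumulates reduced heat over O
// substeps into *dq.  Letters coded 0=R, 1=V, 2=O; tau[i] = fraction_i * dt.
struct Stepper {
  const Potential* pot;
  std::vector<int> letters;
  std::vector<double> tau;       // substep durations
  std::vector<double> a, osig;   // O-substep coefficients per substep (a) ...
  std::vector<double> mass, inv_m, csig; // csig: per-dof sqrt(1/(beta m))
  double beta;
  std::vector<double> g;         // gradient scratch

  Stepper(const Potential* p, IntegerVector let, NumericVector fr,
          double dt, double gamma, NumericVector m, double beta_)
    : pot(p), beta(beta_) {
    int ns = let.size();
    letters.assign(let.begin(), let.end());
    tau.resize(ns); a.resize(ns); osig.resize(ns);
    for (int i = 0; i < ns; ++i) {
      tau[i] = fr[i] * dt;
      a[i] = std::exp(-gamma * tau[i]);
      osig[i] = std::sqrt(std::max(0.0, 1.0 - a[i] * a[i]));
    }
    int d = m.size();
    mass.assign(m.begin(), m.end());
    inv_m.resize(d); csig.resize(d);
    for (int i = 0; i < d; ++i) {
      inv_m[i] = 1.0 / mass[i];
      csig[i] = std::sqrt(1.0 / (beta * mass[i]));
    }
    g.resize(d);
  }

  void cycle(std::vector<double>& x, std::vector<double>& v, double* dq) {
    const int d = (int)x.size();
    for (size_t s = 0; s < letters.size(); ++s) {
      switch (letters[s]) {
      case 0: // R: position drift
        for (int i = 0; i < d; ++i) x[i] += v[i] * tau[s];
        break;
      case 1: // V: velocity kick, one force evaluation per V substep
        pot->grad(x, g);
        for (int i = 0; i < d; ++i) v[i] -= inv_m[i] * g[i] * tau[s];
        break;
      default: { // O: Ornstein-Uhlenbeck partial velocity randomization
        double t0 = kin_red(v, mass, beta);
        for (int i = 0; i < d; ++i)
          v[i] = a[s] * v[i] + osig[s] * csig[i] * norm_rand();
        *dq += kin_red(v, mass, beta) - t0;
        break;
      }
      }
    }
  }
};

// [[Rcpp::export]]
double cpp_potential(int code, NumericVector params, NumericVector x,
                     Nullable<Function> pfun = R_NilValue) {
  Function pf = pfun.isNotNull() ? Function(pfun) : Function("identity");
  Potential p = make_potential(code, params, &pf, &pf);
  std::vector<double> xv(x.begin(), x.end());
  return p.U(xv);
}

// [[Rcpp::export]]
NumericVector cpp_gradient(int code, NumericVector params, NumericVector x,
                           Nullable<Function> gfun = R_NilValue) {
  Function gf = gfun.isNotNull() ? Function(gfun) : Function("identity");
  Potential p = make_potential(code, params, &gf, &gf);
  std::vector<double> xv(x.begin(), x.end()), g(x.size());
  p.grad(xv, g);
  return NumericVector(g.begin(), g.end());
}

// Run n_steps full integrator cycles; returns final state and the work
// ledger (reduced delta_h, delta_q, shadow work).  If record_states, the
// phase point after every substep of every cycle is returned (diagnostic
// use; keep n_steps small).  If thin > 0, the state after every thin-th
// cycle is recorded.
// [[Rcpp::export]]
List cpp_run_cycles(int code, NumericVector params, double beta,
                    NumericVector masses, IntegerVector letters,
                    NumericVector fractions, double dt, double gamma,
                    NumericVector x0, NumericVector v0, int n_steps,
                    bool record_states = false, int thin = 0,
                    Nullable<Function> pfun = R_NilValue,
                    Nullable<Function> gfun = R_NilValue) {
  Function pf = pfun.isNotNull() ? Function(pfun) : Function("identity");
  Function gf = gfun.isNotNull() ? Function(gfun) : Function("identity");
  Potential pot = make_potential(code, params, &pf, &gf);
  Stepper st(&pot, letters, fractions, dt, gamma, masses, beta);

  const int d = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), v(v0.begin(), v0.end());
  double u0 = beta * pot.U(x), t0 = kin_red(v, st.mass, beta);
  double dq = 0.0;
  int failed_step = -1;

  int ns_sub = letters.size();
  NumericMatrix sub_x, sub_v;
  if (record_states) {
    sub_x = NumericMatrix(n_steps * ns_sub + 1, d);
    sub_v = NumericMatrix(n_steps * ns_sub + 1, d);
    for (int i = 0; i < d; ++i) { sub_x(0, i) = x[i]; sub_v(0, i) = v[i]; }
  }
  int n_keep = (thin > 0) ? n_steps / thin : 0;
  NumericMatrix traj_x, traj_v;
  if (n_keep > 0) { traj_x = NumericMatrix(n_keep, d); traj_v = NumericMatrix(n_keep, d); }
  int kept = 0, row = 1;

  for (int k = 0; k < n_steps; ++k) {
    if (record_states) {
      // replay cycle substep-by-substep so intermediate states are visible
      for (int s = 0; s < ns_sub; ++s) {
        IntegerVector one_l = IntegerVector::create(letters[s]);
        NumericVector one_f = NumericVector::create(fractions[s]);
        Stepper st1(&pot, one_l, one_f, dt, gamma, masses, beta);
        st1.cycle(x, v, &dq);
        for (int i = 0; i < d; ++i) { sub_x(row, i) = x[i]; sub_v(row, i) = v[i]; }
        ++row;
      }
    } else {
      st.cycle(x, v, &dq);
    }
    if (!state_ok(x, v)) { failed_step = k + 1; break; }
    if (thin > 0 && (k + 1) % thin == 0 && kept < n_keep) {
      for (int i = 0; i < d; ++i) { traj_x(kept, i) = x[i]; traj_v(kept, i) = v[i]; }
      ++kept;
    }
  }

  bool stable = (failed_step < 0);
  double delta_h = NA_REAL, shadow = NA_REAL;
  if (stable) {
    delta_h = (beta * pot.U(x) + kin_red(v, st.mass, beta)) - (u0 + t0);
    shadow = delta_h - dq;
  }
  List out = List::create(
    _["x"] = NumericVector(x.begin(), x.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["delta_h"] = delta_h, _["delta_q"] = dq,
    _["shadow_work"] = shadow,
    _["stable"] = stable, _["failed_step"] = failed_step);
  if (record_states) { out["states_x"] = sub_x; out["states_v"] = sub_v; }
  if (n_keep > 0) {
    out["traj_x"] = traj_x; out["traj_v"] = traj_v; out["n_kept"] = kept;
  }
  return out;
}

// Independent trajectories: row i of X0/V0 is a start; run n_steps cycles
// from each, returning per-trajectory shadow work and final states.
// [[Rcpp::export]]
List cpp_work_batch(int code, NumericVector params, double beta,
                    NumericVector masses, IntegerVector letters,
                    NumericVector fractions, double dt, double gamma,
                    NumericMatrix X0, NumericMatrix V0, int n_steps,
                    Nullable<Function> pfun = R_NilValue,
                    Nullable<Function> gfun = R_NilValue) {
  Function pf = pfun.isNotNull() ? Function(pfun) : Function("identity");
  Function gf = gfun.isNotNull() ? Function(gfun) : Function("identity");
  Potential pot = make_potential(code, params, &pf, &gf);
  Stepper st(&pot, letters, fractions, dt, gamma, masses, beta);

  const int n = X0.nrow(), d = X0.ncol();
  NumericVector work(n), dh(n), dqv(n);
  LogicalVector stable(n);
  NumericMatrix Xe(n, d), Ve(n, d);
  std::vector<double> x(d), v(d);

  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < d; ++i) { x[i] = X0(r, i); v[i] = V0(r, i); }
    double u0 = beta * pot.U(x), t0 = kin_red(v, st.mass, beta);
    double dq = 0.0;
    bool ok = true;
    for (int k = 0; k < n_steps; ++k) {
      st.cycle(x, v, &dq);
      if (!state_ok(x, v)) { ok = false; break; }
    }
    stable[r] = ok;
    if (ok) {
      dh[r] = (beta * pot.U(x) + kin_red(v, st.mass, beta)) - (u0 + t0);
      dqv[r] = dq;
      work[r] = dh[r] - dq;
      for (int i = 0; i < d; ++i) { Xe(r, i) = x[i]; Ve(r, i) = v[i]; }
    } else {
      dh[r] = NA_REAL; dqv[r] = NA_REAL; work[r] = NA_REAL;
      for (int i = 0; i < d; ++i) { Xe(r, i) = NA_REAL; Ve(r, i) = NA_REAL; }
    }
  }
  return List::create(_["work"] = work, _["delta_h"] = dh, _["delta_q"] = dqv,
                      _["stable"] = stable, _["x_end"] = Xe, _["v_end"] = Ve);
}

// M independent n_steps-cycle realizations from one fixed start (fresh noise
// each): the inner loop of the nested Monte Carlo estimator.
// [[Rcpp::export]]
List cpp_inner_work(int code, NumericVector params, double beta,
                    NumericVector masses, IntegerVector letters,
                    NumericVector fractions, double dt, double gamma,
                    NumericVector x0, NumericVector v0, int n_steps, int M,
                    Nullable<Function> pfun = R_NilValue,
                    Nullable<Function> gfun = R_NilValue) {
  Function pf = pfun.isNotNull() ? Function(pfun) : Function("identity");
  Function gf = gfun.isNotNull() ? Function(gfun) : Function("identity");
  Potential pot = make_potential(code, params, &pf, &gf);
  Stepper st(&pot, letters, fractions, dt, gamma, masses, beta);

  const int d = x0.size();
  std::vector<double> x(d), v(d), xs(x0.begin(), x0.end()), vs(v0.begin(), v0.end());
  double u0 = beta * pot.U(xs), t0 = kin_red(vs, st.mass, beta);
  NumericVector work(M);
  LogicalVector stable(M);
  for (int r = 0; r < M; ++r) {
    x = xs; v = vs;
    double dq = 0.0;
    bool ok = true;
    for (int k = 0; k < n_steps; ++k) {
      st.cycle(x, v, &dq);
      if (!state_ok(x, v)) { ok = false; break; }
    }
    stable[r] = ok;
    work[r] = ok
      ? ((beta * pot.U(x) + kin_red(v, st.mass, beta)) - (u0 + t0) - dq)
      : NA_REAL;
  }
  return List::create(_["work"] = work, _["stable"] = stable);
}

// Long 1D trajectory -> joint (x, v) histogram counts on fixed edges.
// Cycle endpoints after burn-in are binned; out-of-range points are counted
// separately, never silently dropped.
// [[Rcpp::export]]
List cpp_phase_histogram(int code, NumericVector params, double beta,
                         NumericVector masses, IntegerVector letters,
                         NumericVector fractions, double dt, double gamma,
                         NumericVector x0, NumericVector v0,
                         int n_burn, int n_steps,
                         NumericVector xedges, NumericVector vedges,
                         Nullable<Function> pfun = R_NilValue,
                         Nullable<Function> gfun = R_NilValue) {
  if (x0.size() != 1) stop("phase-space histogram requires a 1D system");
  Function pf = pfun.isNotNull() ? Function(pfun) : Function("identity");
  Function gf = gfun.isNotNull() ? Function(gfun) : Function("identity");
  Potential pot = make_potential(code, params, &pf, &gf);
  Stepper st(&pot, letters, fractions, dt, gamma, masses, beta);

  const int nx = xedges.size() - 1, nv = vedges.size() - 1;
  NumericMatrix counts(nx, nv);
  std::vector<double> x(x0.begin(), x0.end()), v(v0.begin(), v0.end());
  double dq = 0.0;
  long n_out = 0;
  int failed_step = -1;
  const double xlo = xedges[0], xhi = xedges[nx], vlo = vedges[0], vhi = vedges[nv];
  const double dxw = (xhi - xlo) / nx, dvw = (vhi - vlo) / nv;

  for (int k = 0; k < n_burn + n_steps; ++k) {
    st.cycle(x, v, &dq);
    if (!state_ok(x, v)) { failed_step = k + 1; break; }
    if (k >= n_burn) {
      double xx = x[0], vv = v[0];
      if (xx >= xlo && xx < xhi && vv >= vlo && vv < vhi) {
        int ix = (int)((xx - xlo) / dxw); if (ix >= nx) ix = nx - 1;
        int iv = (int)((vv - vlo) / dvw); if (iv >= nv) iv = nv - 1;
        counts(ix, iv) += 1.0;
      } else ++n_out;
    }
  }
  return List::create(_["counts"] = counts, _["n_out"] = (double)n_out,
                      _["stable"] = (failed_step < 0),
                      _["failed_step"] = failed_step,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()));
}

// Bounding box of a trial trajectory (used to set histogram edges).
// [[Rcpp::export]]
List cpp_bounding_box(int code, NumericVector params, double beta,
                      NumericVector masses, IntegerVector letters,
                      NumericVector fractions, double dt, double gamma,
                      NumericVector x0, NumericVector v0, int n_steps,
                      Nullable<Function> pfun = R_NilValue,
                      Nullable<Function> gfun = R_NilValue) {
  Function pf = pfun.isNotNull() ? Function(pfun) : Function("identity");
  Function gf = gfun.isNotNull() ? Function(gfun) : Function("identity");
  Potential pot = make_potential(code, params, &pf, &gf);
  Stepper st(&pot, letters, fractions, dt, gamma, masses, beta);

  const int d = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), v(v0.begin(), v0.end());
  NumericVector xmin(d, R_PosInf), xmax(d, R_NegInf),
                vmin(d, R_PosInf), vmax(d, R_NegInf);
  double dq = 0.0;
  int failed_step = -1;
  for (int k = 0; k < n_steps; ++k) {
    st.cycle(x, v, &dq);
    if (!state_ok(x, v)) { failed_step = k + 1; break; }
    for (int i = 0; i < d; ++i) {
      if (x[i] < xmin[i]) xmin[i] = x[i];
      if (x[i] > xmax[i]) xmax[i] = x[i];
      if (v[i] < vmin[i]) vmin[i] = v[i];
      if (v[i] > vmax[i]) vmax[i] = v[i];
    }
  }
  return List::create(_["xmin"] = xmin, _["xmax"] = xmax,
                      _["vmin"] = vmin, _["vmax"] = vmax,
                      _["stable"] = (failed_step < 0),
                      _["failed_step"] = failed_step);
}

// GHMC chain: each iteration proposes steps_per_proposal integrator cycles,
// accepts with min(1, e^{-w_shad}), and negates the velocity on rejection
// (detailed balance).  Velocity randomization is supplied by the O substeps
// inside the proposal.  Positions recorded every `thin` iterations.
// [[Rcpp::export]]
List cpp_ghmc_chain(int code, NumericVector params, double beta,
                    NumericVector masses, IntegerVector letters,
                    NumericVector fractions, double dt, double gamma,
                    NumericVector x0, NumericVector v0,
                    int steps_per_proposal, int n_iterations, int thin,
                    Nullable<Function> pfun = R_NilValue,
                    Nullable<Function> gfun = R_NilValue) {
  Function pf = pfun.isNotNull() ? Function(pfun) : Function("identity");
  Function gf = gfun.isNotNull() ? Function(gfun) : Function("identity");
  Potential pot = make_potential(code, params, &pf, &gf);
  Stepper st(&pot, letters, fractions, dt, gamma, masses, beta);

  const int d = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), v(v0.begin(), v0.end());
  std::vector<double> xp(d), vp(d);
  int n_keep = n_iterations / thin;
  NumericMatrix X(n_keep, d);
  int kept = 0;
  long n_accept = 0;

  for (int it = 0; it < n_iterations; ++it) {
    xp = x; vp = v;
    double u0 = beta * pot.U(xp), t0 = kin_red(vp, st.mass, beta);
    double dq = 0.0;
    bool ok = true;
    for (int k = 0; k < steps_per_proposal; ++k) {
      st.cycle(xp, vp, &dq);
      if (!state_ok(xp, vp)) { ok = false; break; }
    }
    bool accept = false;
    if (ok) {
      double w = (beta * pot.U(xp) + kin_red(vp, st.mass, beta)) - (u0 + t0) - dq;
      accept = (w <= 0.0) || (unif_rand() < std::exp(-w));
    }
    if (accept) {
      x = xp; v = vp; ++n_accept;
    } else {
      for (int i = 0; i < d; ++i) v[i] = -v[i];  // momentum flip
    }
    if ((it + 1) % thin == 0 && kept < n_keep) {
      for (int i = 0; i < d; ++i) X(kept, i) = x[i];
      ++kept;
    }
  }
  return List::create(_["positions"] = X, _["n_accept"] = (double)n_accept,
                      _["n_proposals"] = (double)n_iterations,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()));
}
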