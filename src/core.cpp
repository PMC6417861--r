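#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thomas algorithm for a constant-coefficient tridiagonal system
//   off * x[i-1] + diag * x[i] + off * x[i+1] = d[i]
// with the first/last diagonal entries overridden (needed by the cyclic wrapper).
static void thomas_const(int n, double off, double diag0, double diag, double diagN,
                         const double* d, double* x, double* cp) {
  // forward sweep
  double b0 = diag0;
  cp[0] = off / b0;
  x[0] = d[0] / b0;
  for (int i = 1; i < n; ++i) {
    double bi = (i == n - 1) ? diagN : diag;
    double m = bi - off * cp[i - 1];
    cp[i] = off / m;
    x[i] = (d[i] - off * x[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
}

// Solve the periodic (cyclic) system with uniform diagonal `diag` and uniform
// off-diagonal `off` (including the two wrap-around corners) via
// Sherman-Morrison. Work arrays must have length n.
static void cyclic_const(int n, double off, double diag, const double* d, double* x,
                         double* z, double* cp, double* u) {
  double gamma = -diag;
  double diag0 = diag - gamma;
  double diagN = diag - off * off / gamma;
  thomas_const(n, off, diag0, diag, diagN, d, x, cp);
  for (int i = 0; i < n; ++i) u[i] = 0.0;
  u[0] = gamma;
  u[n - 1] = off;
  thomas_const(n, off, diag0, diag, diagN, u, z, cp);
  double fact = (x[0] + off * x[n - 1] / gamma) / (1.0 + z[0] + off * z[n - 1] / gamma);
  for (int i = 0; i < n; ++i) x[i] -= fact * z[i];
}

// [[Rcpp::export]]
NumericVector cpp_cyclic_solve(double off, double diag, NumericVector rhs) {
  int n = rhs.size();
  NumericVector out(n);
  std::vector<double> z(n), cp(n), u(n);
  cyclic_const(n, off, diag, rhs.begin(), out.begin(), z.data(), cp.data(), u.data());
  return out;
}

// Force balance gamma*v - eta*v'' = d(Pi)/dx on a periodic grid, second-order
// centred differences. Pi is the spatially varying part of the stress.
static void force_balance_fd(int n, double dx, double eta, double gamma,
                             const double* Pi, double* v,
                             double* g, double* z, double* cp, double* u) {
  double inv2dx = 1.0 / (2.0 * dx);
  for (int i = 0; i < n; ++i) {
    int ip = (i + 1 == n) ? 0 : i + 1;
    int im = (i == 0) ? n - 1 : i - 1;
    g[i] = (Pi[ip] - Pi[im]) * inv2dx;
  }
  double s = eta / (dx * dx);
  cyclic_const(n, -s, gamma + 2.0 * s, g, v, z, cp, u);
}

// [[Rcpp::export]]
NumericVector cpp_force_balance_fd(NumericVector Pi, double eta, double gamma, double dx) {
  int n = Pi.size();
  NumericVector v(n);
  std::vector<double> g(n), z(n), cp(n), u(n);
  force_balance_fd(n, dx, eta, gamma, Pi.begin(), v.begin(), g.data(), z.data(),
                   cp.data(), u.data());
  return v;
}

// Semi-implicit integrator for the coupled PAR / active-gel system.
//
// Per step: (1) stress Pi = -beta*P - trig(x)*exp(-t/t_trig); (2) force balance
// solve for v; (3) first-order upwind advection in conservative flux form;
// (4) exchange + antagonism reactions, with linear sinks treated implicitly so
// positivity is unconditional; cytoplasmic pools are slaved to mass
// conservation (Acyto = rhoA - psi*mean(A)); (5) implicit diffusion via a
// cyclic tridiagonal solve.
// [[Rcpp::export]]
List cpp_integrate(NumericVector A0, NumericVector P0, NumericVector konP,
                   NumericVector trig, List par, double dx, double t0,
                   double t_max, double dt_max, double cfl_frac, double tol,
                   double t_min, int check_every, double record_dt) {
  int n = A0.size();
  const double DA = par["D_A"], DP = par["D_P"];
  const double konA = par["kon_A"], koffA = par["koff_A"], koffP = par["koff_P"];
  const double kAP = par["k_AP"], kPA = par["k_PA"];
  const double eta = par["eta"], gam = par["gamma"], beta = par["beta"];
  const double psi = par["psi"], rhoA = par["rho_A"], rhoP = par["rho_P"];
  const double t_trig = par["t_trig"];

  std::vector<double> A(A0.begin(), A0.end()), P(P0.begin(), P0.end());
  std::vector<double> v(n, 0.0), Pi(n), FA(n), FP(n), Pref(P);
  std::vector<double> g(n), z(n), cp(n), u(n), w1(n), w2(n);

  int max_rows = (int)std::ceil((t_max - t0) / record_dt) + 3;
  NumericMatrix kymo(max_rows, n);
  NumericVector ktimes(max_rows);
  int row = 0;
  double next_rec = t0;

  double t = t0, t_ref = t0;
  bool converged = false;
  long step = 0;
  double dt = dt_max;

  while (t < t_max - 1e-12) {
    // record
    if (t >= next_rec - 1e-9) {
      for (int i = 0; i < n; ++i) kymo(row, i) = P[i];
      ktimes[row] = t;
      ++row;
      next_rec += record_dt;
    }

    // stress and force balance
    double trig_fac = (t_trig > 0.0) ? std::exp(-(t - t0) / t_trig) : 0.0;
    for (int i = 0; i < n; ++i) Pi[i] = -beta * P[i] - trig[i] * trig_fac;
    force_balance_fd(n, dx, eta, gam, Pi.data(), v.data(), g.data(), z.data(),
                     cp.data(), u.data());

    // time step from the upwind CFL limit
    double vmax = 0.0;
    for (int i = 0; i < n; ++i) vmax = std::max(vmax, std::fabs(v[i]));
    dt = dt_max;
    if (vmax > 0.0) dt = std::min(dt, cfl_frac * dx / vmax);
    if (t + dt > t_max) dt = t_max - t;

    // upwind advection, conservative flux form (face i between cells i and i+1)
    for (int i = 0; i < n; ++i) {
      int ip = (i + 1 == n) ? 0 : i + 1;
      double vf = 0.5 * (v[i] + v[ip]);
      if (vf > 0.0) { FA[i] = vf * A[i]; FP[i] = vf * P[i]; }
      else          { FA[i] = vf * A[ip]; FP[i] = vf * P[ip]; }
    }
    double r = dt / dx;
    for (int i = 0; i < n; ++i) {
      int im = (i == 0) ? n - 1 : i - 1;
      A[i] -= r * (FA[i] - FA[im]);
      P[i] -= r * (FP[i] - FP[im]);
    }

    // reactions: explicit gains, implicit linear sinks (positivity-preserving)
    double mA = 0.0, mP = 0.0;
    for (int i = 0; i < n; ++i) { mA += A[i]; mP += P[i]; }
    mA /= n; mP /= n;
    double Acyto = rhoA - psi * mA;
    double Pcyto = rhoP - psi * mP;
    if (Acyto < 0.0) Acyto = 0.0;
    if (Pcyto < 0.0) Pcyto = 0.0;
    for (int i = 0; i < n; ++i) {
      double Aold = A[i], Pold = P[i];
      A[i] = (Aold + dt * konA * Acyto) / (1.0 + dt * (koffA + kAP * Pold));
      P[i] = (Pold + dt * konP[i] * Pcyto) / (1.0 + dt * (koffP + kPA * Aold * Aold));
    }

    // implicit diffusion
    double sA = dt * DA / (dx * dx), sP = dt * DP / (dx * dx);
    cyclic_const(n, -sA, 1.0 + 2.0 * sA, A.data(), w1.data(), z.data(), cp.data(), u.data());
    std::copy(w1.begin(), w1.end(), A.begin());
    cyclic_const(n, -sP, 1.0 + 2.0 * sP, P.data(), w1.data(), z.data(), cp.data(), u.data());
    std::copy(w1.begin(), w1.end(), P.begin());

    t += dt;
    ++step;

    if (step % check_every == 0) {
      bool bad = false;
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(A[i]) || !std::isfinite(P[i]) || A[i] < -1e-9 || P[i] < -1e-9)
          bad = true;
      if (bad)
        stop("numerical blow-up at t=%.3f with dt=%.5f; reduce dt_max", t, dt);
      double rate = 0.0;
      for (int i = 0; i < n; ++i) rate = std::max(rate, std::fabs(P[i] - Pref[i]));
      rate /= (t - t_ref);
      std::copy(P.begin(), P.end(), Pref.begin());
      t_ref = t;
      if (rate < tol && (t - t0) >= t_min) { converged = true; break; }
    }
  }

  // final record
  for (int i = 0; i < n; ++i) kymo(row, i) = P[i];
  ktimes[row] = t;
  ++row;

  double mA = 0.0, mP = 0.0;
  for (int i = 0; i < n; ++i) { mA += A[i]; mP += P[i]; }
  mA /= n; mP /= n;

  return List::create(
      _["A"] = NumericVector(A.begin(), A.end()),
      _["P"] = NumericVector(P.begin(), P.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["A_cyto"] = std::max(0.0, rhoA - psi * mA),
      _["P_cyto"] = std::max(0.0, rhoP - psi * mP),
      _["t"] = t, _["converged"] = converged, _["n_steps"] = (double)step,
      _["kymo"] = kymo(Range(0, row - 1), _),
      _["kymo_times"] = ktimes[Range(0, row - 1)]);
}
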