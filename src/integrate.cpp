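#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Polynomial evaluation, coefficients in increasing powers.
static inline double pv(const std::vector<double>& c, double x) {
  double r = c.back();
  for (int k = (int)c.size() - 2; k >= 0; --k) r = r * x + c[k];
  return r;
}

struct FluxWork {
  int N;
  double dx, Pe;
  bool upwind;
  std::vector<double> dsc, Dc;
  std::vector<double> rho, m, Fp, Fm, F0;
  double maxdiff, maxv;
  FluxWork(int N_, double dx_, double Pe_,
           const NumericVector& dscoef, const NumericVector& Dcoef,
           bool upwind_ = true)
    : N(N_), dx(dx_), Pe(Pe_), upwind(upwind_),
      dsc(dscoef.begin(), dscoef.end()), Dc(Dcoef.begin(), Dcoef.end()),
      rho(N_), m(N_), Fp(N_), Fm(N_), F0(N_), maxdiff(1.0), maxv(0.0) {}

  // rhs of the 1D hydrodynamic equations, first-order finite volume:
  // centered two-point diffusive fluxes, upwinded advective fluxes,
  // pointwise orientation-flip reaction -sigma*m.
  void rhs(const double* rp, const double* rm, const double* r0,
           double* dp, double* dm, double* d0) {
    for (int i = 0; i < N; ++i) {
      rho[i] = rp[i] + rm[i] + r0[i];
      m[i] = rp[i] - rm[i];
    }
    maxdiff = 1e-300; maxv = 0.0;
    for (int i = 0; i < N; ++i) {
      int j = (i + 1 == N) ? 0 : i + 1;
      double rf = 0.5 * (rho[i] + rho[j]);
      double mf = 0.5 * (m[i] + m[j]);
      double ds = pv(dsc, rf);
      double D  = pv(Dc, rf);
      double s  = D - 1.0;
      double gr = (rho[j] - rho[i]) / dx;
      double diff = ds + rf * D;
      if (diff > maxdiff) maxdiff = diff;
      // species +1
      {
        double g = (rp[j] - rp[i]) / dx, uf = 0.5 * (rp[i] + rp[j]);
        double v = Pe * (s * mf + ds);
        if (std::fabs(v) > maxv) maxv = std::fabs(v);
        Fp[i] = -(ds * g + uf * D * gr) +
                (upwind ? (v > 0 ? v * rp[i] : v * rp[j]) : v * uf);
      }
      // species -1
      {
        double g = (rm[j] - rm[i]) / dx, uf = 0.5 * (rm[i] + rm[j]);
        double v = Pe * (s * mf - ds);
        if (std::fabs(v) > maxv) maxv = std::fabs(v);
        Fm[i] = -(ds * g + uf * D * gr) +
                (upwind ? (v > 0 ? v * rm[i] : v * rm[j]) : v * uf);
      }
      // species 0
      {
        double g = (r0[j] - r0[i]) / dx, uf = 0.5 * (r0[i] + r0[j]);
        double v = Pe * s * mf;
        if (std::fabs(v) > maxv) maxv = std::fabs(v);
        F0[i] = -(ds * g + uf * D * gr) +
                (upwind ? (v > 0 ? v * r0[i] : v * r0[j]) : v * uf);
      }
    }
    for (int i = 0; i < N; ++i) {
      int im = (i == 0) ? N - 1 : i - 1;
      dp[i] = -(Fp[i] - Fp[im]) / dx - m[i];
      dm[i] = -(Fm[i] - Fm[im]) / dx + m[i];
      d0[i] = -(F0[i] - F0[im]) / dx;
    }
  }
};

// [[Rcpp::export]]
List aplg_rhs_cpp(NumericVector rp, NumericVector rm, NumericVector r0,
                  double L, double Pe,
                  NumericVector ds_coef, NumericVector D_coef,
                  bool upwind = true) {
  int N = rp.size();
  FluxWork w(N, L / N, Pe, ds_coef, D_coef, upwind);
  NumericVector dp(N), dm(N), d0(N);
  w.rhs(rp.begin(), rm.begin(), r0.begin(), dp.begin(), dm.begin(), d0.begin());
  return List::create(_["dp"] = dp, _["dm"] = dm, _["d0"] = d0);
}

// Forward Euler with adaptive time step: diffusive + advective CFL limits,
// further halved on positivity violation (densities must stay in [0,1]).
// [[Rcpp::export]]
List aplg_integrate_cpp(NumericVector rp0, NumericVector rm0, NumericVector r00,
                        double L, double Pe,
                        NumericVector ds_coef, NumericVector D_coef,
                        NumericVector save_times, double t0, double cfl,
                        bool upwind = true) {
  int N = rp0.size();
  int ns = save_times.size();
  double dx = L / N;
  FluxWork w(N, dx, Pe, ds_coef, D_coef, upwind);

  std::vector<double> rp(rp0.begin(), rp0.end());
  std::vector<double> rm(rm0.begin(), rm0.end());
  std::vector<double> r0(r00.begin(), r00.end());
  std::vector<double> dp(N), dm(N), d0(N), trp(N), trm(N), tr0(N);

  NumericMatrix RP(ns, N), RM(ns, N), R0(ns, N);
  double t = t0;
  long long nsteps = 0;
  int k = 0;
  // save any times at/before t0
  while (k < ns && save_times[k] <= t + 1e-14) {
    for (int i = 0; i < N; ++i) { RP(k,i)=rp[i]; RM(k,i)=rm[i]; R0(k,i)=r0[i]; }
    ++k;
  }
  while (k < ns) {
    w.rhs(rp.data(), rm.data(), r0.data(), dp.data(), dm.data(), d0.data());
    double dt = cfl * dx * dx / (2.0 * w.maxdiff);
    if (w.maxv > 0) {
      double dta = cfl * dx / (2.0 * w.maxv);
      if (dta < dt) dt = dta;
    }
    if (t + dt > save_times[k]) dt = save_times[k] - t;
    for (;;) {
      bool ok = true;
      for (int i = 0; i < N; ++i) {
        trp[i] = rp[i] + dt * dp[i];
        trm[i] = rm[i] + dt * dm[i];
        tr0[i] = r0[i] + dt * d0[i];
        double rho = trp[i] + trm[i] + tr0[i];
        if (trp[i] < -1e-13 || trm[i] < -1e-13 || tr0[i] < -1e-13 ||
            rho > 1.0 + 1e-13 || !std::isfinite(rho)) { ok = false; break; }
      }
      if (ok) break;
      dt *= 0.5;
      if (dt < 1e-12)
        stop("time step underflow (dt < 1e-12) at t = %f: stiffness or invalid state", t);
    }
    rp.swap(trp); rm.swap(trm); r0.swap(tr0);
    t += dt;
    ++nsteps;
    if (nsteps % 50000 == 0) Rcpp::checkUserInterrupt();
    while (k < ns && t >= save_times[k] - 1e-12) {
      for (int i = 0; i < N; ++i) { RP(k,i)=rp[i]; RM(k,i)=rm[i]; R0(k,i)=r0[i]; }
      ++k;
    }
  }
  return List::create(_["times"] = save_times, _["rp"] = RP, _["rm"] = RM,
                      _["r0"] = R0, _["nsteps"] = (double)nsteps);
}
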