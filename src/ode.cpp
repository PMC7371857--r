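// Adaptive Dormand-Prince RK45 integration of the PK / receptor / PAL ODE
// systems.  Compiled because model fitting evaluates the PAL ODEs thousands
// of times inside the annealing / pattern-search / gradient stages.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Forcing function u(t): how the driving signal (C_MPL or DRN) is described.
//   mode 0: constant value
//   mode 1: piecewise-linear interpolation on a (t, v) grid, clamped at ends
//   mode 2: c1*exp(l1*t) + c2*exp(l2*t) + css  (closed-form linear-PK output)
struct Forcing {
  int mode;
  double value;                       // mode 0
  std::vector<double> t, v;           // mode 1
  double c1, l1, c2, l2, css;         // mode 2
  size_t hint;                        // last interpolation interval

  Forcing() : mode(0), value(0.0), c1(0), l1(0), c2(0), l2(0), css(0), hint(0) {}

  double operator()(double tt) {
    switch (mode) {
    case 0: return value;
    case 1: {
      size_t n = t.size();
      if (tt <= t.front()) return v.front();
      if (tt >= t.back())  return v.back();
      size_t i = hint;
      if (i >= n - 1 || t[i] > tt) i = 0;
      while (i < n - 2 && t[i + 1] < tt) ++i;
      hint = i;
      double w = (tt - t[i]) / (t[i + 1] - t[i]);
      return v[i] + w * (v[i + 1] - v[i]);
    }
    default:
      return c1 * std::exp(l1 * tt) + c2 * std::exp(l2 * tt) + css;
    }
  }
};

// model ids
enum { MODEL_PK = 1, MODEL_RECEPTOR = 2, MODEL_PAL_RECEPTOR = 3,
       MODEL_PAL_BIOSIGNAL = 4 };

static void rhs(int model, double t, const double* y, double* dy,
                const std::vector<double>& p, Forcing& u) {
  switch (model) {
  case MODEL_PK: {
    // p = (k0, CL, Vp, k12, k21); y = (Ap, At)
    const double k0 = p[0], CL = p[1], Vp = p[2], k12 = p[3], k21 = p[4];
    dy[0] = k0 + k21 * y[1] - (k12 + CL / Vp) * y[0];
    dy[1] = k12 * y[0] - k21 * y[1];
    break;
  }
  case MODEL_RECEPTOR: {
    // p = (ksRm, kdRm, IC50Rm, ksR, kre, kon, kdR, kT, Rf); y = (Rm, R, DR, DRN)
    const double ksRm = p[0], kdRm = p[1], IC50Rm = p[2], ksR = p[3],
                 kre = p[4], kon = p[5], kdR = p[6], kT = p[7], Rf = p[8];
    const double C = u(t);
    const double Rm = y[0], R = y[1], DR = y[2], DRN = y[3];
    dy[0] = ksRm * (1.0 - DRN / (IC50Rm + DRN)) - kdRm * Rm;
    dy[1] = ksR * Rm + Rf * kre * DRN - kon * C * R - kdR * R;
    dy[2] = kon * C * R - kT * DR;
    dy[3] = kT * DR - kre * DRN;
    break;
  }
  case MODEL_PAL_RECEPTOR: {
    // p = (ks, kd, IC50, sign); y = (PAL)
    const double ks = p[0], kd = p[1], IC50 = p[2], sgn = p[3];
    const double DRN = u(t);
    dy[0] = ks * (1.0 + sgn * DRN / (IC50 + DRN)) - kd * y[0];
    break;
  }
  default: {
    // p = (ks, kd, IC50, ke, S, gamma, drn_sign, bs_sign); y = (BS, PAL)
    const double ks = p[0], kd = p[1], IC50 = p[2], ke = p[3], S = p[4],
                 gam = p[5], s1 = p[6], s2 = p[7];
    const double DRN = u(t);
    const double BS = y[0] > 0.0 ? y[0] : 0.0;
    dy[0] = ke * (DRN - y[0]);
    const double bg = std::pow(BS, gam);
    const double hill = bg / (std::pow(IC50, gam) + bg);
    dy[1] = ks * (1.0 + s1 * S * DRN) * (1.0 + s2 * hill) - kd * y[1];
    break;
  }
  }
}

// Dormand-Prince 5(4) coefficients
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
                    A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
                    A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
                    A65 = -5103.0 / 18656.0;
static const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0, B4 = 125.0 / 192.0,
                    B5 = -2187.0 / 6784.0, B6 = 11.0 / 84.0;
static const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0,
                    E4 = 71.0 / 1920.0, E5 = -17253.0 / 339200.0,
                    E6 = 22.0 / 525.0, E7 = -1.0 / 40.0;
static const double C2 = 0.2, C3 = 0.3, C4 = 0.8, C5 = 8.0 / 9.0;

// [[Rcpp::export(name = ".ode_solve")]]
NumericMatrix ode_solve(int model, NumericVector y0, NumericVector times,
                        NumericVector pars, List forcing,
                        double rtol = 1e-10, double atol = 1e-12,
                        double hmax = 0.0, double max_steps = 5e6) {
  const int d = y0.size();
  const int nt = times.size();
  std::vector<double> p(pars.begin(), pars.end());

  Forcing u;
  u.mode = as<int>(forcing["mode"]);
  if (u.mode == 0) {
    u.value = as<double>(forcing["value"]);
  } else if (u.mode == 1) {
    NumericVector ft = forcing["t"], fv = forcing["v"];
    u.t.assign(ft.begin(), ft.end());
    u.v.assign(fv.begin(), fv.end());
  } else {
    u.c1 = as<double>(forcing["c1"]); u.l1 = as<double>(forcing["l1"]);
    u.c2 = as<double>(forcing["c2"]); u.l2 = as<double>(forcing["l2"]);
    u.css = as<double>(forcing["css"]);
  }

  NumericMatrix out(nt, d);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(d), k2(d), k3(d), k4(d), k5(d), k6(d), k7(d),
      ytmp(d), ynew(d);

  double t = times[0];
  for (int j = 0; j < d; ++j) out(0, j) = y[j];

  double tend = times[nt - 1];
  if (hmax <= 0.0) hmax = (tend - t) > 0 ? (tend - t) : 1.0;
  double h = std::min(1e-4, hmax);
  int iout = 1;
  long steps = 0;
  bool first = true;

  rhs(model, t, y.data(), k1.data(), p, u);

  while (iout < nt) {
    if (++steps > (long)max_steps)
      stop("ODE integration exceeded maximum number of steps");
    double tnext = times[iout];
    if (h > tnext - t) h = tnext - t;
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) h = 1e-14 * std::max(1.0, std::fabs(t));

    // stages (FSAL: k1 already holds f(t, y))
    for (int j = 0; j < d; ++j) ytmp[j] = y[j] + h * A21 * k1[j];
    rhs(model, t + C2 * h, ytmp.data(), k2.data(), p, u);
    for (int j = 0; j < d; ++j) ytmp[j] = y[j] + h * (A31 * k1[j] + A32 * k2[j]);
    rhs(model, t + C3 * h, ytmp.data(), k3.data(), p, u);
    for (int j = 0; j < d; ++j)
      ytmp[j] = y[j] + h * (A41 * k1[j] + A42 * k2[j] + A43 * k3[j]);
    rhs(model, t + C4 * h, ytmp.data(), k4.data(), p, u);
    for (int j = 0; j < d; ++j)
      ytmp[j] = y[j] + h * (A51 * k1[j] + A52 * k2[j] + A53 * k3[j] + A54 * k4[j]);
    rhs(model, t + C5 * h, ytmp.data(), k5.data(), p, u);
    for (int j = 0; j < d; ++j)
      ytmp[j] = y[j] + h * (A61 * k1[j] + A62 * k2[j] + A63 * k3[j] +
                            A64 * k4[j] + A65 * k5[j]);
    rhs(model, t + h, ytmp.data(), k6.data(), p, u);
    for (int j = 0; j < d; ++j)
      ynew[j] = y[j] + h * (B1 * k1[j] + B3 * k3[j] + B4 * k4[j] +
                            B5 * k5[j] + B6 * k6[j]);
    rhs(model, t + h, ynew.data(), k7.data(), p, u);

    // error estimate
    double errnorm = 0.0;
    for (int j = 0; j < d; ++j) {
      double e = h * (E1 * k1[j] + E3 * k3[j] + E4 * k4[j] + E5 * k5[j] +
                      E6 * k6[j] + E7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / d);
    if (!std::isfinite(errnorm)) errnorm = 1e10;

    if (errnorm <= 1.0) {
      t += h;
      y = ynew;
      std::swap(k1, k7);  // FSAL
      first = false;
      while (iout < nt && times[iout] <= t + 1e-12 * std::max(1.0, std::fabs(t))) {
        for (int j = 0; j < d; ++j) out(iout, j) = y[j];
        ++iout;
      }
    }
    double fac = 0.9 * std::pow(errnorm > 1e-30 ? errnorm : 1e-30, -0.2);
    fac = std::min(first ? 2.0 : 5.0, std::max(0.2, fac));
    h = std::min(hmax, h * fac);
  }
  return out;
}
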