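#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-moment amyloid kinetics, integrated with an adaptive Cash-Karp RK45.
// State: y[0] = P (fibril number concentration), y[1] = M (fibril mass
// concentration); monomer m = m0 - M. Model ids:
//   0 nucleation_elongation   dP = kn*m^nc
//   1 secondary_nucleation    dP = kn*m^nc + k2*m^n2*M
//   2 fragmentation           dP = kn*m^nc + km*M
//   3 saturating elongation + fragmentation:
//        dP = kn*m^nc + km*M;  dM = 2*kplus*m*P / (1 + m/KS)
// Otherwise dM = 2*kplus*m*P.

struct Params {
  int model;
  double kn, kplus, km, k2, KS, m0;
  double nc, n2;
};

static inline void rhs(double /*t*/, const double y[2], double dy[2],
                       const Params &p) {
  double m = p.m0 - y[1];
  if (m < 0.0) m = 0.0;
  double P = y[0];
  double dP = p.kn * std::pow(m, p.nc);
  if (p.model == 1) dP += p.k2 * std::pow(m, p.n2) * y[1];
  if (p.model == 2 || p.model == 3) dP += p.km * y[1];
  double dM = 2.0 * p.kplus * m * P;
  if (p.model == 3) dM /= (1.0 + m / p.KS);
  dy[0] = dP;
  dy[1] = dM;
}

// Cash-Karp coefficients
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                    b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                    c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                    d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                    d6 = c6 - 1.0 / 4.0;

// one trial step; returns error estimate in err[]
static void ck_step(double t, const double y[2], double h, double ynew[2],
                    double err[2], const Params &p) {
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], yt[2];
  rhs(t, y, k1, p);
  for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * b21 * k1[i];
  rhs(t + 0.2 * h, yt, k2, p);
  for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
  rhs(t + 0.3 * h, yt, k3, p);
  for (int i = 0; i < 2; ++i)
    yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
  rhs(t + 0.6 * h, yt, k4, p);
  for (int i = 0; i < 2; ++i)
    yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
  rhs(t + h, yt, k5, p);
  for (int i = 0; i < 2; ++i)
    yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                        b64 * k4[i] + b65 * k5[i]);
  rhs(t + 0.875 * h, yt, k6, p);
  for (int i = 0; i < 2; ++i) {
    ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    err[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                  d6 * k6[i]);
  }
}

// [[Rcpp::export(name = ".ode_moments")]]
NumericMatrix ode_moments(int model, double kn, double kplus, double km,
                          double k2, double KS, double nc, double n2,
                          double m0, NumericVector times, double rtol,
                          double atol) {
  Params p;
  p.model = model; p.kn = kn; p.kplus = kplus; p.km = km; p.k2 = k2;
  p.KS = KS; p.m0 = m0; p.nc = nc; p.n2 = n2;

  int nt = times.size();
  NumericMatrix out(nt, 2);  // columns: P, M
  double y[2] = {0.0, 0.0};
  double t = times[0];
  out(0, 0) = 0.0; out(0, 1) = 0.0;
  double tend = times[nt - 1];
  double h = (tend - t) / 1000.0;
  if (h <= 0.0) stop("times must be increasing");
  int next = 1;
  const int max_steps = 20000000;
  int steps = 0;
  double ynew[2], err[2];
  while (next < nt) {
    double tstop = times[next];
    if (t + h > tstop) h = tstop - t;
    ck_step(t, y, h, ynew, err, p);
    double emax = 0.0;
    for (int i = 0; i < 2; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = std::fabs(err[i]) / sc;
      if (e > emax) emax = e;
    }
    if (emax <= 1.0) {
      t += h;
      y[0] = ynew[0]; y[1] = ynew[1];
      if (y[1] > m0) y[1] = m0;  // clamp mass to conservation bound
      if (std::fabs(t - tstop) < 1e-12 * std::max(1.0, std::fabs(tstop))) {
        out(next, 0) = y[0];
        out(next, 1) = y[1];
        ++next;
      }
      double fac = 0.9 * std::pow(std::max(emax, 1e-16), -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(emax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
    if (h < 1e-14 * std::max(1.0, std::fabs(tend)))
      stop("step size underflow in kinetic ODE integration");
    if (++steps > max_steps)
      stop("kinetic ODE integration exceeded the step budget");
  }
  return out;
}
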