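#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout (kept in step with .param_vector() on the R side):
// 0 pG, 1 SI, 2 alphaG, 3 alphaI, 4 nI, 5 nK, 6 nL, 7 nC,
// 8 VG, 9 VI, 10 EGP, 11 CNS, 12 d1, 13 d2

static inline void icing_deriv(const double *y, double *dy, const double *p,
                               double uex, double uen, double upn) {
  const double G = y[0], I = y[1], Q = y[2], P1 = y[3], P2 = y[4];
  const double Qeff = Q / (1.0 + p[2] * Q);       // saturable insulin effect
  const double Pin  = p[13] * P2 + upn;           // glucose appearance (mmol/min)
  dy[0] = -p[0] * G - p[1] * G * Qeff + (Pin + p[10] - p[11]) / p[8];
  dy[1] = -p[5] * I - p[6] * I / (1.0 + p[3] * I) - p[4] * (I - Q) + uex / p[9];
  dy[2] = p[4] * (I - Q) - p[7] * Qeff;
  dy[3] = -p[12] * P1 + uen;
  dy[4] = p[12] * P1 - p[13] * P2;
}

// Fixed-step classical RK4 over [t0, t0 + horizon] with piecewise-constant
// inputs held constant for the whole call. Returns a matrix with columns
// t, G, I, Q, P1, P2 at t0, t0+dt, ..., t0+horizon.
// [[Rcpp::export(name = ".icing_rk4")]]
NumericMatrix icing_rk4(NumericVector state0, NumericVector params,
                        double uex, double uen, double upn,
                        double t0, double horizon, double dt) {
  if (horizon <= 0) stop("horizon must be positive");
  if (dt <= 0) stop("dt must be positive");
  const int nstep = (int)std::ceil(horizon / dt - 1e-9);
  NumericMatrix out(nstep + 1, 6);
  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  const double *p = params.begin();
  for (int j = 0; j < 5; ++j) y[j] = state0[j];

  double t = 0.0;
  out(0, 0) = t0;
  for (int j = 0; j < 5; ++j) out(0, j + 1) = y[j];

  for (int i = 0; i < nstep; ++i) {
    double h = std::min(dt, horizon - t);
    icing_deriv(y, k1, p, uex, uen, upn);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
    icing_deriv(tmp, k2, p, uex, uen, upn);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
    icing_deriv(tmp, k3, p, uex, uen, upn);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + h * k3[j];
    icing_deriv(tmp, k4, p, uex, uen, upn);
    for (int j = 0; j < 5; ++j) {
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (y[j] < 0.0) y[j] = 0.0;   // positivity guard at the step boundary
    }
    t += h;
    for (int j = 0; j < 5; ++j) {
      if (!R_finite(y[j]))
        stop("integration failure: non-finite state at t = %f min", t0 + t);
    }
    out(i + 1, 0) = t0 + t;
    for (int j = 0; j < 5; ++j) out(i + 1, j + 1) = y[j];
  }
  return out;
}
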