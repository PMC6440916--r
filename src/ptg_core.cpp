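// Compiled core: full model right-hand side and an adaptive embedded
// Dormand-Prince 5(4) integrator with exact restarts at input breakpoints.
// The R sources define the same equations module by module; the test suite
// cross-checks the two transcriptions at random states.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>

using namespace Rcpp;

// mg/dL per mmol/L of calcium
static const double CA_MGDL_PER_MMOL = 4.008;

// --- parameter vector layout (must match flatten_params() in R/engine.R) ---
// 0  K_C, 1  W1_C, 2  C_opt
// 3  K_P, 4  W1_P, 5  P_opt
// 6  K_D, 7  W1_D, 8  D_opt
// 9  p_ca, 10 n_ca, 11 p_d, 12 n_d, 13 tau_c, 14 tau_d, 15 tau_p
// 16..21 degradation  (p, n, tau_ca, tau_p, A, B)
// 22..27 production   (p, n, tau_ca, tau_p, A, B)
// 28..33 proliferation(p, n, tau_ca, tau_p, A, B)
// 34 k_sq, 35 k_qs, 36 k_a, 37 k_k, 38 A_rel, 39 B_rel, 40 s_r, 41 m,
// 42 k_cl, 43 a_s, 44 s0q0

// --- state vector layout (must match state_names() in R/engine.R) ---
// 0 casr, 1 vdr, 2 chi_in, 3 delta_in, 4 pi_in, 5 cs, 6 ds,
// 7 chi_d, 8 chi_in_d, 9 pi_in_d,
// 10 chi_p, 11 chi_in_p, 12 pi_in_p,
// 13 chi_pr, 14 chi_in_pr, 15 pi_in_pr,
// 16 ptg, 17 pth, 18 s, 19 q, 20 k_cap

static inline double logistic(double z) {
  // numerically safe 1 / (1 + exp(-z))
  if (z >= 0.0) {
    return 1.0 / (1.0 + std::exp(-z));
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

static inline double stimf(double x, double K, double W1) {
  return logistic(K * (x - W1)) + logistic(K * (x + W1)) - 1.0;
}

static inline double effect_rhs(double e, double s, double tau) {
  double sg = (s > 0.0) - (s < 0.0);
  return (s * (1.0 - sg * e) - e) * tau;
}

// linear rate band: basal at activity >= 1, extreme at activity <= 0
static inline double rate_band(double x, double basal, double extreme) {
  if (x >= 1.0) return basal;
  if (x <= 0.0) return extreme;
  return extreme + (basal - extreme) * x;
}

static inline double release_rate(double cs_mmol, double A, double B,
                                  double sr, double m) {
  if (cs_mmol <= 0.0) return A;
  return B + (A - B) * logistic(-m * std::log(cs_mmol / sr));
}

// piecewise-linear interpolation with constant extrapolation
static inline double interp1(const std::vector<double>& xs,
                             const std::vector<double>& ys, double x) {
  const size_t n = xs.size();
  if (n == 1 || x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  size_t hi = std::upper_bound(xs.begin(), xs.end(), x) - xs.begin();
  size_t lo = hi - 1;
  double w = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] + w * (ys[hi] - ys[lo]);
}

struct Inputs {
  std::vector<double> t, ca, p, d;
  void eval(double tt, double& C, double& P, double& D) const {
    C = interp1(t, ca, tt);
    P = interp1(t, p, tt);
    D = interp1(t, d, tt);
  }
};

static void rhs(double t, const double* y, double* dy,
                const double* par, const Inputs& in) {
  double C, P, D;
  in.eval(t, C, P, D);

  const double casr = y[0], vdr = y[1];
  const double cs = y[5], ds = y[6];

  const double s_ca = stimf(cs - par[2], par[0], par[1]);
  const double s_p  = stimf(P - par[5], par[3], par[4]);
  const double s_d  = stimf(ds - par[8], par[6], par[7]);

  // receptor expression with mutual positive feedback, phosphate suppression
  dy[0] = par[9]  * (y[2] + (vdr - 1.0) - y[4]) * casr + par[10] * (1.0 - casr);
  dy[1] = par[11] * (y[3] + (casr - 1.0) - y[4]) * vdr + par[12] * (1.0 - vdr);
  dy[2] = effect_rhs(y[2], s_ca, par[13]);
  dy[3] = effect_rhs(y[3], s_d,  par[14]);
  dy[4] = effect_rhs(y[4], s_p,  par[15]);

  // sensed concentrations, sensitivity clamped to [a_s, 1]
  double xsum = casr + vdr;
  if (xsum < 0.0) xsum = 0.0;
  if (xsum > 2.0) xsum = 2.0;
  const double sv = par[43] + (1.0 - par[43]) * (xsum / 2.0);
  dy[5] = sv * C - cs;
  dy[6] = sv * D - ds;

  // three signaling pathways: (chi, chi_in, pi_in) blocks
  const int pbase[3] = {16, 22, 28};
  const int ybase[3] = {7, 10, 13};
  for (int j = 0; j < 3; ++j) {
    const double* q = par + pbase[j];
    const int i = ybase[j];
    dy[i]     = q[0] * (y[i + 1] - y[i + 2]) * y[i] + q[1] * (1.0 - y[i]);
    dy[i + 1] = effect_rhs(y[i + 1], s_ca, q[2]);
    dy[i + 2] = effect_rhs(y[i + 2], s_p,  q[3]);
  }

  const double k_d  = rate_band(y[7],  par[20], par[21]);
  const double k_p  = rate_band(y[10], par[26], par[27]);
  const double k_pr = rate_band(y[13], par[32], par[33]);

  // PTH pools
  const double cs_mmol = (cs > 0.0 ? cs : 0.0) / CA_MGDL_PER_MMOL;
  const double rel = release_rate(cs_mmol, par[38], par[39], par[40], par[41]);
  dy[16] = k_p * y[18] - rel * y[16] - k_d * y[16];
  dy[17] = rel * y[16] - par[42] * y[17];

  // cell populations with dynamic, non-decreasing carrying capacity
  const double s = y[18], qq = y[19], kcap = y[20];
  dy[18] = -par[34] * s + par[35] * qq;
  double grow = 0.0;
  if (s + qq > 0.0 && kcap > 0.0) {
    grow = k_pr * qq * std::log(kcap / (s + qq));
  }
  dy[19] = par[34] * s - par[35] * qq - par[36] * qq + grow;
  const double excess = (s + qq) / par[44] - 1.0;
  dy[20] = excess > 0.0 ? par[37] * std::pow(excess, 2.0 / 3.0) : 0.0;
}

// [[Rcpp::export]]
NumericVector ptg_rhs_cpp(double t, NumericVector y, NumericVector par,
                          NumericVector in_t, NumericVector in_ca,
                          NumericVector in_p, NumericVector in_d) {
  if (y.size() != 21) stop("state must have length 21");
  if (par.size() != 45) stop("parameter vector must have length 45");
  Inputs in;
  in.t = as<std::vector<double> >(in_t);
  in.ca = as<std::vector<double> >(in_ca);
  in.p = as<std::vector<double> >(in_p);
  in.d = as<std::vector<double> >(in_d);
  NumericVector dy(21);
  rhs(t, y.begin(), dy.begin(), par.begin(), in);
  return dy;
}

// Dormand-Prince 5(4) coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
// error coefficients: b5 - b4 (embedded 4th order), k7 = f(t+h, y_new)
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

// Integrate from the single start time through a strictly increasing list of
// stop times (union of output times and profile breakpoints); record the
// state at each output time. out_times[0] may equal t0.
// [[Rcpp::export]]
NumericMatrix ptg_integrate_cpp(NumericVector y0, NumericVector par,
                                NumericVector in_t, NumericVector in_ca,
                                NumericVector in_p, NumericVector in_d,
                                double t0, NumericVector knots,
                                NumericVector out_times,
                                double rtol, double atol, double max_steps) {
  const int NS = 21;
  if (y0.size() != NS) stop("state must have length 21");
  Inputs in;
  in.t = as<std::vector<double> >(in_t);
  in.ca = as<std::vector<double> >(in_ca);
  in.p = as<std::vector<double> >(in_p);
  in.d = as<std::vector<double> >(in_d);

  const int nout = out_times.size();
  NumericMatrix out(nout, NS);

  // merge output times and interior breakpoints into stop times
  std::vector<double> stops;
  stops.reserve(nout + knots.size());
  {
    int i = 0, j = 0;
    while (i < nout || j < knots.size()) {
      double a = (i < nout) ? out_times[i] : R_PosInf;
      double b = (j < knots.size()) ? knots[j] : R_PosInf;
      double v = std::min(a, b);
      if (stops.empty() || v > stops.back()) stops.push_back(v);
      if (i < nout && out_times[i] == v) ++i;
      if (j < knots.size() && knots[j] == v) ++j;
    }
  }

  std::vector<double> y(y0.begin(), y0.end());
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double yt[NS], ynew[NS];

  double t = t0;
  int iout = 0;
  if (nout > 0 && out_times[0] == t0) {
    for (int s = 0; s < NS; ++s) out(0, s) = y[s];
    iout = 1;
  }

  double nstep = 0.0;
  double h = 0.0;

  for (size_t iseg = 0; iseg < stops.size(); ++iseg) {
    const double tb = stops[iseg];
    if (tb <= t) continue;
    if (h <= 0.0) h = std::min(1.0, tb - t);
    bool at_end = false;
    while (!at_end) {
      if (nstep++ > max_steps) {
        std::ostringstream msg;
        msg << "integration failed: step budget exhausted at t = " << t
            << " min (state: ";
        for (int s = 0; s < NS; ++s) msg << y[s] << (s < NS - 1 ? ", " : ")");
        stop(msg.str());
      }
      double hs = h;
      if (t + hs >= tb) { hs = tb - t; at_end = true; }

      rhs(t, y.data(), k1, par.begin(), in);
      for (int s = 0; s < NS; ++s) yt[s] = y[s] + hs * A21 * k1[s];
      rhs(t + C2 * hs, yt, k2, par.begin(), in);
      for (int s = 0; s < NS; ++s)
        yt[s] = y[s] + hs * (A31 * k1[s] + A32 * k2[s]);
      rhs(t + C3 * hs, yt, k3, par.begin(), in);
      for (int s = 0; s < NS; ++s)
        yt[s] = y[s] + hs * (A41 * k1[s] + A42 * k2[s] + A43 * k3[s]);
      rhs(t + C4 * hs, yt, k4, par.begin(), in);
      for (int s = 0; s < NS; ++s)
        yt[s] = y[s] + hs * (A51 * k1[s] + A52 * k2[s] + A53 * k3[s] +
                             A54 * k4[s]);
      rhs(t + C5 * hs, yt, k5, par.begin(), in);
      for (int s = 0; s < NS; ++s)
        yt[s] = y[s] + hs * (A61 * k1[s] + A62 * k2[s] + A63 * k3[s] +
                             A64 * k4[s] + A65 * k5[s]);
      rhs(t + hs, yt, k6, par.begin(), in);
      for (int s = 0; s < NS; ++s)
        ynew[s] = y[s] + hs * (B1 * k1[s] + B3 * k3[s] + B4 * k4[s] +
                               B5 * k5[s] + B6 * k6[s]);
      rhs(t + hs, ynew, k7, par.begin(), in);

      double errnorm = 0.0;
      for (int s = 0; s < NS; ++s) {
        double err = hs * (E1 * k1[s] + E3 * k3[s] + E4 * k4[s] +
                           E5 * k5[s] + E6 * k6[s] + E7 * k7[s]);
        double sc = atol + rtol * std::max(std::fabs(y[s]), std::fabs(ynew[s]));
        double r = err / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / NS);

      if (!std::isfinite(errnorm)) {
        std::ostringstream msg;
        msg << "integration failed: non-finite state at t = " << t << " min";
        stop(msg.str());
      }

      if (errnorm <= 1.0) {
        t += hs;
        for (int s = 0; s < NS; ++s) y[s] = ynew[s];
      } else {
        at_end = false;
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h = hs * fac;
      if (h < 1e-12) {
        std::ostringstream msg;
        msg << "integration failed: step size underflow at t = " << t << " min";
        stop(msg.str());
      }
    }
    t = tb;  // guard against roundoff drift
    if (iout < nout && out_times[iout] == tb) {
      for (int s = 0; s < NS; ++s) out(iout, s) = y[s];
      ++iout;
    }
  }
  if (iout != nout) stop("internal error: not all output times were reached");
  return out;
}
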