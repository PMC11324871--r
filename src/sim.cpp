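// Euler-Maruyama integration of the coupled electro-thermal neuristor lattice.
//
// All quantities here are SI (volts, ohms, farads, watts, kelvin, seconds);
// unit conversion from the user-facing table units happens once on the R side.
// The R-level reference stepper (lattice_step) mirrors this loop exactly and
// is cross-checked against it in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// Hysteresis fraction F(T) of the metal-insulator transition.
// delta = +1 heating branch, -1 cooling branch. T_pr == 0 encodes the
// major (memory-free) branch; otherwise the reversal-memory term
// T_pr * P((T - T_r)/T_pr) shifts the effective transition curve.
// P is clamped to [0, 1]: full memory offset near the reversal, none far
// from it.
static inline double hyst_fraction(double T, double delta, double Tr, double Tpr,
                                   double w, double Tc, double beta, double gam) {
  double shift = 0.0;
  if (Tpr != 0.0) {
    double x = (T - Tr) / Tpr;
    double P = 0.5 * (1.0 - std::sin(gam * x)) *
               (1.0 + std::tanh(M_PI * M_PI - 2.0 * M_PI * x));
    if (P < 0.0) P = 0.0;
    if (P > 1.0) P = 1.0;
    shift = Tpr * P;
  }
  return 0.5 + 0.5 * std::tanh(beta * (delta * 0.5 * w + Tc - (T + shift)));
}

// R(T) = R0 * exp(Ea/T) * F + Rm, evaluated in log space so that large Ea/T
// or F -> 0 never overflow/underflow.
// The reversal-memory term encodes the frozen insulating/metallic domain
// mixture at the reversal point, which only exists inside the transition
// window. The memory anchor therefore saturates at the window edges
// T_c +/- (w/2 + 2/beta): a reversal further out carries no additional
// information, and an unbounded anchor would make |T_pr| grow with the
// post-spike temperature overshoot and invert the loop.
static inline double anchor_clamp(double T, double w, double Tc, double beta) {
  const double half = 0.5 * w + 2.0 / beta;
  if (T < Tc - half) return Tc - half;
  if (T > Tc + half) return Tc + half;
  return T;
}

static inline double reversal_Tpr(double Frev, double delta_new, double Tr,
                                  double w, double Tc, double beta) {
  return delta_new * 0.5 * w + Tc - (2.0 * Frev - 1.0) / beta - Tr;
}

static inline double vo2_res(double T, double F, double logR0, double Ea, double Rm) {
  if (F <= 0.0) return Rm;
  double l = logR0 + Ea / T + std::log(F);
  if (l > 700.0) l = 700.0;
  return std::exp(l) + Rm;
}

// [[Rcpp::export]]
List cpp_simulate_lattice(NumericMatrix v_in, List pars, double dt, int n_steps,
                          double record_from, double threshold, double min_sep,
                          double deadband, bool record_traces, int trace_stride) {
  const int nr = v_in.nrow(), nc = v_in.ncol(), n = nr * nc;
  const double C     = as<double>(pars["C"]);
  const double RL    = as<double>(pars["R_load"]);
  const double Cth   = as<double>(pars["C_th_eff"]);
  const double Se    = as<double>(pars["S_e"]);
  const double Sc    = as<double>(pars["S_c"]);
  const double T0    = as<double>(pars["T0"]);
  const double sigma = as<double>(pars["sigma"]);
  const double logR0 = as<double>(pars["logR0"]);
  const double Ea    = as<double>(pars["E_a"]);
  const double Rm    = as<double>(pars["R_m"]);
  const double w     = as<double>(pars["w"]);
  const double Tc    = as<double>(pars["T_c"]);
  const double beta  = as<double>(pars["beta"]);
  const double gam   = as<double>(pars["gamma"]);
  const double Tr0   = as<double>(pars["T_r_virgin"]);

  const double dt_C = dt / C, dt_Cth = dt / Cth;
  const double ncoef = (sigma / Cth) * std::sqrt(dt);

  // standard initial condition: V = 0, T = T0, virgin heating branch
  std::vector<double> V(n, 0.0), T(n, T0), Tr(n, Tr0), Tpr(n, 0.0), Text(n, T0);
  std::vector<double> del(n, 1.0);
  std::vector<double> Ipp(n, 0.0), Ip(n, 0.0), Icur(n), Rcur(n), lap(n);
  std::vector<double> last_spk(n, -1e300);

  std::vector<int> ev_site;
  std::vector<double> ev_t, ev_peak;

  // pre-count trace rows
  int n_rec = 0;
  if (record_traces) {
    for (int s = 0; s < n_steps; ++s)
      if (s * dt >= record_from && s % trace_stride == 0) ++n_rec;
  }
  NumericMatrix traces(record_traces ? n_rec : 0, record_traces ? n : 0);
  NumericVector trace_t(record_traces ? n_rec : 0);
  int rec_row = 0;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    for (int k = 0; k < n; ++k) {
      double F = hyst_fraction(T[k], del[k], Tr[k], Tpr[k], w, Tc, beta, gam);
      Rcur[k] = vo2_res(T[k], F, logR0, Ea, Rm);
      Icur[k] = V[k] / Rcur[k];
    }

    if (record_traces && t >= record_from && step % trace_stride == 0) {
      for (int k = 0; k < n; ++k) traces(rec_row, k) = Icur[k];
      trace_t[rec_row] = t;
      ++rec_row;
    }

    // strict local maximum at the previous sample
    if (step >= 2) {
      const double tprev = t - dt;
      for (int k = 0; k < n; ++k) {
        if (Ip[k] >= threshold && Ip[k] > Ipp[k] && Ip[k] > Icur[k] &&
            tprev - last_spk[k] >= min_sep) {
          last_spk[k] = tprev;
          if (tprev >= record_from) {
            ev_site.push_back(k);
            ev_t.push_back(tprev);
            ev_peak.push_back(Ip[k]);
          }
        }
      }
    }

    // zero-flux nearest-neighbour Laplacian
    for (int k = 0; k < n; ++k) {
      const int r = k % nr, c = k / nr;
      const double Tk = T[k];
      double s = 0.0;
      if (r > 0)      s += T[k - 1]  - Tk;
      if (r < nr - 1) s += T[k + 1]  - Tk;
      if (c > 0)      s += T[k - nr] - Tk;
      if (c < nc - 1) s += T[k + nr] - Tk;
      lap[k] = s;
    }

    for (int k = 0; k < n; ++k) {
      const double Vk = V[k], Tk = T[k], Rk = Rcur[k];
      double Vn = Vk + dt_C * (v_in[k] / RL - Vk * (1.0 / Rk + 1.0 / RL));
      double Tn = Tk + dt_Cth * (Vk * Vk / Rk - Se * (Tk - T0) + Sc * lap[k]);
      if (sigma > 0.0) Tn += ncoef * norm_rand();

      if (!std::isfinite(Vn) || !std::isfinite(Tn)) {
        const int r = k % nr, c = k / nr;
        std::string msg = "simulation diverged at site (row " +
          std::to_string(r) + ", col " + std::to_string(c) + "), t = " +
          std::to_string(t * 1e9) + " ns";
        stop(msg);
      }

      // branch update with deadband on the running extremum
      if (del[k] > 0.0) {
        if (Tn >= Text[k]) {
          Text[k] = Tn;
        } else if (Text[k] - Tn > deadband) {
          double anchor = anchor_clamp(Text[k], w, Tc, beta);
          double Frev = hyst_fraction(anchor, 1.0, Tr[k], Tpr[k], w, Tc, beta, gam);
          del[k] = -1.0;
          Tr[k] = anchor;
          Tpr[k] = reversal_Tpr(Frev, -1.0, anchor, w, Tc, beta);
          Text[k] = Tn;
        }
      } else {
        if (Tn <= Text[k]) {
          Text[k] = Tn;
        } else if (Tn - Text[k] > deadband) {
          double anchor = anchor_clamp(Text[k], w, Tc, beta);
          double Frev = hyst_fraction(anchor, -1.0, Tr[k], Tpr[k], w, Tc, beta, gam);
          del[k] = 1.0;
          Tr[k] = anchor;
          Tpr[k] = reversal_Tpr(Frev, 1.0, anchor, w, Tc, beta);
          Text[k] = Tn;
        }
      }

      V[k] = Vn;
      T[k] = Tn;
    }

    Ipp.swap(Ip);
    Ip.assign(Icur.begin(), Icur.end());
  }

  const int ne = (int)ev_t.size();
  IntegerVector out_row(ne), out_col(ne);
  NumericVector out_t(ne), out_peak(ne);
  for (int i = 0; i < ne; ++i) {
    out_row[i] = ev_site[i] % nr;
    out_col[i] = ev_site[i] / nr;
    out_t[i] = ev_t[i];
    out_peak[i] = ev_peak[i];
  }

  NumericMatrix Vf(nr, nc), Tf(nr, nc), delf(nr, nc), Trf(nr, nc), Tprf(nr, nc), Textf(nr, nc);
  for (int k = 0; k < n; ++k) {
    Vf[k] = V[k]; Tf[k] = T[k]; delf[k] = del[k];
    Trf[k] = Tr[k]; Tprf[k] = Tpr[k]; Textf[k] = Text[k];
  }

  return List::create(
    _["row"] = out_row, _["col"] = out_col, _["t"] = out_t, _["peak"] = out_peak,
    _["V"] = Vf, _["T"] = Tf, _["delta"] = delf, _["T_r"] = Trf,
    _["T_pr"] = Tprf, _["T_ext"] = Textf,
    _["traces"] = traces, _["trace_t"] = trace_t);
}
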