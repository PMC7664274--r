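// Fixed-step integrator for the single-compartment conductance model used
// by the current-clamp simulator: leak + transient Na (instantaneous cubic
// activation, inactivating) + persistent Na fraction + delayed-rectifier K.
// Gating uses exponential-Euler updates; the membrane equation uses the
// exact exponential relaxation toward its instantaneous steady state, which
// is unconditionally stable at the 0.01 ms default step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x / y)) with the removable singularity at x = 0 patched
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Gates { double minf, hinf, tauh, ninf, taun, pinf; };

// na_shift moves the Na (and persistent-Na) voltage dependence to more
// depolarized potentials, pulling the window current away from rest
static inline Gates gates(double v, double phi_h, double phi_n,
                          double na_shift) {
  Gates g;
  const double vm = v - na_shift;
  double am = 0.1 * vtrap(vm + 35.0, 10.0);
  double bm = 4.0 * std::exp(-(vm + 60.0) / 18.0);
  g.minf = am / (am + bm);
  double ah = phi_h * 0.07 * std::exp(-(vm + 58.0) / 20.0);
  double bh = phi_h / (1.0 + std::exp(-(vm + 28.0) / 10.0));
  g.hinf = ah / (ah + bh);
  g.tauh = 1.0 / (ah + bh);
  double an = phi_n * 0.01 * vtrap(v + 34.0, 10.0);
  double bn = phi_n * 0.125 * std::exp(-(v + 44.0) / 80.0);
  g.ninf = an / (an + bn);
  g.taun = 1.0 / (an + bn);
  g.pinf = 1.0 / (1.0 + std::exp(-(vm + 48.0) / 6.0));
  return g;
}

// [[Rcpp::export]]
NumericMatrix cc_integrate(List preset, NumericVector step_pa,
                           double onset_s, double step_s, double total_s,
                           double sample_rate, double dt_ms,
                           double settle_ms) {
  const double cm = as<double>(preset["c_m"]);
  const double gl = as<double>(preset["g_leak"]);
  const double el = as<double>(preset["e_leak"]);
  const double gna = as<double>(preset["g_na"]) * as<double>(preset["g_scale"]);
  const double ena = as<double>(preset["e_na"]);
  const double fp = as<double>(preset["persistent_fraction"]);
  const double gk = as<double>(preset["g_k"]);
  const double ek = as<double>(preset["e_k"]);
  const double phi_h = as<double>(preset["phi_h"]);
  const double phi_n = as<double>(preset["phi_n"]);
  const double na_shift = as<double>(preset["na_shift"]);

  const int rec_every = (int)std::lround((1000.0 / sample_rate) / dt_ms);
  if (rec_every < 1 ||
      std::fabs(rec_every * dt_ms - 1000.0 / sample_rate) > 1e-9)
    stop("cc_integrate: dt must divide the sampling interval exactly");
  const long n_steps = (long)std::lround(total_s * 1000.0 / dt_ms);
  const int n_samp = (int)(n_steps / rec_every);
  const long settle_steps = (long)std::lround(settle_ms / dt_ms);
  const long i_on = (long)std::lround(onset_s * 1000.0 / dt_ms);
  const long i_off = (long)std::lround((onset_s + step_s) * 1000.0 / dt_ms);

  NumericMatrix out(n_samp, step_pa.size());

  for (int sw = 0; sw < step_pa.size(); ++sw) {
    double v = el;
    Gates g0 = gates(v, phi_h, phi_n, na_shift);
    double h = g0.hinf, n = g0.ninf;
    const double amp = step_pa[sw];
    int isamp = 0;
    for (long i = -settle_steps; i < n_steps; ++i) {
      const double inj = (i >= i_on && i < i_off) ? amp : 0.0;
      Gates g = gates(v, phi_h, phi_n, na_shift);
      // gating: exponential Euler
      h = g.hinf + (h - g.hinf) * std::exp(-dt_ms / g.tauh);
      n = g.ninf + (n - g.ninf) * std::exp(-dt_ms / g.taun);
      const double m3h = g.minf * g.minf * g.minf * h;
      const double n4 = n * n * n * n;
      const double g_na_t = gna * (m3h + fp * g.pinf);
      const double g_k_t = gk * n4;
      const double g_tot = gl + g_na_t + g_k_t;
      const double v_inf = (gl * el + g_na_t * ena + g_k_t * ek + inj) / g_tot;
      v = v_inf + (v - v_inf) * std::exp(-dt_ms * g_tot / cm);
      if (i >= 0 && ((i + 1) % rec_every == 0) && isamp < n_samp)
        out(isamp++, sw) = v;
    }
  }
  return out;
}
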