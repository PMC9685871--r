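#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment lung driven by ventilator assist and inspiratory
// muscle pressure:
//
//   R_aw * dV/dt = P_vent(t) + P_mus(t) - V / C_rs
//
// with V the volume above end-expiratory lung volume (litres),
// P_vent = nava_level * Edi when Edi exceeds the trigger (pressure above
// PEEP delivered in proportion to diaphragm activity, the NAVA
// principle) and P_mus = k_edi * Edi. Fixed-step classical RK4 at the
// waveform sampling rate; the forcing is supplied on a half-step grid
// (edi_half[2*i] = Edi(t_i), edi_half[2*i+1] = Edi(t_i + dt/2)) so the
// mid-step evaluations are exact.

// [[Rcpp::export]]
List rk4_lung(NumericVector edi_half, double dt, double nava_level,
              double k_edi, double r_aw, double c_rs, double trigger,
              double v0) {
  const int n = (edi_half.size() + 1) / 2;
  if (edi_half.size() != 2 * n - 1)
    stop("edi_half must have odd length 2*n - 1");
  if (r_aw <= 0 || c_rs <= 0 || dt <= 0)
    stop("r_aw, c_rs and dt must be positive");
  NumericVector v(n), flow(n), p_vent(n), p_mus(n);

  auto drive = [&](int half_idx) {
    double e = edi_half[half_idx];
    double pv = (e > trigger) ? nava_level * e : 0.0;
    double pm = k_edi * e;
    return std::pair<double, double>(pv, pm);
  };
  auto rhs = [&](int half_idx, double vol) {
    auto d = drive(half_idx);
    return (d.first + d.second - vol / c_rs) / r_aw;
  };

  double vol = v0;
  for (int i = 0; i < n; ++i) {
    auto d = drive(2 * i);
    p_vent[i] = d.first;
    p_mus[i] = d.second;
    v[i] = vol;
    flow[i] = rhs(2 * i, vol);
    if (i == n - 1) break;
    double k1 = flow[i];
    double k2 = rhs(2 * i + 1, vol + 0.5 * dt * k1);
    double k3 = rhs(2 * i + 1, vol + 0.5 * dt * k2);
    double k4 = rhs(2 * i + 2, vol + dt * k3);
    vol += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!std::isfinite(vol))
      stop("simulation error: non-finite volume at step %d", i + 1);
  }
  return List::create(_["v"] = v, _["flow"] = flow, _["p_vent"] = p_vent,
                      _["p_mus"] = p_mus);
}
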