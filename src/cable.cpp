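// Branched-cable integrator: Crank-Nicolson time stepping with a direct
// Hines tree solve per step.  Nodes must be ordered so that parent[i] < i
// (root has parent -1); the R-side builder guarantees this.
//
// Units follow the NEURON convention: mV, ms, nA, uS, nF.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity at x = 0 filled in
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// Squid-axon HH rate functions on the modern -65 mV resting convention.
// vs is the activation shift applied to the m-gate (negative = activation
// curve moved toward hyperpolarized potentials).
inline void hh_m(double v, double vs, double &minf, double &mtau) {
  double u = v - vs;  // vs = -8 shifts V1/2 by -8 mV
  double a = 0.1 * vtrap(-(u + 40.0), 10.0);
  double b = 4.0 * std::exp(-(u + 65.0) / 18.0);
  mtau = 1.0 / (a + b);
  minf = a * mtau;
}
inline void hh_h(double v, double &hinf, double &htau) {
  double a = 0.07 * std::exp(-(v + 65.0) / 20.0);
  double b = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  htau = 1.0 / (a + b);
  hinf = a * htau;
}
inline void hh_n(double v, double &ninf, double &ntau) {
  double a = 0.01 * vtrap(-(v + 55.0), 10.0);
  double b = 0.125 * std::exp(-(v + 65.0) / 80.0);
  ntau = 1.0 / (a + b);
  ninf = a * ntau;
}
// Single-gate HCN (Ih) kinetics as used in rat L5 pyramidal models.
inline void ih_q(double v, double &qinf, double &qtau) {
  double a, den;
  den = std::exp((v + 154.9) / 11.9) - 1.0;
  if (std::fabs((v + 154.9) / 11.9) < 1e-7)
    a = 0.001 * 6.43 * 11.9;  // limit of x/(exp(x/k)-1)*6.43e-3 form
  else
    a = 0.001 * 6.43 * (v + 154.9) / den;
  double b = 0.001 * 193.0 * std::exp(v / 33.1);
  qtau = 1.0 / (a + b);
  qinf = a * qtau;
}

inline double gate_step(double x, double xinf, double xtau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / xtau);
}

}  // namespace

// [[Rcpp::export(name = ".simulate_cable_cpp")]]
List simulate_cable_cpp(List cable, DataFrame stim, DataFrame syn,
                        double dt, double t_stop, NumericVector v_init,
                        IntegerVector record0, double settle_ms,
                        bool check_balance) {
  IntegerVector parent = cable["parent"];   // 0-based, -1 for root
  NumericVector cap    = cable["cap_nF"];
  NumericVector gpas   = cable["g_pas_uS"];
  NumericVector epas   = cable["e_pas_mV"];
  NumericVector gax    = cable["g_ax_uS"];  // to parent; root entry ignored
  NumericVector gna    = cable["g_na_uS"];
  NumericVector gk     = cable["g_k_uS"];
  NumericVector gh     = cable["g_h_uS"];
  double ena     = as<double>(cable["e_na_mV"]);
  double ek      = as<double>(cable["e_k_mV"]);
  double eh      = as<double>(cable["e_h_mV"]);
  NumericVector mshift = cable["na_m_shift_mV"];  // per-node

  const int n = parent.size();
  for (int i = 1; i < n; ++i)
    if (parent[i] < 0 || parent[i] >= i)
      stop("compartments must be ordered parent-before-child");

  // stimulus table: node0, amp_nA, delay_ms, dur_ms
  IntegerVector st_node = stim["node0"];
  NumericVector st_amp  = stim["amp_nA"];
  NumericVector st_del  = stim["delay_ms"];
  NumericVector st_dur  = stim["dur_ms"];
  const int nstim = st_node.size();

  // synapse table: node0, onset_ms, gmax_uS, tau_rise, tau_decay, norm,
  //                e_syn, nmda (0/1), gamma, mg_mM, mg_n
  IntegerVector sy_node = syn["node0"];
  NumericVector sy_on   = syn["onset_ms"];
  NumericVector sy_g    = syn["gmax_uS"];
  NumericVector sy_tr   = syn["tau_rise"];
  NumericVector sy_td   = syn["tau_decay"];
  NumericVector sy_norm = syn["norm"];
  NumericVector sy_es   = syn["e_syn_mV"];
  IntegerVector sy_nmda = syn["nmda"];
  NumericVector sy_gam  = syn["gamma"];
  NumericVector sy_mg   = syn["mg_mM"];
  NumericVector sy_mgn  = syn["mg_n"];
  const int nsyn = sy_node.size();

  bool any_na = false, any_k = false, any_h = false;
  for (int i = 0; i < n; ++i) {
    if (gna[i] > 0) any_na = true;
    if (gk[i] > 0)  any_k = true;
    if (gh[i] > 0)  any_h = true;
  }

  std::vector<double> v(n), m(n, 0.0), h(n, 0.0), nk(n, 0.0), q(n, 0.0);
  for (int i = 0; i < n; ++i)
    v[i] = (v_init.size() == 1) ? v_init[0] : v_init[i];

  // gates start at steady state for the initial potential
  for (int i = 0; i < n; ++i) {
    double xinf, xtau;
    if (gna[i] > 0) {
      hh_m(v[i], mshift[i], xinf, xtau); m[i] = xinf;
      hh_h(v[i], xinf, xtau);         h[i] = xinf;
    }
    if (gk[i] > 0) { hh_n(v[i], xinf, xtau); nk[i] = xinf; }
    if (gh[i] > 0) { ih_q(v[i], xinf, xtau); q[i] = xinf; }
  }

  const int nrec = record0.size();
  const int nstep = (int)std::lround(t_stop / dt);
  const int nsettle = (settle_ms > 0) ? (int)std::lround(settle_ms / dt) : 0;
  NumericVector time(nstep + 1);
  NumericMatrix vm(nstep + 1, nrec);

  std::vector<double> d(n), rhs(n), off(n), Gtot(n), GE(n), Iinj(n);
  double max_resid = 0.0;

  for (int step = -nsettle; step < nstep; ++step) {
    double t = step * dt;       // negative during settling
    double tmid = t + 0.5 * dt;

    if (step == 0) {
      time[0] = 0.0;
      for (int r = 0; r < nrec; ++r) vm(0, r) = v[record0[r]];
    }

    // 1. staggered gate advance using the current voltage
    if (any_na || any_k || any_h) {
      for (int i = 0; i < n; ++i) {
        double xinf, xtau;
        if (gna[i] > 0) {
          hh_m(v[i], mshift[i], xinf, xtau); m[i] = gate_step(m[i], xinf, xtau, dt);
          hh_h(v[i], xinf, xtau);         h[i] = gate_step(h[i], xinf, xtau, dt);
        }
        if (gk[i] > 0) { hh_n(v[i], xinf, xtau); nk[i] = gate_step(nk[i], xinf, xtau, dt); }
        if (gh[i] > 0) { ih_q(v[i], xinf, xtau); q[i]  = gate_step(q[i], xinf, xtau, dt); }
      }
    }

    // 2. per-node conductances (frozen over the step) and injected current
    for (int i = 0; i < n; ++i) {
      double G = gpas[i], E = gpas[i] * epas[i];
      if (gna[i] > 0) {
        double g = gna[i] * m[i] * m[i] * m[i] * h[i];
        G += g; E += g * ena;
      }
      if (gk[i] > 0) {
        double g = gk[i] * nk[i] * nk[i] * nk[i] * nk[i];
        G += g; E += g * ek;
      }
      if (gh[i] > 0) {
        double g = gh[i] * q[i];
        G += g; E += g * eh;
      }
      Gtot[i] = G; GE[i] = E; Iinj[i] = 0.0;
    }
    if (step >= 0) {
      for (int s = 0; s < nstim; ++s)
        if (tmid >= st_del[s] && tmid < st_del[s] + st_dur[s])
          Iinj[st_node[s]] += st_amp[s];
      for (int s = 0; s < nsyn; ++s) {
        double ts = tmid - sy_on[s];
        if (ts <= 0) continue;
        double g = sy_g[s] * sy_norm[s] *
                   (std::exp(-ts / sy_td[s]) - std::exp(-ts / sy_tr[s]));
        if (g <= 0) continue;
        if (sy_nmda[s]) {
          int nd = sy_node[s];
          double B = 1.0 / (1.0 + std::exp(-sy_gam[s] * v[nd]) * sy_mg[s] * sy_mgn[s]);
          g *= B;
        }
        Gtot[sy_node[s]] += g;
        GE[sy_node[s]]   += g * sy_es[s];
      }
    }

    // 3. assemble the Crank-Nicolson system
    for (int i = 0; i < n; ++i) {
      double cdt = cap[i] / dt;
      d[i]   = cdt + 0.5 * Gtot[i];
      rhs[i] = cdt * v[i] - 0.5 * Gtot[i] * v[i] + GE[i] + Iinj[i];
      off[i] = 0.0;
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double a = gax[i];
      d[i] += 0.5 * a;
      d[p] += 0.5 * a;
      off[i] = -0.5 * a;
      rhs[i] += 0.5 * a * (v[p] - v[i]);
      rhs[p] += 0.5 * a * (v[i] - v[p]);
    }

    // 4. Hines solve: eliminate leaves upward, back-substitute downward
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = off[i] / d[i];
      d[p]   -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    std::vector<double> vnew(n);
    vnew[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      vnew[i] = (rhs[i] - off[i] * vnew[parent[i]]) / d[i];

    if (check_balance) {
      // residual of the CN balance equation, relative to its largest term
      for (int i = 0; i < n; ++i) {
        double cdt = cap[i] / dt;
        double r = cdt * (vnew[i] - v[i])
                 + 0.5 * Gtot[i] * (vnew[i] + v[i]) - GE[i] - Iinj[i];
        double scale = std::fabs(cdt * vnew[i]) + std::fabs(GE[i]) + 1e-12;
        if (i > 0) {
          int p = parent[i];
          r -= 0.5 * gax[i] * ((vnew[p] - vnew[i]) + (v[p] - v[i]));
        }
        for (int c = i + 1; c < n; ++c)
          if (parent[c] == i)
            r -= 0.5 * gax[c] * ((vnew[c] - vnew[i]) + (v[c] - v[i]));
        double rel = std::fabs(r) / scale;
        if (rel > max_resid) max_resid = rel;
      }
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(vnew[i]))
        stop("numerical failure (non-finite voltage) at compartment %d, t = %g ms",
             i + 1, t + dt);
      v[i] = vnew[i];
    }

    if (step >= 0) {
      time[step + 1] = (step + 1) * dt;
      for (int r = 0; r < nrec; ++r) vm(step + 1, r) = v[record0[r]];
    }
  }

  if (nstep == 0) {
    time[0] = 0.0;
    for (int r = 0; r < nrec; ++r) vm(0, r) = v[record0[r]];
  }

  return List::create(_["time_ms"] = time, _["v_mV"] = vm,
                      _["max_balance_resid"] = max_resid);
}
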