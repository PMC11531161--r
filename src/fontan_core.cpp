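// Closed-loop Fontan circulation core: six stressed-volume ODE states
// (single atrium, single ventricle, four Windkessel capacitances), ideal-diode
// valves, optional regurgitant AVV branch, optional continuous-flow pump in
// parallel with the aortic valve. Fixed-step classical RK4; the step (default
// T_c/4000 = 0.2 ms) sits well below the smallest circuit time constant
// (~1 ms through the open AVV), and the scheme preserves the linear invariant
// sum(V) to round-off, so total stressed volume is conserved exactly.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Chamber {
  double Ees, A, B, V0, Tes, offset;
};

struct Bed {
  double Rc, Ra, Rv, Ca, Cv;
};

struct Model {
  Chamber sv, sa;
  double Rav, Ravv;
  bool has_reg;
  double Ravvr;
  Bed sys, pul;
  bool pump_on;
  double KA, KB, KC, rpm;
  double Tc;
  double freeze_e;     // NaN => time-varying activation
  bool diode_resistor; // valves as plain resistors (linearised-circuit mode)
};

// state order: V_SA, V_SV, V_Cas, V_Cvs, V_Cap, V_Cvp
const double MLS_PER_LMIN = 1000.0 / 60.0;

Model unpack(const NumericVector& p) {
  Model m;
  int i = 0;
  m.Tc = p[i++];
  m.sv = {p[i], p[i + 1], p[i + 2], p[i + 3], p[i + 4], p[i + 5]}; i += 6;
  m.sa = {p[i], p[i + 1], p[i + 2], p[i + 3], p[i + 4], p[i + 5]}; i += 6;
  m.Rav = p[i++];
  m.Ravv = p[i++];
  m.has_reg = p[i++] > 0.5;
  m.Ravvr = p[i++];
  m.sys = {p[i], p[i + 1], p[i + 2], p[i + 3], p[i + 4]}; i += 5;
  m.pul = {p[i], p[i + 1], p[i + 2], p[i + 3], p[i + 4]}; i += 5;
  m.pump_on = p[i++] > 0.5;
  m.KA = p[i++]; m.KB = p[i++]; m.KC = p[i++]; m.rpm = p[i++];
  m.freeze_e = p[i++];
  m.diode_resistor = p[i++] > 0.5;
  return m;
}

// time reduced into [0, Tc) without std::fmod (keeps the glibc symbol
// footprint minimal for portability across toolchains)
double mod_cycle(double t, double Tc) {
  double tl = t - std::floor(t / Tc) * Tc;
  if (tl < 0) tl += Tc;
  if (tl >= Tc) tl -= Tc;
  return tl;
}

double activation(double t, const Chamber& ch, const Model& m) {
  if (R_finite(m.freeze_e)) return m.freeze_e;
  double tl = mod_cycle(t - ch.offset, m.Tc);
  if (tl < 2.0 * ch.Tes) return 0.5 * (1.0 - std::cos(M_PI * tl / ch.Tes));
  return 0.0;
}

double chamber_p(double V, double e, const Chamber& ch) {
  double Ped = ch.A * (std::exp(ch.B * (V - ch.V0)) - 1.0);
  double Pes = ch.Ees * (V - ch.V0);
  return (Pes - Ped) * e + Ped;
}

// In the closed loop the device runs at the zero-head operating point of its
// quadratic characteristic: Q0(r) is the descending-branch root of
// K_A r^2 + K_B r Q + K_C Q^2 = 0. Every published assisted operating state
// satisfies CO = Q0(rpm) when the aortic valve is closed, which identifies
// this coupling (see the methods vignette). Returns L/min.
double pump_q0_lmin(const Model& m) {
  if (!m.pump_on || m.rpm <= 0.0) return 0.0;
  double b = m.KB * m.rpm;
  double disc = b * b - 4.0 * m.KC * m.KA * m.rpm * m.rpm;
  double q = (-b - std::sqrt(disc)) / (2.0 * m.KC);
  return q > 0.0 ? q : 0.0;
}

struct Eval {
  double P[6];      // P_SA, P_SV, P_Cas, P_Cvs, P_Cap, P_Cvp
  double e_sa, e_sv;
  double Pao, cvp;
  double Qavv, Qreg, Qav, Qpump_mls, Qras, Qvscp, Qrap, Qrvp;
  double dV[6];
};

// Capacitor-free aortic-root node: AV flow + pump flow = flow into R_c,s.
double solve_aortic_node(double Psv, double Pcas, const Model& m) {
  if (m.diode_resistor) {
    // linear divider (AV as plain resistor); pump assumed off in this mode
    return (Psv / m.Rav + Pcas / m.sys.Rc) / (1.0 / m.Rav + 1.0 / m.sys.Rc);
  }
  double qp = pump_q0_lmin(m) * MLS_PER_LMIN; // constant source, mL/s
  // AV closed: node fed by the pump source only
  double Pn_closed = Pcas + qp * m.sys.Rc;
  if (Psv <= Pn_closed) return Pn_closed;
  // AV conducting: linear divider with the source term
  return (Psv / m.Rav + Pcas / m.sys.Rc + qp) /
         (1.0 / m.Rav + 1.0 / m.sys.Rc);
}

void eval_state(const double* y, double t, const Model& m, Eval& ev) {
  ev.e_sa = activation(t, m.sa, m);
  ev.e_sv = activation(t, m.sv, m);
  ev.P[0] = chamber_p(y[0], ev.e_sa, m.sa);
  ev.P[1] = chamber_p(y[1], ev.e_sv, m.sv);
  ev.P[2] = y[2] / m.sys.Ca;
  ev.P[3] = y[3] / m.sys.Cv;
  ev.P[4] = y[4] / m.pul.Ca;
  ev.P[5] = y[5] / m.pul.Cv;

  double Psa = ev.P[0], Psv = ev.P[1], Pcas = ev.P[2], Pcvs = ev.P[3],
         Pcap = ev.P[4], Pcvp = ev.P[5];

  if (m.diode_resistor) {
    ev.Qavv = (Psa - Psv) / m.Ravv;
    ev.Qreg = 0.0;
  } else {
    ev.Qavv = Psa > Psv ? (Psa - Psv) / m.Ravv : 0.0;
    ev.Qreg = (m.has_reg && Psv > Psa) ? (Psv - Psa) / m.Ravvr : 0.0;
  }

  ev.Pao = solve_aortic_node(Psv, Pcas, m);
  if (m.diode_resistor) {
    ev.Qav = (Psv - ev.Pao) / m.Rav;
    ev.Qpump_mls = 0.0;
  } else {
    ev.Qav = Psv > ev.Pao ? (Psv - ev.Pao) / m.Rav : 0.0;
    ev.Qpump_mls = pump_q0_lmin(m) * MLS_PER_LMIN;
  }

  ev.Qras = (Pcas - Pcvs) / m.sys.Ra;
  ev.Qvscp = (Pcvs - Pcap) / (m.sys.Rv + m.pul.Rc);
  ev.cvp = (Pcap * m.sys.Rv + Pcvs * m.pul.Rc) / (m.sys.Rv + m.pul.Rc);
  ev.Qrap = (Pcap - Pcvp) / m.pul.Ra;
  ev.Qrvp = (Pcvp - Psa) / m.pul.Rv;

  double Qroot = ev.Qav + ev.Qpump_mls; // = flow through R_c,s by node balance
  ev.dV[0] = ev.Qrvp + ev.Qreg - ev.Qavv;          // SA
  ev.dV[1] = ev.Qavv - Qroot - ev.Qreg;            // SV
  ev.dV[2] = Qroot - ev.Qras;                      // C_a,s
  ev.dV[3] = ev.Qras - ev.Qvscp;                   // C_v,s
  ev.dV[4] = ev.Qvscp - ev.Qrap;                   // C_a,p
  ev.dV[5] = ev.Qrap - ev.Qrvp;                    // C_v,p
}

void derivs(const double* y, double t, const Model& m, double* dy) {
  Eval ev;
  eval_state(y, t, m, ev);
  for (int i = 0; i < 6; ++i) dy[i] = ev.dV[i];
}

const int NTRAJ = 25; // trajectory columns

void record_row(double* row, double t, const double* y, const Eval& ev) {
  int k = 0;
  row[k++] = t;
  for (int i = 0; i < 6; ++i) row[k++] = y[i];
  for (int i = 0; i < 6; ++i) row[k++] = ev.P[i];
  row[k++] = ev.Pao;
  row[k++] = ev.cvp;
  row[k++] = ev.Qavv;
  row[k++] = ev.Qreg;
  row[k++] = ev.Qav;
  row[k++] = ev.Qpump_mls;
  row[k++] = ev.Qras;
  row[k++] = ev.Qvscp;
  row[k++] = ev.Qrap;
  row[k++] = ev.Qrvp;
  row[k++] = ev.e_sa;
  row[k++] = ev.e_sv;
}

} // namespace

// [[Rcpp::export(name = ".fontan_derivs_cpp")]]
NumericVector fontan_derivs_cpp(NumericVector par, NumericVector y,
                                double t) {
  Model m = unpack(par);
  double dy[6];
  derivs(REAL(y), t, m, dy);
  return NumericVector(dy, dy + 6);
}

// [[Rcpp::export(name = ".fontan_observe_cpp")]]
NumericVector fontan_observe_cpp(NumericVector par, NumericVector y,
                                 double t) {
  Model m = unpack(par);
  Eval ev;
  eval_state(REAL(y), t, m, ev);
  NumericVector row(NTRAJ);
  record_row(REAL(row), t, REAL(y), ev);
  return row;
}

// Integrate n_beats cardiac cycles from y0. If tol > 0, stop the silent phase
// as soon as the max relative change of beat-averaged volumes between
// consecutive beats drops below tol (cap n_beats), then integrate one further
// beat with recording. If record_all, every beat is recorded and no extra
// beat is added.
// [[Rcpp::export(name = ".fontan_run_cpp")]]
List fontan_run_cpp(NumericVector par, NumericVector y0, int n_beats,
                    int steps_per_beat, double tol, int sample_every,
                    bool record_all, double t0) {
  Model m = unpack(par);
  double y[6];
  for (int i = 0; i < 6; ++i) y[i] = y0[i];
  const double dt = m.Tc / steps_per_beat;
  const double vtot0 = y[0] + y[1] + y[2] + y[3] + y[4] + y[5];

  std::vector<double> traj;
  std::vector<double> beat_means;
  int beats_done = 0;
  bool converged = false;
  double prev_mean[6] = {0, 0, 0, 0, 0, 0};

  // beat-level accumulators for the recorded (or every) beat
  double stat_sum[NTRAJ];
  double min_P_sa = 0, min_P_sv = 0, min_V[6];
  NumericVector stats; // filled from the last completed beat

  int silent_beats = record_all ? 0 : (tol > 0.0 ? n_beats : n_beats - 1);
  int total_cap = record_all ? n_beats : silent_beats + 1;

  for (int beat = 0; beat < total_cap; ++beat) {
    bool recording = record_all || beat >= silent_beats || converged;
    double vol_sum[6] = {0, 0, 0, 0, 0, 0};
    for (int j = 0; j < NTRAJ; ++j) stat_sum[j] = 0.0;
    min_P_sa = R_PosInf; min_P_sv = R_PosInf;
    for (int i = 0; i < 6; ++i) min_V[i] = R_PosInf;

    for (int s = 0; s < steps_per_beat; ++s) {
      double t = t0 + (beats_done * (double)steps_per_beat + s) * dt;
      Eval ev;
      eval_state(y, t, m, ev);
      // accumulate step-start values (uniform sampling over the period)
      for (int i = 0; i < 6; ++i) vol_sum[i] += y[i];
      if (recording) {
        double row[NTRAJ];
        record_row(row, t, y, ev);
        for (int j = 0; j < NTRAJ; ++j) stat_sum[j] += row[j];
        if (ev.P[0] < min_P_sa) min_P_sa = ev.P[0];
        if (ev.P[1] < min_P_sv) min_P_sv = ev.P[1];
        for (int i = 0; i < 6; ++i)
          if (y[i] < min_V[i]) min_V[i] = y[i];
        if (s % sample_every == 0)
          traj.insert(traj.end(), row, row + NTRAJ);
      }
      // classical RK4
      double k1[6], k2[6], k3[6], k4[6], ytmp[6];
      for (int i = 0; i < 6; ++i) k1[i] = ev.dV[i];
      for (int i = 0; i < 6; ++i) ytmp[i] = y[i] + 0.5 * dt * k1[i];
      derivs(ytmp, t + 0.5 * dt, m, k2);
      for (int i = 0; i < 6; ++i) ytmp[i] = y[i] + 0.5 * dt * k2[i];
      derivs(ytmp, t + 0.5 * dt, m, k3);
      for (int i = 0; i < 6; ++i) ytmp[i] = y[i] + dt * k3[i];
      derivs(ytmp, t + dt, m, k4);
      for (int i = 0; i < 6; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!R_finite(y[0]) || !R_finite(y[1]))
        stop("non-finite state at t = %f (beat %d)", t, beats_done + 1);
    }
    ++beats_done;

    double mean_now[6];
    for (int i = 0; i < 6; ++i) mean_now[i] = vol_sum[i] / steps_per_beat;
    beat_means.insert(beat_means.end(), mean_now, mean_now + 6);

    if (recording) {
      stats = NumericVector(NTRAJ);
      for (int j = 0; j < NTRAJ; ++j) stats[j] = stat_sum[j] / steps_per_beat;
    }

    if (tol > 0.0 && beat > 0) {
      double maxrel = 0.0;
      for (int i = 0; i < 6; ++i) {
        double denom = std::max(std::fabs(prev_mean[i]), 1.0);
        double rel = std::fabs(mean_now[i] - prev_mean[i]) / denom;
        if (rel > maxrel) maxrel = rel;
      }
      if (!converged && maxrel < tol) {
        if (record_all) {
          converged = true;
          break;
        }
        converged = true; // next beat records, then we stop
        silent_beats = beat + 1;
        total_cap = beat + 2;
      }
    }
    for (int i = 0; i < 6; ++i) prev_mean[i] = mean_now[i];
  }

  int nrow = traj.size() / NTRAJ;
  NumericMatrix tm(nrow, NTRAJ);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < NTRAJ; ++c) tm(r, c) = traj[r * NTRAJ + c];

  int nb = beat_means.size() / 6;
  NumericMatrix bm(nb, 6);
  for (int r = 0; r < nb; ++r)
    for (int c = 0; c < 6; ++c) bm(r, c) = beat_means[r * 6 + c];

  double vtot1 = y[0] + y[1] + y[2] + y[3] + y[4] + y[5];

  return List::create(
      _["trajectory"] = tm,
      _["beat_means"] = bm,
      _["n_beats"] = beats_done,
      _["converged"] = converged,
      _["final_state"] = NumericVector(y, y + 6),
      _["beat_stats"] = stats,
      _["min_p_sa"] = min_P_sa,
      _["min_p_sv"] = min_P_sv,
      _["min_volumes"] = NumericVector(min_V, min_V + 6),
      _["volume_drift"] = vtot1 - vtot0);
}
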