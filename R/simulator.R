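#' Flow through an ideal diode valve
#'
#' Forward conduction only: `Q = max(P_up - P_down, 0) / R`.
#'
#' @param P_up,P_down Upstream and downstream pressures, mmHg.
#' @param R Series resistance, mmHg s/mL (`> 0`).
#' @return Flow, mL/s (non-negative).
#' @export
valve_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  pmax(P_up - P_down, 0) / R
}

#' Regurgitant atrioventricular flow
#'
#' The incompetent-valve branch conducts ventricle-to-atrium only:
#' `Q = max(P_ventricle - P_atrium, 0) / R_AVVR`. With `R_AVVR = NULL`
#' (competent valve) the flow is identically zero.
#'
#' @param P_ventricle,P_atrium Chamber pressures, mmHg.
#' @param R_AVVR Regurgitant branch resistance, mmHg s/mL, or `NULL`.
#' @return Flow, mL/s.
#' @export
regurgitant_flow <- function(P_ventricle, P_atrium, R_AVVR) {
  if (is.null(R_AVVR)) return(0 * P_ventricle)
  valve_flow(P_ventricle, P_atrium, R_AVVR)
}

#' Aortic-root node pressure
#'
#' The aortic root is a capacitor-free node fed by the aortic valve and the
#' pump (both from the ventricle) and drained through the systemic
#' characteristic impedance. Its pressure solves the scalar flow balance
#' `Q_AV(P_n) + Q_pump = (P_n - P_Cas) / R_c,s`. In the closed loop the
#' device contributes its zero-head characteristic flow
#' `Q_pump = pump_flow(0, pump)` (the operating-point coupling of the source
#' model; see the methods vignette), so the balance is piecewise linear and
#' solved exactly: with the valve reverse-biased,
#' `P_n = P_Cas + Q_pump R_c,s`; with it conducting, the resistive divider
#' augmented by the source term.
#'
#' @param P_SV Ventricular pressure, mmHg.
#' @param P_Cas Systemic arterial capacitance pressure, mmHg.
#' @param model A [fontan_model()].
#' @return Node pressure, mmHg.
#' @export
aortic_node_pressure <- function(P_SV, P_Cas, model) {
  R_av <- model$valves$R_AV
  R_cs <- model$systemic$R_c
  pump <- model$pump
  pump_on <- !is.null(pump) && pump$enabled && pump$rpm > 0
  q_p <- if (pump_on) pump_flow(0, pump, warn_clamp = FALSE) * 1000 / 60 else 0
  pn_closed <- P_Cas + q_p * R_cs
  if (P_SV <= pn_closed) return(pn_closed)
  (P_SV / R_av + P_Cas / R_cs + q_p) / (1 / R_av + 1 / R_cs)
}

#' Volume derivatives of the six-compartment loop
#'
#' Applies the volume balance at each storage element of the closed loop.
#' This is the readable R reference path composed from the exported
#' primitives; the integrator uses an equivalent compiled version. The six
#' rates sum to zero exactly (closed-loop conservation).
#'
#' @param state Named numeric vector `V_SA, V_SV, V_Cas, V_Cvs, V_Cap, V_Cvp`
#'   (mL).
#' @param t Global time, s.
#' @param model A [fontan_model()].
#' @param freeze_activation Optional fixed activation value in \[0, 1\]
#'   replacing the time-varying waveform (linearised-circuit analyses).
#' @param diode_mode `"ideal"` (default) or `"resistor"` (valves conduct in
#'   both directions; pump must be off), used by the linear-network checks.
#' @return Named vector of `dV/dt`, mL/s.
#' @export
circulation_derivatives <- function(state, t, model, freeze_activation = NULL,
                                    diode_mode = c("ideal", "resistor")) {
  diode_mode <- match.arg(diode_mode)
  s <- model$systemic; p <- model$pulmonary
  if (is.null(freeze_activation)) {
    P_sa <- chamber_pressure(state[["V_SA"]], t, model$sa, model$timing)
    P_sv <- chamber_pressure(state[["V_SV"]], t, model$sv, model$timing)
  } else {
    e <- freeze_activation
    P_sa <- (end_systolic_pressure(state[["V_SA"]], model$sa) -
               end_diastolic_pressure(state[["V_SA"]], model$sa)) * e +
      end_diastolic_pressure(state[["V_SA"]], model$sa)
    P_sv <- (end_systolic_pressure(state[["V_SV"]], model$sv) -
               end_diastolic_pressure(state[["V_SV"]], model$sv)) * e +
      end_diastolic_pressure(state[["V_SV"]], model$sv)
  }
  P_cas <- capacitance_pressure(state[["V_Cas"]], s$C_a)
  P_cvs <- capacitance_pressure(state[["V_Cvs"]], s$C_v)
  P_cap <- capacitance_pressure(state[["V_Cap"]], p$C_a)
  P_cvp <- capacitance_pressure(state[["V_Cvp"]], p$C_v)

  if (diode_mode == "resistor") {
    pump_on <- !is.null(model$pump) && model$pump$enabled && model$pump$rpm > 0
    if (pump_on)
      stop("`diode_mode = \"resistor\"` requires the pump to be off",
           call. = FALSE)
    q_avv <- resistor_flow(P_sa, P_sv, model$valves$R_AVV)
    q_reg <- 0
    p_n <- (P_sv / model$valves$R_AV + P_cas / s$R_c) /
      (1 / model$valves$R_AV + 1 / s$R_c)
    q_av <- resistor_flow(P_sv, p_n, model$valves$R_AV)
    q_pump <- 0
  } else {
    q_avv <- valve_flow(P_sa, P_sv, model$valves$R_AVV)
    q_reg <- regurgitant_flow(P_sv, P_sa, model$valves$R_AVVR)
    p_n <- aortic_node_pressure(P_sv, P_cas, model)
    q_av <- valve_flow(P_sv, p_n, model$valves$R_AV)
    q_pump <- if (!is.null(model$pump) && model$pump$enabled &&
                  model$pump$rpm > 0)
      pump_flow(0, model$pump, warn_clamp = FALSE) * 1000 / 60
    else 0
  }

  q_root <- q_av + q_pump
  q_ras <- resistor_flow(P_cas, P_cvs, s$R_a)
  q_vscp <- resistor_flow(P_cvs, P_cap, s$R_v + p$R_c)
  q_rap <- resistor_flow(P_cap, P_cvp, p$R_a)
  q_rvp <- resistor_flow(P_cvp, P_sa, p$R_v)

  c(V_SA = volume_derivative(c(q_rvp, q_reg), q_avv),
    V_SV = volume_derivative(q_avv, c(q_root, q_reg)),
    V_Cas = volume_derivative(q_root, q_ras),
    V_Cvs = volume_derivative(q_ras, q_vscp),
    V_Cap = volume_derivative(q_vscp, q_rap),
    V_Cvp = volume_derivative(q_rap, q_rvp))
}

traj_cols <- c("time", "V_SA", "V_SV", "V_Cas", "V_Cvs", "V_Cap", "V_Cvp",
               "P_SA", "P_SV", "P_Cas", "P_Cvs", "P_Cap", "P_Cvp",
               "P_ao", "CVP", "Q_AVV", "Q_reg", "Q_AV", "Q_pump",
               "Q_ras", "Q_vs_cp", "Q_rap", "Q_rvp", "e_SA", "e_SV")

new_fontan_sim <- function(raw, model, steps_per_beat, sample_every,
                           requested_beats) {
  traj <- tibble::as_tibble(
    stats::setNames(as.data.frame(raw$trajectory), traj_cols))
  structure(
    list(trajectory = traj, model = model, n_beats = raw$n_beats,
         converged = raw$converged,
         final_state = stats::setNames(raw$final_state, names(initial_state(model))),
         beat_means = raw$beat_means,
         beat_stats = stats::setNames(raw$beat_stats, traj_cols),
         min_p_sa = raw$min_p_sa, min_p_sv = raw$min_p_sv,
         min_volumes = stats::setNames(raw$min_volumes,
                                       names(initial_state(model))),
         volume_drift = raw$volume_drift,
         steps_per_beat = steps_per_beat, sample_every = sample_every,
         requested_beats = requested_beats),
    class = "fontan_sim"
  )
}

#' Simulate the circulation for a fixed number of beats
#'
#' Integrates the six-volume ODE with a fixed-step classical Runge-Kutta
#' scheme (default 4000 steps per beat, i.e. 0.2 ms at 75 bpm) and returns
#' the dense trajectory with all derived pressures and flows. Total stressed
#' volume is conserved to round-off.
#'
#' @param model A [fontan_model()].
#' @param n_beats Number of cardiac cycles to integrate (`>= 1`).
#' @param init Initial state vector; defaults to [initial_state()].
#' @param steps_per_beat Integration steps per cycle.
#' @param sample_every Record every this-many steps (default gives 1000
#'   samples per beat).
#' @param record `"all"` to keep every beat's samples, `"last"` to keep only
#'   the final beat.
#' @param freeze_activation,diode_mode Linearised-circuit options, see
#'   [circulation_derivatives()].
#' @return A `fontan_sim` object; `$trajectory` is a tibble, `tidy()` gives
#'   the beat-averaged summary of the final recorded beat.
#' @examples
#' \donttest{
#' sim <- simulate_fontan(make_systolic_dysfunction(), n_beats = 5)
#' tidy(sim)
#' }
#' @export
simulate_fontan <- function(model, n_beats = 30, init = NULL,
                            steps_per_beat = 4000,
                            sample_every = max(1L, steps_per_beat %/% 1000L),
                            record = c("all", "last"),
                            freeze_activation = NULL,
                            diode_mode = c("ideal", "resistor")) {
  stopifnot(inherits(model, "fontan_model"), n_beats >= 1)
  record <- match.arg(record)
  if (is.null(init)) init <- initial_state(model)
  raw <- .fontan_run_cpp(pack_model(model, freeze_activation, diode_mode),
                         as.numeric(init),
                         as.integer(n_beats), as.integer(steps_per_beat),
                         0, as.integer(sample_every), record == "all", 0)
  new_fontan_sim(raw, model, steps_per_beat, sample_every, n_beats)
}

#' Run a model to its periodic steady state
#'
#' Integrates beat by beat until the maximum relative change of the
#' beat-averaged compartment volumes between consecutive beats falls below
#' `tol`, then records one further (converged) beat densely. Errors if the
#' cap is reached without convergence.
#'
#' @param model A [fontan_model()].
#' @param init Initial state; defaults to [initial_state()].
#' @param tol Convergence tolerance on the relative change of beat-averaged
#'   volumes (denominator floored at 1 mL).
#' @param max_beats Beat cap before a convergence error.
#' @param steps_per_beat,sample_every See [simulate_fontan()].
#' @param freeze_activation,diode_mode Linearised-circuit options, see
#'   [circulation_derivatives()].
#' @return A `fontan_sim` object whose trajectory is the converged beat.
#' @examples
#' \donttest{
#' ss <- run_to_steady_state(make_systolic_dysfunction())
#' glance(ss)
#' }
#' @export
run_to_steady_state <- function(model, init = NULL, tol = 1e-6,
                                max_beats = 300, steps_per_beat = 4000,
                                sample_every = max(1L, steps_per_beat %/% 1000L),
                                freeze_activation = NULL,
                                diode_mode = c("ideal", "resistor")) {
  stopifnot(inherits(model, "fontan_model"))
  if (is.null(init)) init <- initial_state(model)
  raw <- .fontan_run_cpp(pack_model(model, freeze_activation, diode_mode),
                         as.numeric(init),
                         as.integer(max_beats), as.integer(steps_per_beat),
                         tol, as.integer(sample_every), FALSE, 0)
  if (!raw$converged) {
    bm <- raw$beat_means
    n <- nrow(bm)
    resid <- max(abs(bm[n, ] - bm[n - 1, ]) / pmax(abs(bm[n - 1, ]), 1))
    stop(sprintf(
      "no periodic steady state within %d beats (residual %.2e > tol %.1e)",
      max_beats, resid, tol), call. = FALSE)
  }
  new_fontan_sim(raw, model, steps_per_beat, sample_every, max_beats)
}

#' @export
print.fontan_sim <- function(x, ...) {
  cat("<fontan_sim>\n")
  cat(sprintf("  %d beat(s) integrated%s, %d trajectory samples\n",
              x$n_beats,
              if (isTRUE(x$converged)) " (converged to periodic steady state)"
              else "",
              nrow(x$trajectory)))
  s <- beat_summary(x)
  cat(sprintf("  CI %.2f L/min/m^2 | MAP %.1f | CVP %.1f | SA %.2f mmHg\n",
              s$cardiac_index, s$mean_arterial_pressure, s$cvp,
              s$mean_sa_pressure))
  invisible(x)
}

#' Beat-averaged hemodynamic summary
#'
#' Summarises the final recorded beat: cardiac index (beat-mean aortic valve
#' plus pump flow, indexed to BSA), mean arterial pressure (beat-mean
#' aortic-root pressure; the systemic arterial capacitance mean is reported
#' separately), central venous pressure at the cavopulmonary node, mean and
#' minimum chamber pressures, per-beat minimum compartment volumes, pump
#' flow, and the regurgitant fraction (backward / forward atrioventricular
#' volume per beat, as a percentage).
#'
#' @param sim A `fontan_sim` object.
#' @return A one-row tibble.
#' @export
beat_summary <- function(sim) {
  stopifnot(inherits(sim, "fontan_sim"))
  st <- sim$beat_stats
  model <- sim$model
  T_c <- model$timing$T_c
  co_mls <- st[["Q_AV"]] + st[["Q_pump"]]
  fwd_vol <- st[["Q_AVV"]] * T_c
  reg_vol <- st[["Q_reg"]] * T_c
  tibble::tibble(
    cardiac_index = co_mls * 60 / 1000 / model$bsa,
    mean_arterial_pressure = st[["P_ao"]],
    mean_p_cas = st[["P_Cas"]],
    cvp = st[["CVP"]],
    mean_sa_pressure = st[["P_SA"]],
    mean_sv_pressure = st[["P_SV"]],
    regurgitant_fraction = if (fwd_vol > 0) 100 * reg_vol / fwd_vol else 0,
    mean_pump_flow = st[["Q_pump"]] * 60 / 1000,
    stroke_forward_avv = fwd_vol,
    stroke_regurgitant = reg_vol,
    min_p_sa = sim$min_p_sa,
    min_p_sv = sim$min_p_sv,
    min_v_sa = sim$min_volumes[["V_SA"]],
    min_v_sv = sim$min_volumes[["V_SV"]],
    min_v_cas = sim$min_volumes[["V_Cas"]],
    min_v_cvs = sim$min_volumes[["V_Cvs"]],
    min_v_cap = sim$min_volumes[["V_Cap"]],
    min_v_cvp = sim$min_volumes[["V_Cvp"]],
    n_beats = sim$n_beats,
    rpm = if (!is.null(model$pump) && model$pump$enabled) model$pump$rpm else 0,
    stressed_blood_volume = model$stressed_blood_volume
  )
}

#' @rdname beat_summary
#' @param x A `fontan_sim` object.
#' @param ... Unused.
#' @export
tidy.fontan_sim <- function(x, ...) beat_summary(x)

#' One-line model/run overview
#'
#' @param x A `fontan_sim` object.
#' @param ... Unused.
#' @return A one-row tibble with the headline hemodynamics and run metadata.
#' @export
glance.fontan_sim <- function(x, ...) {
  s <- beat_summary(x)
  tibble::tibble(
    cardiac_index = s$cardiac_index,
    mean_arterial_pressure = s$mean_arterial_pressure,
    cvp = s$cvp,
    mean_sa_pressure = s$mean_sa_pressure,
    regurgitant_fraction = s$regurgitant_fraction,
    n_beats = x$n_beats,
    converged = isTRUE(x$converged),
    volume_drift = x$volume_drift
  )
}

# All per-beat minima that the titration stop rules guard: the two chamber
# pressures and all six compartment volumes.
guarded_minima <- function(sim) {
  c(p_sa = sim$min_p_sa, p_sv = sim$min_p_sv, sim$min_volumes)
}

feasible_minima <- function(sim, slack = 1e-9) {
  all(guarded_minima(sim) >= -slack)
}
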