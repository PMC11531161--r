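#' Valve parameters
#'
#' Each valve is an ideal diode in series with a small resistance. An
#' incompetent atrioventricular valve additionally carries a reverse-connected
#' diode-resistor branch (`R_AVVR`); leave it `NULL` for a competent valve.
#'
#' @param R_AV Forward aortic valve resistance, mmHg s/mL.
#' @param R_AVV Forward atrioventricular valve resistance, mmHg s/mL.
#' @param R_AVVR Regurgitant atrioventricular branch resistance, mmHg s/mL,
#'   or `NULL` (competent valve).
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(R_AV = 0.001, R_AVV = 0.001, R_AVVR = NULL) {
  if (R_AV <= 0 || R_AVV <= 0)
    stop("forward valve resistances must be positive", call. = FALSE)
  if (!is.null(R_AVVR) && R_AVVR <= 0)
    stop("`R_AVVR` must be positive when present", call. = FALSE)
  structure(list(R_AV = R_AV, R_AVV = R_AVV, R_AVVR = R_AVVR),
            class = "valve_params")
}

#' Assemble a closed-loop Fontan circulation model
#'
#' Combines the two chambers, the valves, the systemic and pulmonary
#' Windkessel beds, an optional continuous-flow pump, the cardiac timing, the
#' body surface area and the total stressed blood volume into one model
#' object. The loop topology is: SV -> (aortic valve || pump) -> aortic root
#' -> R_c,s -> C_a,s -> R_a,s -> C_v,s -> R_v,s -> cavopulmonary node ->
#' R_c,p -> C_a,p -> R_a,p -> C_v,p -> R_v,p -> SA -> AVV -> SV.
#'
#' @param sv,sa [chamber_params()] for the single ventricle and atrium.
#' @param valves A [valve_params()] object.
#' @param systemic,pulmonary [vascular_bed_params()] objects.
#' @param pump A [pump_params()] object or `NULL` (no device attached).
#' @param timing A [timing_params()] object.
#' @param bsa Body surface area, m^2.
#' @param stressed_blood_volume Total stressed blood volume `V_s`, mL: the sum
#'   of the four capacitance stressed volumes and the two chamber volumes.
#' @return An object of class `fontan_model`.
#' @seealso [baseline_fontan()] for the standard parameterization.
#' @export
fontan_model <- function(sv, sa, valves, systemic, pulmonary, pump = NULL,
                         timing = timing_params(75), bsa = 1.9,
                         stressed_blood_volume = 1500) {
  stopifnot(inherits(sv, "chamber_params"), inherits(sa, "chamber_params"),
            inherits(valves, "valve_params"),
            inherits(systemic, "vascular_bed_params"),
            inherits(pulmonary, "vascular_bed_params"),
            inherits(timing, "timing_params"))
  if (!is.null(pump)) stopifnot(inherits(pump, "pump_params"))
  if (bsa <= 0) stop("`bsa` must be positive", call. = FALSE)
  if (stressed_blood_volume <= 0)
    stop("`stressed_blood_volume` must be positive", call. = FALSE)
  for (ch in list(sv, sa))
    if (2 * ch$T_es > timing$T_c)
      stop("`2 * T_es` must not exceed the cycle duration", call. = FALSE)
  structure(
    list(sv = sv, sa = sa, valves = valves, systemic = systemic,
         pulmonary = pulmonary, pump = pump, timing = timing, bsa = bsa,
         stressed_blood_volume = stressed_blood_volume),
    class = "fontan_model"
  )
}

#' @export
print.fontan_model <- function(x, ...) {
  cat("<fontan_model>\n")
  cat(sprintf("  HR %g bpm (T_c %g s), BSA %g m^2, V_s %g mL\n",
              x$timing$heart_rate, x$timing$T_c, x$bsa,
              x$stressed_blood_volume))
  cat(sprintf("  SV: E_es %g, A %g, B %g, V0 %g | SA: E_es %g, A %g, B %g, V0 %g\n",
              x$sv$E_es, x$sv$A, x$sv$B, x$sv$V0,
              x$sa$E_es, x$sa$A, x$sa$B, x$sa$V0))
  cat(sprintf("  AVV regurgitation: %s\n",
              if (is.null(x$valves$R_AVVR)) "none"
              else sprintf("R_AVVR %g", x$valves$R_AVVR)))
  cat(sprintf("  PVRI %.2f Wood units m^2\n",
              pvri_from_resistances(x$pulmonary$R_a, x$pulmonary$R_c,
                                    x$pulmonary$R_v, x$bsa)))
  if (is.null(x$pump) || !x$pump$enabled) {
    cat("  pump: off\n")
  } else {
    cat(sprintf("  pump: on at %g rpm\n", x$pump$rpm))
  }
  invisible(x)
}

#' Set the pump speed of a model
#'
#' @param model A [fontan_model()].
#' @param rpm Rotational frequency, rpm; `0` turns the pump off.
#' @return The modified model.
#' @export
set_pump_speed <- function(model, rpm) {
  stopifnot(inherits(model, "fontan_model"))
  if (is.null(model$pump)) model$pump <- pump_params(rpm = rpm)
  model$pump$rpm <- rpm
  model$pump$enabled <- rpm > 0
  model
}

#' Set the total stressed blood volume of a model
#'
#' @param model A [fontan_model()].
#' @param sbv Total stressed blood volume, mL.
#' @return The modified model.
#' @export
set_stressed_volume <- function(model, sbv) {
  stopifnot(inherits(model, "fontan_model"))
  if (sbv <= 0) stop("`sbv` must be positive", call. = FALSE)
  model$stressed_blood_volume <- sbv
  model
}

# Flatten a model (plus simulator options) into the parameter vector consumed
# by the compiled core. Order must match src/fontan_core.cpp.
pack_model <- function(model, freeze_activation = NULL,
                       diode_mode = c("ideal", "resistor")) {
  diode_mode <- match.arg(diode_mode)
  pump <- model$pump
  pump_on <- !is.null(pump) && pump$enabled && pump$rpm > 0
  if (is.null(pump)) pump <- pump_params(rpm = 0, enabled = FALSE)
  has_reg <- !is.null(model$valves$R_AVVR)
  c(model$timing$T_c,
    model$sv$E_es, model$sv$A, model$sv$B, model$sv$V0, model$sv$T_es,
    model$sv$activation_offset,
    model$sa$E_es, model$sa$A, model$sa$B, model$sa$V0, model$sa$T_es,
    model$sa$activation_offset,
    model$valves$R_AV, model$valves$R_AVV,
    as.numeric(has_reg), if (has_reg) model$valves$R_AVVR else 1,
    model$systemic$R_c, model$systemic$R_a, model$systemic$R_v,
    model$systemic$C_a, model$systemic$C_v,
    model$pulmonary$R_c, model$pulmonary$R_a, model$pulmonary$R_v,
    model$pulmonary$C_a, model$pulmonary$C_v,
    as.numeric(pump_on), pump$K_A, pump$K_B, pump$K_C, pump$rpm,
    if (is.null(freeze_activation)) NaN else freeze_activation,
    as.numeric(diode_mode == "resistor"))
}

#' Initial distribution of the stressed blood volume
#'
#' Places the ventricle at its unstressed volume plus a nominal 50 mL, the
#' atrium at its unstressed volume plus 10 mL (the steep atrial EDPVR keeps
#' the working atrial stressed volume below ~20 mL, so a larger seed would
#' put the exponential far outside its physiological range), and the
#' remaining stressed volume in the systemic venous capacitance — the
#' compartment through which the titration protocols add or withdraw volume.
#' The other capacitances start empty. The periodic steady state does not
#' depend on this split, only on the total.
#'
#' @param model A [fontan_model()].
#' @return Named numeric vector of the six state volumes, mL.
#' @export
initial_state <- function(model) {
  sbv <- model$stressed_blood_volume
  v_sa <- model$sa$V0 + 10
  v_sv <- model$sv$V0 + 50
  rem <- sbv - v_sa - v_sv
  if (rem < 0) {
    # tiny total volumes: split evenly instead
    v_sa <- sbv / 2
    v_sv <- sbv / 2
    rem <- 0
  }
  c(V_SA = v_sa, V_SV = v_sv, V_Cas = 0, V_Cvs = rem, V_Cap = 0, V_Cvp = 0)
}

# Stressed-volume accounting: the chamber volumes enter the budget as-is
# (the atrial unstressed 5 mL is part of V_s in the source parameterization).
stressed_total <- function(state, model) {
  sum(state)
}
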