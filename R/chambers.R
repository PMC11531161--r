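#' Chamber parameters for the time-varying elastance model
#'
#' Each cardiac chamber (single atrium, SA, or single ventricle, SV) is
#' described by a linear end-systolic pressure-volume relation (ESPVR, slope
#' `E_es`), an exponential end-diastolic relation (EDPVR, `A`, `B`), an
#' unstressed volume `V0`, a time to end systole `T_es`, and an activation
#' offset relative to ventricular systole onset (negative values mean the
#' chamber activates earlier; the atrium leads by 16 ms).
#'
#' @param E_es End-systolic elastance, mmHg/mL. Must be positive.
#' @param A EDPVR scaling factor, mmHg. Non-negative.
#' @param B EDPVR exponent, 1/mL. Non-negative.
#' @param V0 Unstressed volume, mL. Non-negative.
#' @param T_es Time to end systole, s. Must satisfy `0 < T_es` and
#'   `2 * T_es <= T_c` of the timing used with the chamber.
#' @param activation_offset Activation time shift, s (0 for the ventricle,
#'   -0.016 for the atrium).
#'
#' @return An object of class `chamber_params` (a named list).
#' @examples
#' sv <- chamber_params(E_es = 3, A = 0.35, B = 0.033, V0 = 0, T_es = 0.2)
#' end_systolic_pressure(100, sv)
#' @export
chamber_params <- function(E_es, A, B, V0, T_es, activation_offset = 0) {
  stopifnot(is.numeric(E_es), is.numeric(A), is.numeric(B),
            is.numeric(V0), is.numeric(T_es))
  if (E_es <= 0) stop("`E_es` must be positive", call. = FALSE)
  if (A < 0) stop("`A` must be non-negative", call. = FALSE)
  if (B < 0) stop("`B` must be non-negative", call. = FALSE)
  if (V0 < 0) stop("`V0` must be non-negative", call. = FALSE)
  if (T_es <= 0) stop("`T_es` must be positive", call. = FALSE)
  structure(
    list(E_es = E_es, A = A, B = B, V0 = V0, T_es = T_es,
         activation_offset = activation_offset),
    class = "chamber_params"
  )
}

#' Cardiac timing parameters
#'
#' @param heart_rate Heart rate, beats/min.
#' @param T_c Cardiac cycle duration, s. Defaults to `60 / heart_rate`.
#' @return An object of class `timing_params`.
#' @examples
#' timing_params(75)
#' @export
timing_params <- function(heart_rate = 75, T_c = 60 / heart_rate) {
  if (T_c <= 0) stop("`T_c` must be positive", call. = FALSE)
  if (abs(T_c - 60 / heart_rate) > 1e-9)
    stop("`T_c` must equal 60 / heart_rate", call. = FALSE)
  structure(list(T_c = T_c, heart_rate = heart_rate), class = "timing_params")
}

#' Normalized elastance (activation) waveform
#'
#' Raised-cosine activation: `0.5 * (1 - cos(pi * t / T_es))` for
#' `0 <= t < 2 * T_es` within the cycle, 0 for the rest of the cycle. Time is
#' reduced modulo `T_c`, so the waveform extends periodically.
#'
#' @param t Time, s (vectorised).
#' @param T_es Time to end systole, s.
#' @param T_c Cycle duration, s. Requires `2 * T_es <= T_c`.
#' @return Activation value(s) in \[0, 1\].
#' @examples
#' normalized_elastance(c(0, 0.1, 0.2, 0.5), T_es = 0.2, T_c = 0.8)
#' @export
normalized_elastance <- function(t, T_es, T_c) {
  if (T_es <= 0) stop("`T_es` must be positive", call. = FALSE)
  if (2 * T_es > T_c)
    stop("`2 * T_es` must not exceed `T_c`", call. = FALSE)
  tl <- t %% T_c
  ifelse(tl < 2 * T_es, 0.5 * (1 - cos(pi * tl / T_es)), 0)
}

#' End-diastolic pressure-volume relation (EDPVR)
#'
#' Exponential EDPVR `A * (exp(B * (V - V0)) - 1)`. Below the unstressed
#' volume the formula is extended unchanged and returns small negative
#' pressures; the titration protocols rely on inspecting true minima, so no
#' clamping is applied.
#'
#' @param V Chamber volume, mL (vectorised).
#' @param params A [chamber_params()] object.
#' @return Pressure, mmHg.
#' @examples
#' sv <- chamber_params(E_es = 3, A = 0.35, B = 0.033, V0 = 0, T_es = 0.2)
#' end_diastolic_pressure(100, sv)
#' @export
end_diastolic_pressure <- function(V, params) {
  params$A * (exp(params$B * (V - params$V0)) - 1)
}

#' End-systolic pressure-volume relation (ESPVR)
#'
#' Linear ESPVR `E_es * (V - V0)`.
#'
#' @inheritParams end_diastolic_pressure
#' @return Pressure, mmHg.
#' @export
end_systolic_pressure <- function(V, params) {
  params$E_es * (V - params$V0)
}

#' Instantaneous chamber pressure
#'
#' Time-varying elastance blend of the ESPVR and EDPVR pressures:
#' `P = (P_es(V) - P_ed(V)) * e(t) + P_ed(V)`, where `e(t)` is the
#' normalized elastance evaluated on the chamber's own clock
#' `(t - activation_offset) mod T_c`.
#'
#' @param V Chamber volume, mL.
#' @param t Global time, s (0 = ventricular systole onset).
#' @param params A [chamber_params()] object.
#' @param timing A [timing_params()] object.
#' @return Pressure, mmHg.
#' @examples
#' sv <- chamber_params(E_es = 3, A = 0.35, B = 0.033, V0 = 0, T_es = 0.2)
#' chamber_pressure(100, 0.1, sv, timing_params(75))
#' @export
chamber_pressure <- function(V, t, params, timing) {
  e <- normalized_elastance(t - params$activation_offset, params$T_es,
                            timing$T_c)
  ped <- end_diastolic_pressure(V, params)
  pes <- end_systolic_pressure(V, params)
  (pes - ped) * e + ped
}
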