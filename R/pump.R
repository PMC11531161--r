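#' Continuous-flow rotary pump parameters
#'
#' Quadratic pressure-head/flow characteristic
#' `dP = K_A r^2 + K_B r Q + K_C Q^2` with `Q` in L/min and the rotational
#' frequency `r` in rpm. `K_A > 0` sets the shut-off head, `K_B <= 0` and
#' `K_C < 0` make the head fall with flow, giving the concave-down family of
#' curves characteristic of a centrifugal ventricular assist device.
#'
#' @param K_A Head coefficient, mmHg/rpm^2.
#' @param K_B Cross coefficient, mmHg per rpm per L/min. Must be `<= 0`.
#' @param K_C Flow coefficient, mmHg per (L/min)^2. Must be `< 0`.
#' @param rpm Rotational frequency, rpm (`>= 0`).
#' @param enabled Logical; whether the pump is connected in the circuit.
#' @return An object of class `pump_params`.
#' @examples
#' pump_params(rpm = 3000)
#' @export
pump_params <- function(K_A = 3.45e-6, K_B = -5.9e-5, K_C = -1.45,
                        rpm = 0, enabled = rpm > 0) {
  if (K_A <= 0) stop("`K_A` must be positive", call. = FALSE)
  if (K_B > 0) stop("`K_B` must be non-positive", call. = FALSE)
  if (K_C >= 0) stop("`K_C` must be negative", call. = FALSE)
  if (rpm < 0) stop("`rpm` must be non-negative", call. = FALSE)
  structure(list(K_A = K_A, K_B = K_B, K_C = K_C, rpm = rpm,
                 enabled = isTRUE(enabled)),
            class = "pump_params")
}

#' Pump pressure head at a given flow
#'
#' Forward characteristic `dP = K_A r^2 + K_B r Q + K_C Q^2`, strictly
#' decreasing in `Q >= 0` when the speed is positive.
#'
#' @param Q Pump flow, L/min (vectorised).
#' @param params A [pump_params()] object.
#' @param rpm Optional rpm override.
#' @return Pressure head (outlet minus inlet), mmHg.
#' @examples
#' hm <- pump_params()
#' pump_pressure_head(5, hm, rpm = 4000)
#' @export
pump_pressure_head <- function(Q, params, rpm = params$rpm) {
  if (any(rpm < 0)) stop("`rpm` must be non-negative", call. = FALSE)
  params$K_A * rpm^2 + params$K_B * rpm * Q + params$K_C * Q^2
}

#' Pump flow from pressure head and speed
#'
#' Inverts the quadratic characteristic, selecting the descending-branch root
#' (the physical one, on which head falls as flow rises):
#' `Q = (-K_B r - sqrt((K_B r)^2 - 4 K_C (K_A r^2 - dP))) / (2 K_C)`.
#' When the head is at or above the shut-off head `K_A r^2`, flow is clamped
#' at zero (no retrograde branch is modelled) with a warning; at `rpm = 0`
#' the pump is off and the flow is zero by convention.
#'
#' @param dP Pressure head (outlet minus inlet), mmHg (vectorised).
#' @param params A [pump_params()] object.
#' @param rpm Optional rpm override.
#' @param warn_clamp Warn when the zero-flow clamp activates.
#' @return Pump flow, L/min (non-negative).
#' @examples
#' hm <- pump_params()
#' pump_flow(17.77, hm, rpm = 4000)
#' @export
pump_flow <- function(dP, params, rpm = params$rpm, warn_clamp = TRUE) {
  if (rpm < 0) stop("`rpm` must be non-negative", call. = FALSE)
  if (rpm == 0) return(rep(0, length(dP)))
  shut <- params$K_A * rpm^2
  clamped <- dP > shut
  if (any(clamped) && warn_clamp)
    warning("pressure head exceeds the shut-off head at ", rpm,
            " rpm; pump flow clamped at 0", call. = FALSE)
  b <- params$K_B * rpm
  disc <- b^2 - 4 * params$K_C * (shut - dP)
  if (any(disc[!clamped] < 0))
    stop("pump characteristic has no real root: head ", max(dP),
         " mmHg unachievable at ", rpm, " rpm", call. = FALSE)
  q <- (-b - sqrt(pmax(disc, 0))) / (2 * params$K_C)
  q[clamped] <- 0
  pmax(q, 0)
}
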