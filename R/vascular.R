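#' Windkessel parameters of one vascular bed
#'
#' A modified three-element Windkessel: characteristic impedance `R_c`,
#' arterial resistance `R_a` and capacitance `C_a`, venous resistance `R_v`
#' and capacitance `C_v`. Used for both the systemic and the pulmonary
#' circulation.
#'
#' @param R_c Characteristic impedance, mmHg s/mL.
#' @param R_a Arterial resistance, mmHg s/mL.
#' @param R_v Venous resistance, mmHg s/mL.
#' @param C_a Arterial capacitance, mL/mmHg.
#' @param C_v Venous capacitance, mL/mmHg.
#' @return An object of class `vascular_bed_params`.
#' @examples
#' vascular_bed_params(R_c = 0.03, R_a = 0.7, R_v = 0.015, C_a = 1.32, C_v = 70)
#' @export
vascular_bed_params <- function(R_c, R_a, R_v, C_a, C_v) {
  vals <- c(R_c = R_c, R_a = R_a, R_v = R_v)
  if (any(vals < 0)) stop("resistances must be non-negative", call. = FALSE)
  if (C_a <= 0 || C_v <= 0) stop("capacitances must be positive", call. = FALSE)
  structure(list(R_c = R_c, R_a = R_a, R_v = R_v, C_a = C_a, C_v = C_v),
            class = "vascular_bed_params")
}

#' Flow through a linear resistance
#'
#' Ohmic pressure-flow relation `Q = (P_up - P_down) / R`; the sign carries
#' the direction.
#'
#' @param P_up,P_down Upstream and downstream pressures, mmHg.
#' @param R Resistance, mmHg s/mL. Must be strictly positive (an ideal wire
#'   is not permitted).
#' @return Flow, mL/s.
#' @examples
#' resistor_flow(10, 0, 0.7)
#' @export
resistor_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("`R` must be strictly positive", call. = FALSE)
  (P_up - P_down) / R
}

#' Pressure of a linear capacitance
#'
#' `P = V / C` on the stressed volume, so `P = 0` at zero stressed volume.
#'
#' @param V Stressed volume, mL.
#' @param C Capacitance, mL/mmHg. Must be positive.
#' @return Pressure, mmHg.
#' @export
capacitance_pressure <- function(V, C) {
  if (any(C <= 0)) stop("`C` must be positive", call. = FALSE)
  V / C
}

#' Volume balance at a storage element
#'
#' `dV/dt = sum(inflows) - sum(outflows)`.
#'
#' @param inflows,outflows Numeric vectors of flows, mL/s.
#' @return Net rate of volume change, mL/s.
#' @export
volume_derivative <- function(inflows, outflows) {
  sum(inflows) - sum(outflows)
}

#' Central venous pressure at the cavopulmonary node
#'
#' The Fontan cavopulmonary junction is the capacitor-free series node
#' between the systemic venous resistance `R_v,s` and the pulmonary
#' characteristic impedance `R_c,p`. Its pressure is the resistive divider
#' `(P_Cap * R_vs + P_Cvs * R_cp) / (R_vs + R_cp)` — a convex combination of
#' the two adjacent capacitance pressures.
#'
#' @param P_Cap Pulmonary arterial capacitance pressure, mmHg.
#' @param P_Cvs Systemic venous capacitance pressure, mmHg.
#' @param R_vs Systemic venous resistance, mmHg s/mL.
#' @param R_cp Pulmonary characteristic impedance, mmHg s/mL.
#' @return Central venous pressure, mmHg.
#' @examples
#' central_venous_pressure(19, 21, 0.015, 0.02)
#' @export
central_venous_pressure <- function(P_Cap, P_Cvs, R_vs, R_cp) {
  if (R_vs + R_cp <= 0)
    stop("`R_vs + R_cp` must be positive", call. = FALSE)
  (P_Cap * R_vs + P_Cvs * R_cp) / (R_vs + R_cp)
}

#' Pulmonary vascular resistance index from circuit resistances
#'
#' Total pulmonary resistance is the series sum `R_a,p + R_c,p + R_v,p`;
#' 1 mmHg s/mL equals 1000/60 Wood units (1 Wood unit = 1 mmHg per L/min),
#' and indexing multiplies by body surface area.
#'
#' @param R_ap Pulmonary arterial resistance, mmHg s/mL (vectorised).
#' @param R_cp Pulmonary characteristic impedance, mmHg s/mL.
#' @param R_vp Pulmonary venous resistance, mmHg s/mL.
#' @param BSA Body surface area, m^2.
#' @return PVRI, Wood units m^2.
#' @examples
#' pvri_from_resistances(0.06, 0.02, 0.015, 1.9)
#' @export
pvri_from_resistances <- function(R_ap, R_cp, R_vp, BSA) {
  if (BSA <= 0) stop("`BSA` must be positive", call. = FALSE)
  (R_ap + R_cp + R_vp) * (1000 / 60) * BSA
}
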