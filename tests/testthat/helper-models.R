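# Coarse solver settings for protocol-mechanics tests (the acceptance suite
# runs the full-resolution protocols).
fast <- list(steps_per_beat = 1000L, tol = 1e-5)

run_fast <- function(model, ...) {
  run_to_steady_state(model, steps_per_beat = fast$steps_per_beat,
                      tol = fast$tol, ...)
}

# a linear parameterization: no EDPVR (A = 0), used with frozen activation
# and resistor diodes so the whole network is a linear RC circuit
linear_model <- function(sbv = 800) {
  fontan_model(
    sv = chamber_params(E_es = 2, A = 0, B = 0, V0 = 0, T_es = 0.2),
    sa = chamber_params(E_es = 0.5, A = 0, B = 0, V0 = 5, T_es = 0.12,
                        activation_offset = -0.016),
    valves = valve_params(),
    systemic = vascular_bed_params(R_c = 0.03, R_a = 0.7, R_v = 0.015,
                                   C_a = 1.32, C_v = 70),
    pulmonary = vascular_bed_params(R_c = 0.02, R_a = 0.03, R_v = 0.015,
                                    C_a = 13, C_v = 8),
    pump = NULL, stressed_blood_volume = sbv)
}

# A random initial split of the total stressed volume. Chamber seeds stay in
# their working ranges (the exponential atrial EDPVR makes volumes far above
# ~25 mL physically meaningless and numerically explosive); the remainder is
# spread randomly over the four capacitances.
random_state <- function(model, total = model$stressed_blood_volume) {
  v_sa <- model$sa$V0 + stats::runif(1, 2, 15)
  v_sv <- model$sv$V0 + stats::runif(1, 20, 90)
  w <- stats::runif(4, 0.05, 1)
  caps <- (total - v_sa - v_sv) * w / sum(w)
  stats::setNames(c(v_sa, v_sv, caps),
                  c("V_SA", "V_SV", "V_Cas", "V_Cvs", "V_Cap", "V_Cvp"))
}
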