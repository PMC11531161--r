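#' Baseline Fontan circulation parameterization
#'
#' The standard adult Fontan parameter set: HR 75 bpm (T_c 0.8 s); ventricle
#' T_es 0.2 s, E_es 3 mmHg/mL, EDPVR A 0.35 mmHg / B 0.033 per mL, V0 0 mL;
#' atrium T_es 0.12 s, E_es 0.5, A 0.06, B 0.264, V0 5 mL, activating 16 ms
#' before the ventricle; forward valve resistances 0.001 mmHg s/mL; systemic
#' bed R_c 0.03 / R_a 0.7 / R_v 0.015 mmHg s/mL, C_a 1.32 / C_v 70 mL/mmHg;
#' pulmonary bed R_c 0.02 / R_a 0.03 / R_v 0.015, C_a 13 / C_v 8; centrifugal
#' pump coefficients K_A 3.45e-6, K_B -5.9e-5, K_C -1.45 (attached but off);
#' BSA 1.9 m^2.
#'
#' @param stressed_blood_volume Total stressed blood volume, mL. The failing
#'   scenario factories override this with their own calibrated values; the
#'   default is a nominal mid-range volume.
#' @return A [fontan_model()].
#' @examples
#' baseline_fontan()
#' @export
baseline_fontan <- function(stressed_blood_volume = 1500) {
  fontan_model(
    sv = chamber_params(E_es = 3, A = 0.35, B = 0.033, V0 = 0, T_es = 0.2,
                        activation_offset = 0),
    sa = chamber_params(E_es = 0.5, A = 0.06, B = 0.264, V0 = 5, T_es = 0.12,
                        activation_offset = -0.016),
    valves = valve_params(R_AV = 0.001, R_AVV = 0.001),
    systemic = vascular_bed_params(R_c = 0.03, R_a = 0.7, R_v = 0.015,
                                   C_a = 1.32, C_v = 70),
    pulmonary = vascular_bed_params(R_c = 0.02, R_a = 0.03, R_v = 0.015,
                                    C_a = 13, C_v = 8),
    pump = pump_params(K_A = 3.45e-6, K_B = -5.9e-5, K_C = -1.45,
                       rpm = 0, enabled = FALSE),
    timing = timing_params(75),
    bsa = 1.9,
    stressed_blood_volume = stressed_blood_volume
  )
}

#' Failing-Fontan scenario factories
#'
#' Each factory starts from [baseline_fontan()] and applies only the named
#' overrides of the corresponding pathophysiology; the first three set the
#' pulmonary arterial resistance to 0.06 mmHg s/mL (PVRI 3 Wood units m^2).
#' All four are calibrated to a cardiac index near 1.9 L/min/m^2 and a
#' central venous pressure of 20 mmHg before assist:
#'
#' * `make_systolic_dysfunction()`: ventricular `E_es` 1.215 mmHg/mL,
#'   V_s 2036 mL.
#' * `make_diastolic_dysfunction()`: ventricular EDPVR exponent `B`
#'   0.0511 per mL, V_s 1999 mL.
#' * `make_avvr()`: regurgitant branch `R_AVVR` 0.225 mmHg s/mL, V_s 2015 mL.
#' * `make_high_pvr()`: pulmonary arterial resistance 0.23 mmHg s/mL
#'   (PVRI 8.39 Wood units m^2), V_s 1903 mL, baseline contractility.
#'
#' @return A [fontan_model()].
#' @examples
#' make_systolic_dysfunction()
#' @export
make_systolic_dysfunction <- function() {
  m <- baseline_fontan(stressed_blood_volume = 2036)
  m$sv$E_es <- 1.215
  m$pulmonary$R_a <- 0.06
  m
}

#' @rdname make_systolic_dysfunction
#' @export
make_diastolic_dysfunction <- function() {
  m <- baseline_fontan(stressed_blood_volume = 1999)
  m$sv$B <- 0.0511
  m$pulmonary$R_a <- 0.06
  m
}

#' @rdname make_systolic_dysfunction
#' @export
make_avvr <- function() {
  m <- baseline_fontan(stressed_blood_volume = 2015)
  m$valves$R_AVVR <- 0.225
  m$pulmonary$R_a <- 0.06
  m
}

#' @rdname make_systolic_dysfunction
#' @export
make_high_pvr <- function() {
  m <- baseline_fontan(stressed_blood_volume = 1903)
  m$pulmonary$R_a <- 0.23
  m
}

#' Base model for the pulmonary-resistance sweep
#'
#' Combined systolic and diastolic ventricular dysfunction (ventricular
#' `E_es` 1.215 mmHg/mL and EDPVR exponent `B` 0.0511 per mL) with the pump
#' running at 3500 rpm and the pulmonary arterial resistance at its
#' low-PVRI starting value 0.06 mmHg s/mL. The sweep titrates the stressed
#' blood volume per resistance value, so the initial V_s is nominal.
#'
#' @param stressed_blood_volume Starting total stressed volume, mL.
#' @return A [fontan_model()].
#' @export
make_pvri_sweep_base <- function(stressed_blood_volume = 1500) {
  m <- baseline_fontan(stressed_blood_volume = stressed_blood_volume)
  m$sv$E_es <- 1.215
  m$sv$B <- 0.0511
  m$pulmonary$R_a <- 0.06
  m <- set_pump_speed(m, 3500)
  m
}

# ---- scenario configuration files -------------------------------------------

# parameter paths a config override may address
override_paths <- function() {
  c(paste0("sv.", c("E_es", "A", "B", "V0", "T_es", "activation_offset")),
    paste0("sa.", c("E_es", "A", "B", "V0", "T_es", "activation_offset")),
    paste0("valves.", c("R_AV", "R_AVV", "R_AVVR")),
    paste0("systemic.", c("R_c", "R_a", "R_v", "C_a", "C_v")),
    paste0("pulmonary.", c("R_c", "R_a", "R_v", "C_a", "C_v")),
    paste0("pump.", c("K_A", "K_B", "K_C", "rpm", "enabled")),
    "timing.heart_rate", "bsa", "stressed_blood_volume")
}

#' Scenario configuration
#'
#' A serialisable description of a simulation scenario: a name, a map of
#' dotted parameter paths (e.g. `"sv.E_es"`, `"pulmonary.R_a"`) to values
#' overriding [baseline_fontan()], the total stressed blood volume, an
#' optional pump speed schedule, and the protocol to run.
#'
#' @param name Scenario identifier.
#' @param overrides Named list of parameter overrides (dotted paths).
#' @param stressed_blood_volume Total stressed volume, mL.
#' @param rpm Pump speed for plain simulation, rpm (0 = off).
#' @param rpm_schedule Optional numeric vector of pump speeds for the ramp
#'   protocol.
#' @param protocol One of `"simulate"`, `"ramp"`, `"titrate_down"`,
#'   `"titrate_up"`, `"sweep"`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, overrides = list(),
                            stressed_blood_volume = 1500, rpm = 0,
                            rpm_schedule = NULL,
                            protocol = c("simulate", "ramp", "titrate_down",
                                         "titrate_up", "sweep")) {
  protocol <- match.arg(protocol)
  bad <- setdiff(names(overrides), override_paths())
  if (length(bad) > 0)
    stop("unknown parameter path(s) in overrides: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, overrides = overrides,
                 stressed_blood_volume = stressed_blood_volume, rpm = rpm,
                 rpm_schedule = rpm_schedule, protocol = protocol),
            class = "scenario_config")
}

#' Build the model described by a scenario configuration
#'
#' @param config A [scenario_config()].
#' @return A [fontan_model()].
#' @export
as_fontan_model <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  m <- baseline_fontan(stressed_blood_volume = config$stressed_blood_volume)
  for (path in names(config$overrides)) {
    val <- config$overrides[[path]]
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      m[[parts]] <- val
    } else if (parts[1] == "timing") {
      m$timing <- timing_params(val)
    } else {
      m[[parts[1]]][[parts[2]]] <- val
    }
  }
  if (config$rpm > 0) m <- set_pump_speed(m, config$rpm)
  # re-validate invariants after overrides
  fontan_model(sv = do.call(chamber_params, unclass(m$sv)),
               sa = do.call(chamber_params, unclass(m$sa)),
               valves = do.call(valve_params, unclass(m$valves)),
               systemic = do.call(vascular_bed_params, unclass(m$systemic)),
               pulmonary = do.call(vascular_bed_params, unclass(m$pulmonary)),
               pump = m$pump, timing = m$timing, bsa = m$bsa,
               stressed_blood_volume = m$stressed_blood_volume)
}

#' Read or write a scenario configuration file
#'
#' Scenario files are YAML with keys `name`, `overrides`,
#' `stressed_blood_volume`, `rpm`, `rpm_schedule`, `protocol`. Unknown keys
#' or unknown override paths are rejected with a message naming them; a
#' save/load round trip is lossless. Five canonical scenario files ship under
#' `system.file("scenarios", package = "fontansim")`.
#'
#' @param path File path.
#' @return `load_scenario_config()` returns a [scenario_config()];
#'   `save_scenario_config()` returns `path` invisibly.
#' @examples
#' f <- system.file("scenarios", "systolic_dysfunction.yaml",
#'                  package = "fontansim")
#' load_scenario_config(f)
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("name", "overrides", "stressed_blood_volume", "rpm",
             "rpm_schedule", "protocol")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown key(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  scenario_config(
    name = raw$name,
    overrides = if (is.null(raw$overrides)) list() else raw$overrides,
    stressed_blood_volume = raw$stressed_blood_volume %||% 1500,
    rpm = raw$rpm %||% 0,
    rpm_schedule = if (is.null(raw$rpm_schedule)) NULL
                   else as.numeric(raw$rpm_schedule),
    protocol = raw$protocol %||% "simulate"
  )
}

#' @rdname load_scenario_config
#' @param config A [scenario_config()].
#' @export
save_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a model's parameter table
#'
#' One row per parameter with its dotted path, value and unit, mirroring the
#' standard parameter-table layout.
#'
#' @param model A [fontan_model()].
#' @return A tibble with columns `parameter`, `value`, `unit`.
#' @export
parameter_table <- function(model) {
  stopifnot(inherits(model, "fontan_model"))
  ch_units <- c(E_es = "mmHg/mL", A = "mmHg", B = "1/mL", V0 = "mL",
                T_es = "s", activation_offset = "s")
  bed_units <- c(R_c = "mmHg s/mL", R_a = "mmHg s/mL", R_v = "mmHg s/mL",
                 C_a = "mL/mmHg", C_v = "mL/mmHg")
  rows <- list(
    tibble::tibble(parameter = "timing.heart_rate",
                   value = model$timing$heart_rate, unit = "beats/min"),
    tibble::tibble(parameter = "timing.T_c", value = model$timing$T_c,
                   unit = "s"))
  for (part in c("sv", "sa")) {
    vals <- unlist(model[[part]])
    rows <- c(rows, list(tibble::tibble(
      parameter = paste0(part, ".", names(vals)),
      value = unname(vals), unit = unname(ch_units[names(vals)]))))
  }
  v <- model$valves
  rows <- c(rows, list(tibble::tibble(
    parameter = paste0("valves.", c("R_AV", "R_AVV",
                                    if (!is.null(v$R_AVVR)) "R_AVVR")),
    value = c(v$R_AV, v$R_AVV, if (!is.null(v$R_AVVR)) v$R_AVVR),
    unit = "mmHg s/mL")))
  for (part in c("systemic", "pulmonary")) {
    vals <- unlist(model[[part]])
    rows <- c(rows, list(tibble::tibble(
      parameter = paste0(part, ".", names(vals)),
      value = unname(vals), unit = unname(bed_units[names(vals)]))))
  }
  if (!is.null(model$pump)) {
    p <- model$pump
    rows <- c(rows, list(tibble::tibble(
      parameter = paste0("pump.", c("K_A", "K_B", "K_C", "rpm", "enabled")),
      value = c(p$K_A, p$K_B, p$K_C, p$rpm, as.numeric(p$enabled)),
      unit = c("mmHg/rpm^2", "mmHg/(rpm L/min)", "mmHg/(L/min)^2", "rpm", ""))))
  }
  rows <- c(rows, list(tibble::tibble(
    parameter = c("bsa", "stressed_blood_volume"),
    value = c(model$bsa, model$stressed_blood_volume),
    unit = c("m^2", "mL"))))
  dplyr::bind_rows(rows)
}
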