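fmt6 <- function(x) {
  if (is.numeric(x)) sprintf("%.6g", x) else as.character(x)
}

#' Write a simulation trajectory as CSV
#'
#' One row per sample: time, the six compartment volumes, all pressures
#' (chambers, capacitances, aortic root, cavopulmonary node), valve, pump and
#' bed flows, and the two activation waveforms. Numeric values are written
#' with six significant digits so that repeated runs are byte-identical.
#'
#' @param sim A `fontan_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  stopifnot(inherits(sim, "fontan_sim"))
  out <- dplyr::mutate(sim$trajectory, dplyr::across(dplyr::everything(),
                                                     fmt6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a beat summary as JSON or CSV
#'
#' @param sim A `fontan_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(sim, path) {
  stopifnot(inherits(sim, "fontan_sim"))
  s <- as.list(beat_summary(sim))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
write_summary_csv <- function(sim, path) {
  stopifnot(inherits(sim, "fontan_sim"))
  out <- dplyr::mutate(beat_summary(sim),
                       dplyr::across(dplyr::everything(), fmt6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a scenario end to end and write its artefacts
#'
#' Builds the model from a scenario configuration (or file path), runs it to
#' periodic steady state, and writes the converged-beat trajectory CSV, the
#' beat-summary JSON and a run manifest into `out_dir`. The manifest records
#' the fully resolved parameter set and solver settings, so
#' [run_from_manifest()] reproduces the numeric outputs exactly.
#'
#' @param config A [scenario_config()] or the path of a scenario YAML file.
#' @param out_dir Output directory (created if needed).
#' @param steps_per_beat,tol,max_beats Solver settings, see
#'   [run_to_steady_state()].
#' @return The `fontan_sim` object, invisibly; artefact paths are in
#'   `attr(, "paths")`.
#' @export
run_scenario <- function(config, out_dir,
                         steps_per_beat = 4000, tol = 1e-6,
                         max_beats = 300) {
  if (is.character(config)) config <- load_scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- as_fontan_model(config)
  t0 <- proc.time()[["elapsed"]]
  sim <- run_to_steady_state(model, tol = tol, max_beats = max_beats,
                             steps_per_beat = steps_per_beat)
  wall <- proc.time()[["elapsed"]] - t0
  paths <- list(
    trajectory = file.path(out_dir, paste0(config$name, "_trajectory.csv")),
    summary = file.path(out_dir, paste0(config$name, "_summary.json")),
    manifest = file.path(out_dir, paste0(config$name, "_manifest.json"))
  )
  write_trajectory_csv(sim, paths$trajectory)
  write_summary_json(sim, paths$summary)
  pt <- parameter_table(model)
  manifest <- list(
    scenario = config$name,
    parameters = as.list(stats::setNames(pt$value, pt$parameter)),
    solver = list(steps_per_beat = steps_per_beat, tol = tol,
                  max_beats = max_beats),
    software_version = as.character(utils::packageVersion("fontansim")),
    wall_time_s = round(wall, 3),
    outputs = paths[c("trajectory", "summary")]
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = 15, pretty = TRUE)
  attr(sim, "paths") <- paths
  invisible(sim)
}

#' Re-run a simulation from its manifest
#'
#' Rebuilds the model from the fully resolved parameter set stored in a run
#' manifest and repeats the steady-state run with the recorded solver
#' settings; the numeric outputs are bit-identical to the original run.
#'
#' @param manifest_path Path of a `*_manifest.json` written by
#'   [run_scenario()].
#' @return A `fontan_sim` object.
#' @export
run_from_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  p <- man$parameters
  g <- function(key) as.numeric(p[[key]])
  ch <- function(prefix) chamber_params(
    E_es = g(paste0(prefix, ".E_es")), A = g(paste0(prefix, ".A")),
    B = g(paste0(prefix, ".B")), V0 = g(paste0(prefix, ".V0")),
    T_es = g(paste0(prefix, ".T_es")),
    activation_offset = g(paste0(prefix, ".activation_offset")))
  bed <- function(prefix) vascular_bed_params(
    R_c = g(paste0(prefix, ".R_c")), R_a = g(paste0(prefix, ".R_a")),
    R_v = g(paste0(prefix, ".R_v")), C_a = g(paste0(prefix, ".C_a")),
    C_v = g(paste0(prefix, ".C_v")))
  pump <- if (!is.null(p[["pump.K_A"]]))
    pump_params(K_A = g("pump.K_A"), K_B = g("pump.K_B"), K_C = g("pump.K_C"),
                rpm = g("pump.rpm"), enabled = g("pump.enabled") > 0)
  model <- fontan_model(
    sv = ch("sv"), sa = ch("sa"),
    valves = valve_params(
      R_AV = g("valves.R_AV"), R_AVV = g("valves.R_AVV"),
      R_AVVR = if (!is.null(p[["valves.R_AVVR"]])) g("valves.R_AVVR")),
    systemic = bed("systemic"), pulmonary = bed("pulmonary"),
    pump = pump, timing = timing_params(g("timing.heart_rate")),
    bsa = g("bsa"), stressed_blood_volume = g("stressed_blood_volume"))
  run_to_steady_state(model, tol = man$solver$tol,
                      max_beats = man$solver$max_beats,
                      steps_per_beat = man$solver$steps_per_beat)
}

ref_table <- function(which) {
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "fontansim")
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Reproduce the scenario-by-pump-speed results table
#'
#' For each failing-Fontan scenario: the unassisted baseline, the pump-speed
#' ramp 3000/3500/4000 rpm at the scenario's stressed blood volume (with
#' 100 mL up-titration at any speed where a per-beat minimum would fall below
#' zero, as in the high-PVR scenario), and the 100 mL down-titration at
#' 4000 rpm where the starting volume is feasible. Each row carries the
#' bundled reference values and `delta_*` columns (measured minus reference).
#'
#' @param scenarios Character vector naming the scenarios to run.
#' @param ... Passed to [run_to_steady_state()].
#' @return A tibble, one row per (scenario, condition).
#' @export
reproduce_table2 <- function(scenarios = c("systolic", "diastolic", "avvr",
                                           "high_pvr"), ...) {
  factories <- list(systolic = make_systolic_dysfunction,
                    diastolic = make_diastolic_dysfunction,
                    avvr = make_avvr,
                    high_pvr = make_high_pvr)
  scenarios <- match.arg(scenarios, names(factories), several.ok = TRUE)
  keep <- c("stressed_blood_volume", "rpm", "cardiac_index",
            "mean_arterial_pressure", "cvp", "mean_sa_pressure",
            "regurgitant_fraction")
  rows <- list()
  for (nm in scenarios) {
    model <- factories[[nm]]()
    base <- beat_summary(run_to_steady_state(model, ...))
    rows[[length(rows) + 1]] <- dplyr::mutate(
      base[keep], scenario = nm, condition = "baseline", .before = 1)
    up_titrated <- FALSE
    for (rpm in c(3000, 3500, 4000)) {
      m <- set_pump_speed(model, rpm)
      sim <- run_to_steady_state(m, ...)
      if (!feasible_minima(sim)) {
        tit <- titrate_sbv(m, step = 100, direction = "up", ...)
        model <- set_stressed_volume(model, tit$final_sbv)
        s <- tit$summary
        up_titrated <- TRUE
      } else {
        s <- beat_summary(sim)
      }
      rows[[length(rows) + 1]] <- dplyr::mutate(
        s[keep], scenario = nm, condition = sprintf("rpm%d", rpm),
        .before = 1)
    }
    if (!up_titrated) {
      tit <- titrate_sbv(set_pump_speed(model, 4000), step = 100,
                         direction = "down", ...)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        tit$summary[keep], scenario = nm, condition = "rpm4000_titrated",
        .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  ref <- ref_table("table2")
  out <- dplyr::left_join(out, ref, by = c("scenario", "condition"),
                          suffix = c("", "_ref"))
  add_deltas(out, setdiff(keep, "rpm"))
}

#' Reproduce the pulmonary-resistance sweep table
#'
#' Runs [sweep_pvri()] at full 1 mL resolution and joins the bundled
#' reference values with `delta_*` columns.
#'
#' @param resolution Titration resolution, mL.
#' @param ... Passed to [sweep_pvri()].
#' @return A tibble, one row per PVRI value.
#' @export
reproduce_table3 <- function(resolution = 1, ...) {
  out <- sweep_pvri(resolution = resolution, ...)
  keep <- c("pvri", "R_ap", "stressed_blood_volume", "cardiac_index",
            "mean_arterial_pressure", "cvp", "mean_sa_pressure")
  out <- out[keep]
  ref <- ref_table("table3")
  out <- dplyr::left_join(out, ref, by = "R_ap", suffix = c("", "_ref"))
  add_deltas(out, setdiff(keep, "R_ap"))
}

add_deltas <- function(df, cols) {
  for (cl in cols) {
    refcol <- paste0(cl, "_ref")
    if (refcol %in% names(df))
      df[[paste0("delta_", cl)]] <- df[[cl]] - df[[refcol]]
  }
  df
}
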