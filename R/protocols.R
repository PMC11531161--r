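#' Pump-speed ramp at fixed stressed blood volume
#'
#' Runs the model to periodic steady state at each pump speed in turn,
#' warm-starting each run from the previous converged state, and collects the
#' beat-averaged summaries. The total stressed blood volume is held fixed.
#'
#' @param model A [fontan_model()] with a pump attached.
#' @param rpm_schedule Numeric vector of pump speeds, rpm.
#' @param ... Passed to [run_to_steady_state()].
#' @return A tibble with one row per speed (the [beat_summary()] columns).
#' @examples
#' \donttest{
#' ramp_rpm(make_systolic_dysfunction(), c(3000, 3500, 4000))
#' }
#' @export
ramp_rpm <- function(model, rpm_schedule, ...) {
  stopifnot(inherits(model, "fontan_model"), length(rpm_schedule) >= 1)
  if (is.null(model$pump))
    stop("`model` has no pump attached", call. = FALSE)
  init <- initial_state(model)
  rows <- vector("list", length(rpm_schedule))
  for (i in seq_along(rpm_schedule)) {
    rpm <- rpm_schedule[i]
    ss <- tryCatch(
      run_to_steady_state(set_pump_speed(model, rpm), init = init, ...),
      error = function(e)
        stop(sprintf("ramp failed at %g rpm: %s", rpm, conditionMessage(e)),
             call. = FALSE))
    rows[[i]] <- beat_summary(ss)
    init <- ss$final_state
  }
  dplyr::bind_rows(rows)
}

# Change total stressed volume by delta, applied to the systemic venous
# capacitance of a warm-start state (the protocol's injection/withdrawal
# site). Falls back to the cold initial split when no state is given.
shift_state <- function(model, state, delta) {
  model <- set_stressed_volume(model, model$stressed_blood_volume + delta)
  if (is.null(state)) return(list(model = model, init = initial_state(model)))
  state[["V_Cvs"]] <- state[["V_Cvs"]] + delta
  if (state[["V_Cvs"]] < 0)
    stop("systemic venous capacitance volume exhausted during titration",
         call. = FALSE)
  list(model = model, init = state)
}

#' Stressed-blood-volume titration
#'
#' Steps the total stressed blood volume `V_s` by `step` mL at a time
#' (applied to the systemic venous capacitance), re-running to periodic
#' steady state after each step.
#'
#' Direction `"down"` withdraws volume while the circulation stays feasible —
#' no per-beat minimum chamber pressure or compartment volume below zero —
#' and stops at the last feasible `V_s` (the mean atrial pressure is then the
#' smallest non-negative value reachable in whole steps). Direction `"up"`
#' stops at the first `V_s` at which all per-beat minima are non-negative;
#' a model that is already feasible returns `delta_sbv = 0`.
#'
#' @param model A [fontan_model()].
#' @param step Titration step, mL (`> 0`).
#' @param direction `"down"` or `"up"`.
#' @param max_sbv,min_sbv Bounds on `V_s`, mL; hitting one raises an error.
#' @param ... Passed to [run_to_steady_state()].
#' @return An object of class `fontan_titration`: a list with `steps` (tibble
#'   of one [beat_summary()] row per tried volume plus a `feasible` column),
#'   `final_sbv`, `delta_sbv`, `stop_reason` (`"min-below-zero-guard"`,
#'   `"mean-pressure-near-zero"` or `"bound-reached"` is an error), and the
#'   final converged summary row.
#' @examples
#' \donttest{
#' titrate_sbv(set_pump_speed(make_systolic_dysfunction(), 4000),
#'             step = 100, direction = "down")
#' }
#' @export
titrate_sbv <- function(model, step = 100, direction = c("down", "up"),
                        max_sbv = 5000, min_sbv = 0, ...) {
  stopifnot(inherits(model, "fontan_model"), step > 0)
  direction <- match.arg(direction)
  sbv0 <- model$stressed_blood_volume

  run_at <- function(mod, init) run_to_steady_state(mod, init = init, ...)

  ss <- run_at(model, NULL)
  rows <- list(dplyr::mutate(beat_summary(ss), feasible = feasible_minima(ss)))
  state <- ss$final_state
  cur <- list(model = model, sim = ss)

  if (direction == "up") {
    stop_reason <- "min-below-zero-guard"
    while (!feasible_minima(cur$sim)) {
      if (cur$model$stressed_blood_volume + step > max_sbv)
        stop("titration bound reached: V_s would exceed ", max_sbv, " mL",
             call. = FALSE)
      nxt <- shift_state(cur$model, state, +step)
      sim <- run_at(nxt$model, nxt$init)
      rows <- c(rows, list(dplyr::mutate(beat_summary(sim),
                                         feasible = feasible_minima(sim))))
      state <- sim$final_state
      cur <- list(model = nxt$model, sim = sim)
    }
  } else {
    if (!feasible_minima(cur$sim))
      stop("model is infeasible at its starting V_s; down-titration ",
           "requires a feasible start (consider direction = \"up\")",
           call. = FALSE)
    stop_reason <- "min-below-zero-guard"
    repeat {
      if (cur$model$stressed_blood_volume - step < min_sbv)
        stop("titration bound reached: V_s would fall below ", min_sbv,
             " mL", call. = FALSE)
      nxt <- shift_state(cur$model, state, -step)
      sim <- run_at(nxt$model, nxt$init)
      ok <- feasible_minima(sim)
      rows <- c(rows, list(dplyr::mutate(beat_summary(sim), feasible = ok)))
      if (!ok) break
      state <- sim$final_state
      cur <- list(model = nxt$model, sim = sim)
      if (beat_summary(sim)$mean_sa_pressure <= 0) {
        stop_reason <- "mean-pressure-near-zero"
        break
      }
    }
  }

  final_sbv <- cur$model$stressed_blood_volume
  structure(
    list(steps = dplyr::bind_rows(rows),
         final_sbv = final_sbv,
         delta_sbv = final_sbv - sbv0,
         stop_reason = stop_reason,
         summary = beat_summary(cur$sim),
         model = cur$model),
    class = "fontan_titration"
  )
}

#' @export
print.fontan_titration <- function(x, ...) {
  cat("<fontan_titration>\n")
  cat(sprintf("  V_s %g mL (delta %+g mL), stop: %s\n", x$final_sbv,
              x$delta_sbv, x$stop_reason))
  s <- x$summary
  cat(sprintf("  CI %.2f | MAP %.1f | CVP %.1f | SA %.2f mmHg\n",
              s$cardiac_index, s$mean_arterial_pressure, s$cvp,
              s$mean_sa_pressure))
  invisible(x)
}

#' @export
tidy.fontan_titration <- function(x, ...) x$steps

#' @export
glance.fontan_titration <- function(x, ...) {
  dplyr::mutate(x$summary, delta_sbv = x$delta_sbv,
                stop_reason = x$stop_reason)
}

# Smallest whole-mL V_s at which all per-beat minima are non-negative.
# Feasibility is monotone in V_s here (more stressed volume raises every
# compartment's working pressures), so binary search on integers gives the
# same answer as 1 mL stepping with far fewer steady-state solves; the
# resolution-1 verification below re-checks both sides of the boundary.
find_min_feasible_sbv <- function(model, lo, hi, resolution = 1,
                                  verify = TRUE, ...) {
  run_feasible <- function(sbv) {
    m <- set_stressed_volume(model, sbv)
    sim <- run_to_steady_state(m, ...)
    list(ok = feasible_minima(sim), sim = sim)
  }
  r_hi <- run_feasible(hi)
  if (!r_hi$ok) stop("upper bracket ", hi, " mL is infeasible", call. = FALSE)
  r_lo <- run_feasible(lo)
  if (r_lo$ok) stop("lower bracket ", lo, " mL is already feasible",
                    call. = FALSE)
  best <- r_hi
  while (hi - lo > resolution) {
    mid <- lo + floor((hi - lo) / 2 / resolution) * resolution
    if (mid <= lo) break
    r <- run_feasible(mid)
    if (r$ok) {
      hi <- mid
      best <- r
    } else {
      lo <- mid
    }
  }
  if (verify) {
    stopifnot(!run_feasible(hi - resolution)$ok)
  }
  list(sbv = hi, sim = best$sim)
}

#' Pulmonary vascular resistance sweep under ventricular assist
#'
#' For each pulmonary arterial resistance value, finds the smallest stressed
#' blood volume (at the given resolution, default 1 mL) for which no per-beat
#' minimum chamber pressure or compartment volume falls below zero — the
#' volume at which the mean atrial pressure sits just above zero — and
#' records the steady-state hemodynamics there. The search is a bisection
#' over whole millilitres with a verification of both sides of the boundary,
#' equivalent to 1 mL stepping; set `resolution` coarser for quick looks.
#'
#' @param model Base model, typically [make_pvri_sweep_base()].
#' @param R_ap_values Pulmonary arterial resistances to sweep, mmHg s/mL.
#' @param rpm Pump speed, rpm.
#' @param resolution Titration resolution, mL.
#' @param sbv_bracket Initial volume bracket `c(lo, hi)`, mL.
#' @param ... Passed to [run_to_steady_state()].
#' @return A tibble with one row per resistance: `pvri`, `R_ap`,
#'   `stressed_blood_volume`, and the [beat_summary()] hemodynamics.
#' @examples
#' \donttest{
#' sweep_pvri(R_ap_values = c(0.06, 0.125), resolution = 10)
#' }
#' @export
sweep_pvri <- function(model = make_pvri_sweep_base(),
                       R_ap_values = c(0.06, 0.09, 0.125, 0.155, 0.185,
                                       0.22, 0.25),
                       rpm = 3500, resolution = 1,
                       sbv_bracket = c(300, 3000), ...) {
  stopifnot(inherits(model, "fontan_model"))
  model <- set_pump_speed(model, rpm)
  lo <- sbv_bracket[1]
  rows <- vector("list", length(R_ap_values))
  for (i in seq_along(R_ap_values)) {
    m <- model
    m$pulmonary$R_a <- R_ap_values[i]
    found <- find_min_feasible_sbv(m, lo = lo, hi = sbv_bracket[2],
                                   resolution = resolution, ...)
    s <- beat_summary(found$sim)
    rows[[i]] <- dplyr::mutate(
      s,
      pvri = pvri_from_resistances(R_ap_values[i], m$pulmonary$R_c,
                                   m$pulmonary$R_v, m$bsa),
      R_ap = R_ap_values[i],
      .before = 1)
    # required volume grows with resistance: reuse as the next lower bound
    lo <- max(sbv_bracket[1], found$sbv - 2 * resolution - 200)
  }
  dplyr::bind_rows(rows)
}

#' PVRI at which the venous pressure crosses a tolerance limit
#'
#' Linear interpolation of the central venous pressure over the swept PVRI
#' values; CVP increases monotonically with pulmonary resistance, so the
#' crossing is unique.
#'
#' @param rows A tibble from [sweep_pvri()] (columns `pvri`, `cvp`).
#' @param cvp_limit Acceptable central venous pressure, mmHg.
#' @return The interpolated PVRI, Wood units m^2.
#' @examples
#' rows <- tibble::tibble(pvri = c(3, 6), cvp = c(10, 20))
#' cvp_vs_pvri_threshold(rows, 15)
#' @export
cvp_vs_pvri_threshold <- function(rows, cvp_limit) {
  stopifnot(nrow(rows) >= 2, all(c("pvri", "cvp") %in% names(rows)))
  rows <- dplyr::arrange(rows, .data$pvri)
  if (is.unsorted(rows$cvp))
    stop("`cvp` must be monotone in `pvri`", call. = FALSE)
  if (cvp_limit < min(rows$cvp) || cvp_limit > max(rows$cvp))
    stop(sprintf("cvp_limit %.3g mmHg outside the swept range [%.3g, %.3g]",
                 cvp_limit, min(rows$cvp), max(rows$cvp)), call. = FALSE)
  stats::approx(rows$cvp, rows$pvri, xout = cvp_limit, ties = "ordered")$y
}
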