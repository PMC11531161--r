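#' Plot a simulated beat
#'
#' `autoplot()` renders the recorded trajectory of a simulation: chamber and
#' arterial pressures over time (`"pressures"`), the six compartment volumes
#' (`"volumes"`), or the ventricular/atrial pressure-volume loops
#' (`"pv_loop"`).
#'
#' @param object A `fontan_sim` object.
#' @param type One of `"pressures"`, `"volumes"`, `"pv_loop"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
#' @method autoplot fontan_sim
autoplot.fontan_sim <- function(object,
                                type = c("pressures", "volumes", "pv_loop"),
                                ...) {
  type <- match.arg(type)
  tr <- object$trajectory
  if (type == "pv_loop") return(plot_pv_loop(object))
  cols <- switch(type,
    pressures = c("P_SA", "P_SV", "P_Cas", "P_ao", "CVP"),
    volumes = c("V_SA", "V_SV", "V_Cas", "V_Cvs", "V_Cap", "V_Cvp"))
  long <- tidyr::pivot_longer(tr[c("time", cols)], -"time",
                              names_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = if (type == "pressures") "pressure (mmHg)"
                      else "volume (mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pressure-volume loop of one chamber
#'
#' @param sim A `fontan_sim` object (ideally a converged beat, so the loop
#'   closes).
#' @param chamber `"sv"` (ventricle) or `"sa"` (atrium).
#' @return A ggplot object.
#' @export
plot_pv_loop <- function(sim, chamber = c("sv", "sa")) {
  chamber <- match.arg(chamber)
  tr <- sim$trajectory
  v <- if (chamber == "sv") "V_SV" else "V_SA"
  p <- if (chamber == "sv") "P_SV" else "P_SA"
  ggplot2::ggplot(tr, ggplot2::aes(.data[[v]], .data[[p]])) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "volume (mL)", y = "pressure (mmHg)",
                  title = if (chamber == "sv") "single ventricle"
                          else "single atrium") +
    ggplot2::theme_minimal()
}

#' Central venous pressure against pulmonary resistance index
#'
#' The congestion curve of the assisted Fontan circulation: CVP rises
#' steeply with PVRI. An optional horizontal tolerance line marks the
#' acceptable-CVP limit whose crossing [cvp_vs_pvri_threshold()] computes.
#'
#' @param rows A tibble from [sweep_pvri()].
#' @param cvp_limit Optional CVP limit to mark, mmHg.
#' @return A ggplot object.
#' @export
plot_cvp_vs_pvri <- function(rows, cvp_limit = NULL) {
  gg <- ggplot2::ggplot(rows, ggplot2::aes(.data$pvri, .data$cvp)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PVRI (Wood units m²)",
                  y = "central venous pressure (mmHg)") +
    ggplot2::theme_minimal()
  if (!is.null(cvp_limit))
    gg <- gg + ggplot2::geom_hline(yintercept = cvp_limit,
                                   linetype = "dashed")
  gg
}

#' Cardiac index against central venous pressure
#'
#' One marker per simulated condition, optionally grouped by a `scenario`
#' column — the standard display of how assist moves each pathophysiology in
#' the CI/CVP plane.
#'
#' @param summaries A tibble of beat summaries (columns `cardiac_index`,
#'   `cvp`, optionally `scenario`).
#' @return A ggplot object.
#' @export
plot_ci_vs_cvp <- function(summaries) {
  aes <- if ("scenario" %in% names(summaries))
    ggplot2::aes(.data$cvp, .data$cardiac_index, colour = .data$scenario)
  else ggplot2::aes(.data$cvp, .data$cardiac_index)
  ggplot2::ggplot(summaries, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "central venous pressure (mmHg)",
                  y = "cardiac index (L/min/m²)") +
    ggplot2::theme_minimal()
}
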