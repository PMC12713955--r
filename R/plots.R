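#' Plot a melatonin profile and its DLMO estimate
#'
#' Sampled concentrations with the piecewise-linear interpolant, the
#' threshold line, and (when estimated) the DLMO crossing.
#'
#' @param melatonin Melatonin tibble for one subject (`noon_min`,
#'   `concentration_pg_ml`).
#' @param estimate Optional result of [estimate_dlmo()].
#' @param threshold Threshold line (pg/mL).
#' @return A ggplot object.
#' @export
plot_melatonin_profile <- function(melatonin, estimate = NULL, threshold = 4) {
  p <- ggplot2::ggplot(melatonin,
                       ggplot2::aes(x = .data$noon_min,
                                    y = .data$concentration_pg_ml)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_continuous(
      labels = function(x) noon_to_clock(x)) +
    ggplot2::labs(x = "clock time", y = "melatonin (pg/mL)",
                  title = "Salivary melatonin profile")
  if (!is.null(estimate) && estimate$status == "ok") {
    p <- p + ggplot2::geom_vline(xintercept = estimate$dlmo,
                                 colour = "firebrick") +
      ggplot2::annotate("text", x = estimate$dlmo,
                        y = max(melatonin$concentration_pg_ml),
                        label = paste0("DLMO ", estimate$dlmo_clock),
                        hjust = -0.1, colour = "firebrick")
  }
  p
}

#' Plot one night of scored activity
#'
#' Minute counts coloured by Sadeh sleep/wake label, with detected onset and
#' offset marked.
#'
#' @param scored Tibble `noon_min`, `count`, `label` (e.g. the window minutes
#'   with [sadeh_scores()] applied).
#' @param period Optional list with `onset`/`offset` from
#'   [detect_sleep_period()].
#' @return A ggplot object.
#' @export
plot_activity_trace <- function(scored, period = NULL) {
  p <- ggplot2::ggplot(scored,
                       ggplot2::aes(x = .data$noon_min, y = .data$count,
                                    colour = .data$label)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_colour_manual(values = c(sleep = "steelblue",
                                            wake = "darkorange")) +
    ggplot2::scale_x_continuous(labels = function(x) noon_to_clock(x)) +
    ggplot2::labs(x = "clock time", y = "activity counts/min",
                  colour = NULL, title = "Sadeh-scored activity")
  if (!is.null(period)) {
    p <- p + ggplot2::geom_vline(xintercept = c(period$onset, period$offset),
                                 linetype = "dotted")
  }
  p
}

#' Effect-size overview of the comparison grid
#'
#' Dot plot of partial eta squared for every grouping x outcome cell, with
#' the small/medium/large benchmarks.
#'
#' @param object A `circ_comparisons` tibble from [run_all_comparisons()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circ_comparisons
#' @export
autoplot.circ_comparisons <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$eta_p2, y = .data$outcome,
                                  colour = .data$interpret)) +
    ggplot2::geom_vline(xintercept = c(0.01, 0.06, 0.14),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~grouping) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = expression(partial~eta^2), y = NULL,
                  title = "Circadian group effects on mental-health outcomes")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
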