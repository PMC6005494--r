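# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.bifurcation_diagram <- function(x, ...) x$points

#' @export
glance.bifurcation_diagram <- function(x, ...) {
  tibble::tibble(sn_location = x$sn_location,
                 n_branches = dplyr::n_distinct(x$points$branch),
                 input_min = x$input_range[1], input_max = x$input_range[2])
}

#' @export
tidy.transition_path <- function(x, ...) x$points

#' @export
glance.transition_path <- function(x, ...) {
  tibble::tibble(total_action = x$total_action, barrier = x$barrier,
                 converged = x$converged, iterations = x$iterations,
                 n_points = nrow(x$points))
}

#' @export
tidy.fpt_ensemble <- function(x, ...) x$samples

#' @export
glance.fpt_ensemble <- function(x, ...) {
  tibble::tibble(mfpt = x$mfpt, sd = x$sd, cv = x$cv, se = x$se,
                 n_runs = x$n_runs, n_censored = x$n_censored,
                 threshold_count = x$threshold_count,
                 threshold_fraction = x$threshold_fraction,
                 omega = x$omega, input_value = x$input_value)
}

#' @export
tidy.sensitivity_spectrum <- function(x, ...) x$entries

#' @export
glance.sensitivity_spectrum <- function(x, ...) {
  tibble::tibble(output_kind = x$output_kind, baseline = x$baseline,
                 delta = x$delta, n_parameters = nrow(x$entries),
                 n_flagged = sum(!x$entries$ok))
}

#' @export
tidy.sobol_spectrum <- function(x, ...) x$entries

#' @export
glance.sobol_spectrum <- function(x, ...) {
  tibble::tibble(n_base = x$n_base, n_drawn = x$n_drawn,
                 acceptance = x$n_base / x$n_drawn, variance = x$variance)
}

#' @export
tidy.arrhenius_fit <- function(x, ...) x$by_size

#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = summary(x$fit)$r.squared,
                 n_sizes = nrow(x$by_size))
}

#' @export
tidy.landscape_profile <- function(x, ...) x$profile

#' Plot a bifurcation diagram
#' @param object A `bifurcation_diagram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$input_value,
                                         y = .data$output_level,
                                         group = .data$branch,
                                         linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(stable = "solid", saddle = "dashed", unstable = "dotted")) +
    ggplot2::labs(x = object$input_parameter,
                  y = paste(object$output_species, "(nM)"),
                  linetype = NULL)
  if (!is.na(object$sn_location)) {
    p <- p + ggplot2::geom_vline(xintercept = object$sn_location,
                                 linetype = "dotdash", colour = "grey40")
  }
  p
}

#' Plot cumulative action along a transition path
#' @param object A `transition_path`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.transition_path <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$arc_position,
                               y = .data$cumulative_action)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$barrier, linetype = "dashed") +
    ggplot2::labs(x = "normalised arc length", y = "cumulative action S")
}

#' Plot a two-well quasi-potential profile
#' @param object A `landscape_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.landscape_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$coordinate, y = .data$action,
                               colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (object$log_coordinate) "log10 output (nM)" else "output (nM)",
      y = "quasi-potential S", colour = NULL)
}

#' Plot a sensitivity spectrum as paired bars
#' @param object A `sensitivity_spectrum`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sensitivity_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(object$entries[object$entries$ok, ],
                              cols = c("pct_up", "pct_down"),
                              names_to = "direction", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$parameter, -abs(.data$pct)),
    y = .data$pct, fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL,
                  y = sprintf("%% change of %s", object$output_kind),
                  fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot Sobol total-effect indices with bootstrap CIs
#' @param object A `sobol_spectrum`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sobol_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$entries, ggplot2::aes(
    x = stats::reorder(.data$parameter, -.data$total_effect),
    y = .data$total_effect)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$total_lo,
                                        ymax = .data$total_hi), width = 0.3) +
    ggplot2::labs(x = NULL, y = "total-effect index") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot first-passage-time distribution
#' @param object An `fpt_ensemble`.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fpt_ensemble <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$samples[!object$samples$censored, ],
                  ggplot2::aes(x = .data$fpt)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = object$mfpt, linetype = "dashed") +
    ggplot2::labs(x = "first-passage time", y = "count")
}

#' @importFrom rlang .data
NULL
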