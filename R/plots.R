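#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_col
#'   geom_hline geom_rect labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a symptom trace
#' @param object A `symptom_trace`.
#' @param ... Unused.
#' @return A ggplot: score over time with the dichotomization cutoff and
#'   high-state shading.
#' @export
autoplot.symptom_trace <- function(object, ...) {
  cutoff <- trace_cutoff(object)
  ggplot(as_tibble(object), aes(x = .data$time, y = .data$score)) +
    geom_line(colour = "grey30") +
    geom_hline(yintercept = cutoff, linetype = "dashed", colour = "red") +
    geom_step(aes(y = .data$state * 10), colour = "steelblue",
              alpha = 0.5) +
    labs(x = "time (s)", y = "pain score (0-10)",
         title = "Symptom trace",
         subtitle = sprintf("cutoff %.1f; blue step: dichotomized state (x10)",
                            cutoff)) +
    theme_minimal()
}

#' Plot an LFP recording
#' @param object An `lfp_recording`.
#' @param max_seconds Plot at most this many seconds (default 10).
#' @param ... Unused.
#' @return A ggplot with one facet per channel.
#' @export
autoplot.lfp_recording <- function(object, max_seconds = 10, ...) {
  df <- dplyr::filter(as_tibble(object),
                      .data$time <= min(.data$time) + max_seconds)
  long <- tidyr::pivot_longer(df, -"time", names_to = "channel",
                              values_to = "uV")
  ggplot(long, aes(x = .data$time, y = .data$uV)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "LFP (uV)") +
    theme_minimal()
}

#' Plot a band-power feature stream
#' @param object A `feature_stream`.
#' @param ... Unused.
#' @return A ggplot faceted by (channel, band) feature.
#' @export
autoplot.feature_stream <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "feature", values_to = "power")
  ggplot(long, aes(x = .data$time, y = .data$power)) +
    geom_line(colour = "grey30") +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = "time (s)", y = "band power (uV^2)") +
    theme_minimal()
}

#' Plot feature importances
#' @param object A `feature_ranking`.
#' @param ... Unused.
#' @return A ggplot bar chart of |correlation| per feature.
#' @export
autoplot.feature_ranking <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      feature = factor(.data$feature,
                                       levels = rev(.data$feature)))
  ggplot(df, aes(x = .data$importance, y = .data$feature)) +
    geom_col(fill = "steelblue") +
    labs(x = "|correlation| with symptom score", y = NULL,
         title = "Feature importance") +
    theme_minimal()
}

#' Plot an LD stream with its thresholds
#' @param object An `ld_stream`.
#' @param ... Unused.
#' @return A ggplot of the LD value over time; attached thresholds are
#'   drawn as dashed lines.
#' @export
autoplot.ld_stream <- function(object, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$time, y = .data$ld)) +
    geom_line(colour = "purple4") +
    labs(x = "time (s)", y = "LD output") +
    theme_minimal()
  thr <- attr(object, "thresholds", exact = TRUE)
  if (!is.null(thr)) {
    p <- p + geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "red")
  }
  p
}

#' Plot a detector state trace
#' @param object A `state_trace`.
#' @param ... Unused.
#' @return A ggplot step plot of the detector state.
#' @export
autoplot.state_trace <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time, y = .data$state)) +
    geom_step(colour = "darkgreen") +
    labs(x = "time (s)", y = "detector state") +
    theme_minimal()
}

#' Plot a closed-loop run
#' @param object A `closed_loop_trace`.
#' @param ... Unused.
#' @return A ggplot with stacked facets: LD, detector state, effective
#'   amplitude and modeled score.
#' @export
autoplot.closed_loop_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "time", "ld", "state", "amp_eff",
                  "score"),
    -"time", names_to = "series", values_to = "value")
  long$series <- factor(long$series,
                        levels = c("ld", "state", "amp_eff", "score"),
                        labels = c("LD output", "detector state",
                                   "amplitude (mA)", "pain score"))
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(colour = "grey20") +
    facet_wrap(~series, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL, title = "Closed-loop run") +
    theme_minimal()
}

#' Plot an LD histogram with candidate thresholds
#' @param object A `threshold_report`.
#' @param ... Unused.
#' @return A ggplot of the binned LD counts (the programming-session
#'   histogram) with the selected percentile thresholds.
#' @export
autoplot.threshold_report <- function(object, ...) {
  ggplot(object$histogram) +
    geom_rect(aes(xmin = .data$lower, xmax = .data$upper, ymin = 0,
                  ymax = .data$count), fill = "grey60") +
    geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = unname(object$thresholds),
                        colour = "red", linetype = "dashed") +
    labs(x = "LD output", y = "count",
         title = "LD distribution and percentile thresholds") +
    theme_minimal()
}

#' Plot a wash-in/wash-out test
#' @param object A `washout_fit`.
#' @param ... Unused.
#' @return A ggplot of the simulated reports with the fitted exponentials
#'   and step times.
#' @export
autoplot.washout_fit <- function(object, ...) {
  df <- object$data
  pred <- dplyr::bind_rows(
    if (!is.null(object$fit_in)) {
      seg <- df[df$time > object$t_on & df$time < object$t_off, ]
      tibble(time = seg$time, score = predict(object$fit_in))
    },
    if (!is.null(object$fit_out)) {
      seg <- df[df$time > object$t_off, ]
      tibble(time = seg$time, score = predict(object$fit_out))
    })
  ggplot(df, aes(x = .data$time, y = .data$score)) +
    geom_line(colour = "grey60") +
    geom_line(data = pred, colour = "red") +
    ggplot2::geom_vline(xintercept = c(object$t_on, object$t_off),
                        linetype = "dashed") +
    labs(x = "time (s)", y = "pain score",
         title = sprintf("Wash-in/wash-out: tau_in %.3g s, tau_out %.3g s",
                         object$tau_in, object$tau_out)) +
    theme_minimal()
}
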