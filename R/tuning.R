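#' Percentile-based threshold selection
#'
#' The data-driven threshold heuristic: collect a long stretch of LD
#' output, take its empirical distribution, and place the threshold(s) at
#' chosen percentiles. The threshold percentile is inversely related to
#' how often stimulation triggers: a threshold at the 50th percentile
#' should leave future LD values above and below it about half the time
#' each.
#'
#' @param ld An `ld_stream`, tibble with an `ld` column, or numeric LD
#'   vector of at least 100 updates.
#' @param percentiles Strictly increasing percentiles in (0, 100]
#'   (1 or 2 values for a device configuration).
#' @param n_bins Histogram bins for the report.
#' @return A `threshold_report` list: `thresholds` (named by percentile),
#'   `histogram` (bin edges + counts), `reference` (25/50/75th
#'   percentiles), `predicted_duty` (1 - p/100 per candidate, the expected
#'   above-threshold occupancy for counters of 1), and the percentile
#'   `convention` used (linear interpolation between order statistics,
#'   R quantile type 7).
#' @export
select_threshold <- function(ld, percentiles = 50, n_bins = 50) {
  vals <- if (is.data.frame(ld)) ld$ld else ld
  if (length(vals) < 100) {
    abort("at least 100 LD updates are needed for threshold selection")
  }
  if (!length(percentiles) || any(percentiles <= 0) ||
      any(percentiles > 100)) {
    abort("percentiles must lie in (0, 100]")
  }
  if (is.unsorted(percentiles, strictly = TRUE)) {
    abort("percentiles must be strictly increasing")
  }
  thr <- quantile(vals, percentiles / 100, type = 7, names = FALSE)
  h <- graphics::hist(vals, breaks = n_bins, plot = FALSE)
  structure(list(
    thresholds = setNames(thr, paste0("p", percentiles)),
    percentiles = percentiles,
    histogram = tibble(lower = head(h$breaks, -1),
                       upper = tail(h$breaks, -1), count = h$counts),
    reference = tibble(percentile = c(25, 50, 75),
                       ld = quantile(vals, c(0.25, 0.5, 0.75), type = 7,
                                     names = FALSE)),
    predicted_duty = tibble(percentile = percentiles, threshold = thr,
                            predicted_above = 1 - percentiles / 100),
    convention = "linear interpolation between order statistics (quantile type 7)",
    n = length(vals)),
    class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report> n =", x$n, "updates;", x$convention, "\n")
  print(x$predicted_duty)
  invisible(x)
}

#' Score detector output against the symptom state
#'
#' Compares the (binarized) detector state with the dichotomized symptom
#' state on the update grid, after previous-value-hold resampling of the
#' symptom trace. Latency is the lag, within `lag_window` updates either
#' side, at which shifting the detector maximizes agreement (positive =
#' detector lags the symptom); ties take the median qualifying lag.
#'
#' @param states A `state_trace` (states > 0 count as "detected").
#' @param trace A `symptom_trace` overlapping it in time.
#' @param lag_window Half-width of the latency search, in updates.
#' @return One-row tibble: `agreement`, `sensitivity`,
#'   `false_positive_rate`, `latency` (s), `latency_updates`.
#' @export
evaluate_detection <- function(states, trace, lag_window = 10) {
  if (min(trace$time) > max(states$time) ||
      max(trace$time) < min(states$time)) {
    abort("state trace and symptom trace do not overlap in time")
  }
  det <- as.integer(states$state > 0)
  sym <- as.integer(hold_resample(trace$time, trace$state, states$time) > 0)
  n <- length(det)
  dt <- if (n > 1) diff(states$time[1:2]) else 1
  agreement <- mean(det == sym)
  sensitivity <- if (any(sym == 1)) mean(det[sym == 1] == 1) else NA_real_
  fpr <- if (any(sym == 0)) mean(det[sym == 0] == 1) else NA_real_
  lags <- -lag_window:lag_window
  lag_agree <- vapply(lags, function(l) {
    if (l >= 0) {
      idx_d <- (1 + l):n; idx_s <- 1:(n - l)
    } else {
      idx_d <- 1:(n + l); idx_s <- (1 - l):n
    }
    if (!length(idx_d)) return(NA_real_)
    mean(det[idx_d] == sym[idx_s])
  }, numeric(1))
  best <- lags[which(lag_agree == max(lag_agree, na.rm = TRUE))]
  latency_updates <- median(best)
  tibble(agreement = agreement, sensitivity = sensitivity,
         false_positive_rate = fpr,
         latency = latency_updates * dt, latency_updates = latency_updates)
}

#' Grid search over closed-loop control parameters
#'
#' The systematic exploration clinicians perform when first programming a
#' device: every combination of candidate onset/termination counters,
#' blanking, threshold percentile and ramp rate is simulated with common
#' random numbers, scored by a weighted sum of disagreement, normalized
#' energy and a lock penalty, and the best cell is returned. Percentiles
#' are converted to LD thresholds using an open-loop (0 mA) calibration
#' run of the same scenario and seed.
#'
#' @param scenario A scenario argument list as produced by
#'   [high_snr_scenario()] (anything accepted by
#'   [simulate_closed_loop()]).
#' @param grid Named list of candidate vectors; recognized names:
#'   `onset`, `termination`, `blanking` (s), `percentile`, `ramp` (s).
#' @param objective_weights Named weights for `agreement` (applied to
#'   1 - agreement), `energy` (applied to energy normalized by the grid
#'   maximum) and `lock` (hard penalty per locked cell).
#' @param seed Seed shared by every cell (common random numbers).
#' @param lock_max_dwell Dwell defining a lock (default: half the
#'   scenario duration).
#' @param cap Maximum number of grid cells (default 500).
#' @return A `grid_search_result`; see [tidy.grid_search_result()] and
#'   [glance.grid_search_result()]. The chosen cell minimizes the
#'   scalarized objective (ties: first in grid order).
#' @export
grid_search <- function(scenario, grid,
                        objective_weights = c(agreement = 1, energy = 0.2,
                                              lock = 100),
                        seed = 1, lock_max_dwell = NULL, cap = 500) {
  if (!length(grid)) abort("empty grid")
  known <- c("onset", "termination", "blanking", "percentile", "ramp")
  if (!all(names(grid) %in% known)) {
    abort(paste("unknown grid axes:",
                paste(setdiff(names(grid), known), collapse = ", ")))
  }
  cells <- do.call(tidyr::expand_grid, grid)
  if (nrow(cells) > cap) {
    abort(sprintf("grid has %d cells, exceeding the cap of %d",
                  nrow(cells), cap))
  }
  lock_max_dwell <- lock_max_dwell %||% (scenario$duration / 2)
  # open-loop calibration for percentile -> threshold conversion
  thr_lookup <- NULL
  if ("percentile" %in% names(cells)) {
    open <- scenario
    open$stim <- stim_config(rep(0, length(open$stim$amplitudes)),
                             ramp = open$stim$ramp,
                             frequency = open$stim$frequency,
                             pulse_width = open$stim$pulse_width)
    ol <- do.call(simulate_closed_loop, c(open, list(seed = seed)))
    pcts <- sort(unique(cells$percentile))
    rep_thr <- select_threshold(ol$ld, percentiles = pcts)
    thr_lookup <- setNames(rep_thr$thresholds, pcts)
  }
  run_cell <- function(cell_row) {
    cell <- as.list(cell_row)
    scn <- scenario
    det <- scn$detector
    if (!is.null(cell[["onset"]])) det$onset <- as.integer(cell[["onset"]])
    if (!is.null(cell[["termination"]])) {
      det$termination <- as.integer(cell[["termination"]])
    }
    if (!is.null(cell[["blanking"]])) {
      det$blank_updates <- as.integer(
        ceiling(cell[["blanking"]] / det$update_interval - 1e-9))
      det$blanking <- cell[["blanking"]]
    }
    if (!is.null(cell[["percentile"]])) {
      det$thresholds[1] <- thr_lookup[[as.character(cell[["percentile"]])]]
    }
    scn$detector <- det
    if (!is.null(cell[["ramp"]])) {
      scn$stim$ramp <- rep_len(cell[["ramp"]], length(scn$stim$ramp))
    }
    clt <- do.call(simulate_closed_loop, c(scn, list(seed = seed)))
    ev <- evaluate_detection(as_state_trace(clt), as_symptom_trace(clt))
    en <- energy_delivered(clt$amp_eff, scn$stim,
                           dt = scn$sense$update_interval)
    locks <- detect_lock(as_state_trace(clt), max_dwell = lock_max_dwell)
    dplyr::bind_cols(cell_row, ev,
                     tibble(energy = en$energy, lock_count = nrow(locks)))
  }
  results <- purrr::map_dfr(seq_len(nrow(cells)),
                            function(i) run_cell(cells[i, ]))
  e_max <- max(results$energy)
  results$energy_norm <- if (e_max > 0) results$energy / e_max else 0
  w <- objective_weights
  results$score <- w[["agreement"]] * (1 - results$agreement) +
    w[["energy"]] * results$energy_norm +
    w[["lock"]] * (results$lock_count > 0)
  chosen <- which.min(results$score)
  structure(list(results = results, chosen = chosen,
                 objective_weights = w, seed = seed,
                 rule = "minimize w_a*(1-agreement) + w_e*energy_norm + w_l*[lock]"),
            class = "grid_search_result")
}

#' Per-cell grid-search metrics
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @return Tibble of cells with agreement, false-positive rate, energy,
#'   lock count and scalarized score; `chosen` marks the selected cell.
#' @export
tidy.grid_search_result <- function(x, ...) {
  dplyr::mutate(x$results, chosen = dplyr::row_number() == x$chosen)
}

#' One-row summary of a grid search
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @return The chosen cell with its metrics, plus the number of cells.
#' @export
glance.grid_search_result <- function(x, ...) {
  dplyr::bind_cols(x$results[x$chosen, ], tibble(n_cells = nrow(x$results)))
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result>", nrow(x$results), "cells;", x$rule, "\n")
  cat("chosen cell:\n")
  print(x$results[x$chosen, ])
  invisible(x)
}

#' Estimate wash-in and wash-out time constants
#'
#' Emulates open-loop wash-in/wash-out testing: stimulation is stepped on
#' and later off following `protocol`, the patient model's score is
#' simulated (with report noise), and single-exponential relaxations are
#' fitted to the on- and off-phase scores by least squares
#' ([minpack.lm::nlsLM]).
#'
#' @param patient A [patient_model()]. Its baseline trace should be flat
#'   over the protocol (diurnal drift biases the fit; see the report).
#' @param protocol Tibble `time`, `amplitude` (mA) with one 0 -> on step
#'   and one on -> 0 step; default: on at 1/6 of the baseline duration,
#'   off at the midpoint. Each phase should last at least 5 time
#'   constants.
#' @param noise_sd Report noise SD (score units).
#' @param dt Sampling interval of the simulated reports (s).
#' @param seed Seed for the report noise.
#' @return A `washout_fit` list with `tau_in`, `tau_out`, the two `nls`
#'   fits, convergence flags and the simulated data; see
#'   [tidy.washout_fit()] / [glance.washout_fit()].
#' @export
washin_washout <- function(patient, protocol = NULL, noise_sd = 0,
                           dt = 1, seed = NULL) {
  base <- patient$baseline
  t_max <- max(base$time)
  if (is.null(protocol)) {
    protocol <- tibble(time = c(0, t_max / 6, t_max * 2 / 3),
                       amplitude = c(0, 1, 0))
  }
  times <- seq(0, t_max, by = dt)
  amp <- hold_resample(protocol$time, protocol$amplitude, times)
  full_scale <- max(amp)
  if (full_scale <= 0) abort("protocol never turns stimulation on")
  on_idx <- which(amp > 0)
  t_on <- times[on_idx[1]]
  after_on <- which(amp == 0 & times > t_on)
  if (!length(after_on)) abort("protocol never turns stimulation off")
  t_off <- times[after_on[1]]
  relief <- numeric(length(times))
  r <- 0
  for (i in seq_along(times)) {
    target <- patient$relief * amp[i] / full_scale
    r <- relief_step(r, target, dt, patient$tau_in, patient$tau_out)
    relief[i] <- r
  }
  baseline_score <- hold_resample(base$time, base$score, times)
  score <- baseline_score - relief
  score <- with_seed_maybe(seed, {
    if (noise_sd > 0) score + rnorm(length(score), sd = noise_sd) else score
  })
  data <- tibble(time = times, amplitude = amp, score = score)

  fit_phase <- function(seg, t0, direction) {
    tt <- seg$time - t0
    y <- seg$score
    span <- diff(range(y))
    start <- list(a = y[1], b = if (direction == "in") -max(span, 1e-3)
                             else max(span, 1e-3),
                  tau = max(diff(range(tt)) / 5, dt))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + b * (1 - exp(-tt / tau)), start = start,
                        lower = c(-Inf, -Inf, dt / 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    fit
  }
  seg_in <- data[data$time > t_on & data$time < t_off, ]
  seg_out <- data[data$time > t_off, ]
  fit_in <- fit_phase(seg_in, t_on, "in")
  fit_out <- fit_phase(seg_out, t_off, "out")
  tau_hat <- function(fit) if (is.null(fit)) NA_real_ else coef(fit)[["tau"]]
  conv <- function(fit) !is.null(fit) && fit$convInfo$isConv
  if (!conv(fit_in) || !conv(fit_out)) {
    warn("wash-in/wash-out fit did not converge; estimates flagged")
  }
  structure(list(tau_in = tau_hat(fit_in), tau_out = tau_hat(fit_out),
                 fit_in = fit_in, fit_out = fit_out,
                 converged_in = conv(fit_in), converged_out = conv(fit_out),
                 t_on = t_on, t_off = t_off, data = data),
            class = "washout_fit")
}

#' Tidy wash-in/wash-out estimates
#' @param x A `washout_fit`.
#' @param ... Unused.
#' @return One row per phase: `phase`, `tau`, `converged`, `resid_sd`.
#' @export
tidy.washout_fit <- function(x, ...) {
  rs <- function(fit) if (is.null(fit)) NA_real_ else sd(resid(fit))
  tibble(phase = c("wash_in", "wash_out"),
         tau = c(x$tau_in, x$tau_out),
         converged = c(x$converged_in, x$converged_out),
         resid_sd = c(rs(x$fit_in), rs(x$fit_out)))
}

#' One-row wash-in/wash-out summary
#' @param x A `washout_fit`.
#' @param ... Unused.
#' @return Tibble with both time constants, step times and convergence.
#' @export
glance.washout_fit <- function(x, ...) {
  tibble(tau_in = x$tau_in, tau_out = x$tau_out, t_on = x$t_on,
         t_off = x$t_off,
         converged = x$converged_in && x$converged_out)
}

#' @export
print.washout_fit <- function(x, ...) {
  cat(sprintf("<washout_fit> tau_in = %.3g s, tau_out = %.3g s (converged: %s)\n",
              x$tau_in, x$tau_out, x$converged_in && x$converged_out))
  invisible(x)
}
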