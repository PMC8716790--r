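#' Detector (state machine) configuration
#'
#' The embedded thresholding logic: the LD output is compared against one
#' threshold (two device states) or two thresholds (three states, the
#' third usable as a "catch" state for artifactually high LD values). A
#' rise requires `onset` *consecutive* updates at or above the threshold
#' (effective onset duration = `onset * update_interval` seconds); a fall
#' requires `termination` consecutive updates below it; a single
#' non-qualifying update resets the relevant counter. After every state
#' change, updates within the blanking window are ignored for counting,
#' absorbing stimulation-switching artifacts.
#'
#' Ties count as "above": the comparison is `ld >= threshold`. With two
#' thresholds the states are ordered bands (`ld < t1`, `t1 <= ld < t2`,
#' `ld >= t2`) reached only through adjacent transitions; rises past t2 and
#' falls below t2 use the same counters unless overridden per threshold.
#'
#' @param thresholds 1 or 2 ascending thresholds in LD units.
#' @param update_interval Seconds between LD updates (shared clock with
#'   sensing).
#' @param onset,termination Consecutive-update counters (integers >= 1).
#' @param onset2,termination2 Optional per-threshold overrides for the
#'   upper threshold (default: same as `onset`/`termination`).
#' @param blanking Blanking duration in seconds (>= 0); converted to
#'   `ceiling(blanking / update_interval)` ignored updates.
#' @param strict_blanking If `TRUE`, counters are also cleared when the
#'   blanking window ends. Because every state change already resets the
#'   counters and blanked updates are not counted, both modes behave
#'   identically here; the flag is kept so either reading of device
#'   behaviour can be stated explicitly.
#' @return A `detector_config` list.
#' @export
detector_config <- function(thresholds, update_interval, onset = 1L,
                            termination = 1L, onset2 = NULL,
                            termination2 = NULL, blanking = 0,
                            strict_blanking = FALSE) {
  if (length(thresholds) < 1 || length(thresholds) > 2) {
    abort("1 or 2 thresholds are required")
  }
  if (length(thresholds) == 2 && thresholds[1] >= thresholds[2]) {
    abort("thresholds must be strictly increasing")
  }
  check_scalar(update_interval, "update_interval", lower = 0,
               strict_lower = TRUE)
  check_scalar(onset, "onset", lower = 1)
  check_scalar(termination, "termination", lower = 1)
  check_scalar(blanking, "blanking", lower = 0)
  structure(list(thresholds = as.numeric(thresholds),
                 update_interval = update_interval,
                 onset = as.integer(onset),
                 termination = as.integer(termination),
                 onset2 = as.integer(onset2 %||% onset),
                 termination2 = as.integer(termination2 %||% termination),
                 blank_updates = as.integer(ceiling(blanking / update_interval - 1e-9)),
                 blanking = blanking,
                 strict_blanking = isTRUE(strict_blanking)),
            class = "detector_config")
}

#' Effective onset and termination durations
#'
#' Devices specify onset/termination as counters; the effective duration in
#' seconds is the counter multiplied by the FFT update interval.
#' @param cfg A [detector_config()].
#' @return Tibble with `onset_duration` and `termination_duration` (s).
#' @export
detector_durations <- function(cfg) {
  tibble(onset_duration = cfg$onset * cfg$update_interval,
         termination_duration = cfg$termination * cfg$update_interval)
}

detector_init <- function(initial_state = 0L) {
  list(state = as.integer(initial_state), up1 = 0L, down1 = 0L,
       up2 = 0L, down2 = 0L, blank = 0L)
}

# One update of the state machine. Returns the new internal state plus the
# transition (or NULL). Shared verbatim by run_detector() and the
# closed-loop simulator, so streaming and batch traces are bit-identical.
detector_step <- function(st, ld, cfg) {
  change <- NULL
  if (st$blank > 0L) {
    st$blank <- st$blank - 1L
    if (st$blank == 0L && cfg$strict_blanking) {
      st$up1 <- st$down1 <- st$up2 <- st$down2 <- 0L
    }
    return(list(st = st, change = change))
  }
  t1 <- cfg$thresholds[1]
  t2 <- if (length(cfg$thresholds) == 2) cfg$thresholds[2] else NA_real_
  from <- st$state
  if (st$state == 0L) {
    st$up1 <- if (ld >= t1) st$up1 + 1L else 0L
    if (st$up1 >= cfg$onset) {
      st$state <- 1L; change <- "onset t1"
    }
  } else if (st$state == 1L) {
    if (!is.na(t2)) {
      st$up2 <- if (ld >= t2) st$up2 + 1L else 0L
      if (st$up2 >= cfg$onset2) {
        st$state <- 2L; change <- "onset t2"
      }
    }
    if (is.null(change)) {
      st$down1 <- if (ld < t1) st$down1 + 1L else 0L
      if (st$down1 >= cfg$termination) {
        st$state <- 0L; change <- "termination t1"
      }
    }
  } else { # state 2
    st$down2 <- if (ld < t2) st$down2 + 1L else 0L
    if (st$down2 >= cfg$termination2) {
      st$state <- 1L; change <- "termination t2"
    }
  }
  if (!is.null(change)) {
    st$up1 <- st$down1 <- st$up2 <- st$down2 <- 0L
    st$blank <- cfg$blank_updates
    change <- list(from = from, to = st$state, cause = change)
  }
  list(st = st, change = change)
}

#' Run the detector over an LD stream
#'
#' Applies the onset/termination/blanking state machine update by update.
#' State changes occur only at update instants and only between adjacent
#' states.
#'
#' @param ld An `ld_stream`, a tibble with `time` and `ld` columns, or a
#'   bare numeric LD vector.
#' @param cfg A [detector_config()]. If `ld` is an `ld_stream` with
#'   attached thresholds and `cfg` is missing, those thresholds are used
#'   with default counters.
#' @param initial_state Starting state (default 0).
#' @return A `state_trace`: tibble `time`, `state`, with the change log
#'   (`time`, `from`, `to`, `cause`) as attribute `"changes"` (retrieve
#'   with [state_changes()]).
#' @export
run_detector <- function(ld, cfg, initial_state = 0L) {
  if (is.numeric(ld) && is.null(dim(ld))) {
    ld <- tibble(time = (seq_along(ld) - 1) * cfg$update_interval, ld = ld)
  }
  if (!nrow(ld)) abort("empty LD stream")
  vals <- ld$ld
  st <- detector_init(initial_state)
  states <- integer(length(vals))
  changes <- list()
  for (i in seq_along(vals)) {
    res <- detector_step(st, vals[i], cfg)
    st <- res$st
    states[i] <- st$state
    if (!is.null(res$change)) {
      changes[[length(changes) + 1]] <-
        tibble(time = ld$time[i], from = res$change$from,
               to = res$change$to, cause = res$change$cause)
    }
  }
  new_state_trace(tibble(time = ld$time, state = states),
                  changes = if (length(changes)) dplyr::bind_rows(changes)
                            else tibble(time = numeric(), from = integer(),
                                        to = integer(), cause = character()),
                  config = cfg)
}

new_state_trace <- function(df, changes, config = NULL) {
  structure(df, class = c("state_trace", class(tibble())),
            changes = changes, config = config)
}

#' Change log of a state trace
#' @param states A `state_trace`.
#' @return Tibble `time`, `from`, `to`, `cause`.
#' @export
state_changes <- function(states) attr(states, "changes", exact = TRUE)

#' Fraction of time spent in each detector state
#'
#' Computed on the update grid (each update contributes equally).
#' @param states A `state_trace` (or tibble with a `state` column).
#' @return Tibble `state`, `fraction`; fractions sum to 1.
#' @export
duty_cycle <- function(states) {
  if (!nrow(states)) abort("empty state trace")
  tab <- table(states$state)
  tibble(state = as.integer(names(tab)),
         fraction = as.numeric(tab) / nrow(states))
}

#' Find therapy-lock episodes
#'
#' A lock is the pathological condition where a stimulation-delivering
#' state persists beyond a clinically plausible dwell — typically because
#' stimulation artifact keeps the LD above threshold, so stimulation never
#' terminates. An empty result means no lock.
#'
#' @param states A `state_trace`.
#' @param max_dwell Maximum acceptable continuous dwell in a
#'   stimulation-on state, in seconds (> 0).
#' @param stim_states States that deliver stimulation (default 1; in a
#'   three-state "catch" configuration the catch state 2 is typically off).
#' @return Tibble of episodes: `start`, `end`, `state`, `duration` (s).
#'   Episodes still open at the end of the trace are reported up to the
#'   last update.
#' @export
detect_lock <- function(states, max_dwell, stim_states = 1L) {
  check_scalar(max_dwell, "max_dwell", lower = 0, strict_lower = TRUE)
  if (!nrow(states)) {
    return(tibble(start = numeric(), end = numeric(), state = integer(),
                  duration = numeric()))
  }
  r <- rle(states$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt <- if (nrow(states) > 1) diff(states$time[1:2]) else 1
  tibble(start = states$time[starts], end = states$time[ends],
         state = r$values, duration = r$lengths * dt) |>
    dplyr::filter(.data$state %in% stim_states,
                  .data$duration > max_dwell)
}
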