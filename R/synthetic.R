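#' Generate a synthetic symptom trace
#'
#' Produces a continuous pain-intensity score (0--10) on a uniform time grid
#' together with its dichotomized state label, emulating the two timescales
#' chronic-pain reports typically show: a slow diurnal drift and abrupt
#' flare transitions. The score is the sum of a baseline, a sinusoidal
#' diurnal term, a two-state telegraph (random flare) process and Gaussian
#' report noise, clipped to \[0, 10\].
#'
#' The state label is `score >= cutoff`. When the configured dynamics are
#' stochastic and the realized trace occupies only one state, the generator
#' redraws (up to `max_tries` times, advancing the seed deterministically)
#' and warns if the trace is still degenerate; a fully deterministic
#' configuration (no noise, no flares) returns its single-state trace
#' silently, since that is the exact answer.
#'
#' @param duration Total duration in seconds (> 0).
#' @param dt Grid spacing in seconds between successive scores.
#' @param cutoff Dichotomization cutoff on the 0--10 scale, in (0, 10);
#'   state 1 ("high pain") is `score >= cutoff`.
#' @param baseline Mean pain score about which the dynamics fluctuate.
#' @param diurnal_amplitude Amplitude of the sinusoidal diurnal term
#'   (score units; 0 disables it).
#' @param diurnal_period Period of the diurnal term in seconds (default one
#'   day).
#' @param diurnal_phase Phase offset of the diurnal sinusoid (radians).
#' @param flare_amplitude Score offset added while the telegraph process is
#'   in its flare state.
#' @param transition_rate Telegraph switching rate in 1/s (0 disables
#'   flares). The default gives a mean dwell of 10 minutes per state.
#' @param noise_sd Standard deviation of the per-report Gaussian noise
#'   (score units).
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @param max_tries Redraw attempts when a stochastic trace is degenerate.
#'
#' @return A `symptom_trace`: a tibble with columns `time` (s), `score` and
#'   `state` (0/1), carrying the cutoff and grid spacing as attributes.
#' @examples
#' tr <- generate_symptom_trace(3600, dt = 10, seed = 1)
#' mean(tr$state)
#' @export
generate_symptom_trace <- function(duration, dt = 1, cutoff = 5,
                                   baseline = 4, diurnal_amplitude = 2,
                                   diurnal_period = 86400, diurnal_phase = 0,
                                   flare_amplitude = 3,
                                   transition_rate = 1 / 600,
                                   noise_sd = 0.5, seed = NULL,
                                   max_tries = 5L) {
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(cutoff, "cutoff", lower = 0, upper = 10, strict_lower = TRUE)
  if (cutoff >= 10) abort("`cutoff` must lie strictly inside (0, 10)")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(transition_rate, "transition_rate", lower = 0)

  n <- floor(duration / dt)
  if (n < 1) abort("`duration` must cover at least one grid step")
  times <- (seq_len(n) - 1) * dt
  stochastic <- noise_sd > 0 ||
    (transition_rate > 0 && abs(flare_amplitude) > 0)

  draw <- function(s) {
    with_seed_maybe(s, {
      flare <- if (transition_rate > 0) {
        p <- 1 - exp(-transition_rate * dt)
        cumsum(c(0L, rbinom(n - 1, 1, p))) %% 2L
      } else {
        rep(0L, n)
      }
      score <- baseline +
        diurnal_amplitude * sin(2 * pi * times / diurnal_period + diurnal_phase) +
        flare_amplitude * flare +
        if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
      pmin(pmax(score, 0), 10)
    })
  }

  score <- draw(seed)
  tries <- 1L
  while (stochastic && length(unique(score >= cutoff)) < 2 &&
         tries < max_tries) {
    score <- draw(if (is.null(seed)) NULL else seed + tries)
    tries <- tries + 1L
  }
  state <- as.integer(score >= cutoff)
  if (stochastic && length(unique(state)) < 2) {
    warn("symptom trace is degenerate: only one state occupied after redraws")
  }
  new_symptom_trace(tibble(time = times, score = score, state = state),
                    cutoff = cutoff, dt = dt)
}

new_symptom_trace <- function(df, cutoff, dt) {
  structure(df, class = c("symptom_trace", class(tibble())),
            cutoff = cutoff, dt = dt)
}

#' Dichotomization cutoff of a symptom trace
#' @param trace A `symptom_trace`.
#' @return The cutoff score (0--10).
#' @export
trace_cutoff <- function(trace) attr(trace, "cutoff", exact = TRUE)

#' Describe a state-dependent spectral biomarker
#'
#' A biomarker is a narrow frequency band on one recording channel whose
#' power differs between low- and high-symptom states (e.g., elevated theta
#' power, 4--8 Hz, during high-pain states).
#'
#' @param channel 1-based index of the carrying channel.
#' @param band Numeric length-2 vector: band edges in Hz, `0 < low < high`.
#' @param power_low,power_high Total band power (uV^2, the variance of the
#'   band-limited component) in state 0 and state 1.
#' @return A one-row tibble; rows from several calls can be bound together
#'   and passed to [generate_lfp()].
#' @examples
#' biomarker_spec(1, c(4, 8), power_low = 25, power_high = 100)
#' @export
biomarker_spec <- function(channel, band, power_low, power_high) {
  stopifnot(length(band) == 2)
  check_scalar(band[1], "band[1]", lower = 0, strict_lower = TRUE)
  if (band[2] <= band[1]) abort("`band` must satisfy 0 < low < high")
  check_scalar(power_low, "power_low", lower = 0)
  check_scalar(power_high, "power_high", lower = 0)
  tibble(channel = as.integer(channel), low = band[1], high = band[2],
         power_low = power_low, power_high = power_high,
         sign = sign(power_high - power_low))
}

#' Describe a recording artifact class
#'
#' The artifact classes routinely seen on sense-enabled stimulators:
#' open-circuit noise when stimulation is programmed to 0 mA rather than
#' off, EKG volume conduction (common with left-sided implants), and
#' movement transients. Stimulation-locked artifacts (`stim_transient`,
#' `cross_region_stim`) trigger on stimulation events and are applied by
#' [inject_stim_artifacts()], not by [generate_lfp()].
#'
#' @param kind One of `"zero_mA_noise"`, `"ekg"`, `"movement"`,
#'   `"stim_transient"`, `"cross_region_stim"`.
#' @param amplitude Amplitude scale in uV (>= 0). For `zero_mA_noise` this
#'   is the added broadband noise SD; for `ekg` the QRS lobe amplitude; for
#'   `movement` the excursion scale.
#' @param rate Event rate in Hz where applicable (defaults: 1.2 for `ekg`,
#'   0.02 for `movement`).
#' @param channels Affected channel indices (`NULL` = all).
#' @return A one-row tibble; bind rows to combine several classes.
#' @export
artifact_spec <- function(kind = c("zero_mA_noise", "ekg", "movement",
                                   "stim_transient", "cross_region_stim"),
                          amplitude, rate = NULL, channels = NULL) {
  kind <- match.arg(kind)
  check_scalar(amplitude, "amplitude", lower = 0)
  if (is.null(rate)) {
    rate <- switch(kind, ekg = 1.2, movement = 0.02, NA_real_)
  }
  tibble(kind = kind, amplitude = amplitude, rate = rate,
         channels = list(channels))
}

#' Synthesize a multichannel LFP recording from a symptom trace
#'
#' Builds per-channel local field potentials as 1/f-shaped broadband
#' background plus, for each biomarker, state-gated band-limited Gaussian
#' noise whose variance equals the state's specified band power, plus any
#' non-stimulation artifacts. Band-limited noise (rather than a sinusoid)
#' is used so that downstream band-power estimates fluctuate realistically.
#'
#' @param trace A [generate_symptom_trace()] result driving the state gate.
#' @param biomarkers Tibble of [biomarker_spec()] rows (`NULL` = pure
#'   noise).
#' @param artifacts Tibble of [artifact_spec()] rows; only
#'   non-stimulation-locked kinds are accepted here.
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge.
#' @param n_channels Number of channels (default: highest biomarker channel,
#'   or 2 for a pure-noise recording).
#' @param background_sd Broadband background SD in uV.
#' @param background_exponent Spectral exponent of the background
#'   (1 = pink noise, the conventional LFP stand-in).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#'
#' @return An `lfp_recording`: a tibble with columns `time, ch1..chN` (uV)
#'   carrying the sampling rate and an artifact event log as attributes.
#' @examples
#' tr <- generate_symptom_trace(120, dt = 1, seed = 1)
#' rec <- generate_lfp(tr, biomarker_spec(1, c(4, 8), 25, 100), fs = 250,
#'                     seed = 2)
#' @export
generate_lfp <- function(trace, biomarkers = NULL, artifacts = NULL,
                         fs = 500, n_channels = NULL, background_sd = 20,
                         background_exponent = 1, seed = NULL) {
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  if (!inherits(trace, "symptom_trace")) abort("`trace` must be a symptom_trace")
  if (!is.null(biomarkers) && nrow(biomarkers)) {
    if (fs <= 2 * max(biomarkers$high)) {
      abort("`fs` must exceed twice the highest biomarker band edge")
    }
  }
  if (!is.null(artifacts) && nrow(artifacts)) {
    locked <- artifacts$kind %in% c("stim_transient", "cross_region_stim")
    if (any(locked)) {
      abort(paste("stimulation-locked artifact kinds trigger on stimulation",
                  "events; apply them with inject_stim_artifacts()"))
    }
  }
  dt_trace <- attr(trace, "dt", exact = TRUE) %||% diff(trace$time[1:2])
  duration <- max(trace$time) + dt_trace
  n <- floor(duration * fs)
  t_s <- (seq_len(n) - 1) / fs
  state_s <- hold_resample(trace$time, trace$state, t_s)
  n_ch <- n_channels %||% max(c(2L, biomarkers$channel))

  with_seed_maybe(seed, {
    sig <- matrix(0, n, n_ch)
    for (j in seq_len(n_ch)) {
      sig[, j] <- background_sd * pink_noise(n, fs, background_exponent)
    }
    if (!is.null(biomarkers)) {
      for (i in seq_len(nrow(biomarkers))) {
        b <- biomarkers[i, ]
        if (b$channel > n_ch) abort("biomarker channel exceeds `n_channels`")
        comp <- band_limited_noise(n, fs, b$low, b$high)
        amp <- sqrt(ifelse(state_s > 0, b$power_high, b$power_low))
        sig[, b$channel] <- sig[, b$channel] + amp * comp
      }
    }
    events <- tibble(time = numeric(), kind = character())
    if (!is.null(artifacts)) {
      for (i in seq_len(nrow(artifacts))) {
        a <- artifacts[i, ]
        chs <- a$channels[[1]] %||% seq_len(n_ch)
        if (a$kind == "zero_mA_noise") {
          for (j in chs) sig[, j] <- sig[, j] + rnorm(n, sd = a$amplitude)
          events <- dplyr::bind_rows(events,
                                     tibble(time = 0, kind = "zero_mA_noise"))
        } else if (a$kind == "ekg") {
          beat_times <- seq(runif(1, 0, 1 / a$rate), duration, by = 1 / a$rate)
          wav <- ekg_waveform(fs, a$amplitude)
          for (bt in beat_times) {
            i0 <- floor(bt * fs) + 1
            idx <- i0:min(n, i0 + length(wav) - 1)
            for (j in chs) {
              sig[idx, j] <- sig[idx, j] + wav[seq_along(idx)]
            }
          }
          events <- dplyr::bind_rows(events,
                                     tibble(time = beat_times, kind = "ekg"))
        } else if (a$kind == "movement") {
          n_ev <- stats::rpois(1, a$rate * duration)
          ev_times <- sort(runif(n_ev, 0, duration))
          for (et in ev_times) {
            bump <- a$amplitude * exp(-(t_s - et)^2 / (2 * 0.25^2))
            for (j in chs) sig[, j] <- sig[, j] + bump
          }
          if (n_ev > 0) {
            events <- dplyr::bind_rows(events,
                                       tibble(time = ev_times, kind = "movement"))
          }
        }
      }
    }
    df <- as_tibble(as.data.frame(sig))
    names(df) <- paste0("ch", seq_len(n_ch))
    new_lfp_recording(dplyr::bind_cols(tibble(time = t_s), df),
                      fs = fs, events = dplyr::arrange(events, .data$time))
  })
}

# Biphasic QRS-like lobe pair, ~60 ms total.
ekg_waveform <- function(fs, amplitude) {
  n_w <- max(4L, round(0.06 * fs))
  tt <- seq_len(n_w) / n_w
  amplitude * sin(2 * pi * tt)
}

new_lfp_recording <- function(df, fs, events) {
  structure(df, class = c("lfp_recording", class(tibble())),
            fs = fs, events = events, units = "uV")
}

#' Sampling rate of a recording
#' @param rec An `lfp_recording`.
#' @return Sampling rate in Hz.
#' @export
lfp_fs <- function(rec) attr(rec, "fs", exact = TRUE)

#' Artifact event log of a recording
#' @param rec An `lfp_recording`.
#' @return Tibble with columns `time` and `kind`.
#' @export
lfp_events <- function(rec) attr(rec, "events", exact = TRUE)

#' Add stimulation artifacts to a recording
#'
#' Pure function: returns a modified copy of `rec` with (a) a tonic
#' artifact proportional to the instantaneous stimulation amplitude at the
#' stimulation frequency, (b) a decaying high-amplitude transient across
#' all channels at every 0 -> nonzero amplitude onset, and optionally (c) a
#' band-limited "leak" term proportional to amplitude, modelling
#' cross-region or aliased stimulation energy contaminating a sensed band.
#'
#' @param rec An `lfp_recording`.
#' @param amplitude Stimulation amplitude in mA: numeric vector with one
#'   value per sample of `rec`, or a data frame with `time` and `amplitude`
#'   columns on the same clock.
#' @param gains Tonic artifact gain per channel in uV/mA (recycled).
#' @param stim_freq Stimulation frequency in Hz.
#' @param transient List `list(magnitude, decay)`: onset transient peak (uV)
#'   and exponential decay constant (s).
#' @param band_leak `NULL`, or `list(band = c(low, high), gain, channels)`:
#'   adds band-limited noise with RMS `gain * amplitude` (uV) to the given
#'   channels (default all).
#' @param seed Seed for the band-leak noise realization.
#' @return A new `lfp_recording`; transient onsets are appended to the
#'   event log.
#' @export
inject_stim_artifacts <- function(rec, amplitude, gains = 1,
                                  stim_freq = 130,
                                  transient = list(magnitude = 200,
                                                   decay = 0.05),
                                  band_leak = NULL, seed = NULL) {
  if (!inherits(rec, "lfp_recording")) abort("`rec` must be an lfp_recording")
  fs <- lfp_fs(rec)
  n <- nrow(rec)
  if (is.data.frame(amplitude)) {
    if (nrow(amplitude) != n ||
        max(abs(amplitude$time - rec$time)) > 1e-9) {
      abort("`amplitude` series is not aligned to the recording clock")
    }
    amplitude <- amplitude$amplitude
  }
  if (length(amplitude) != n) {
    abort("`amplitude` must have one value per recording sample")
  }
  if (stim_freq >= fs / 2) {
    warn("stimulation frequency is at or above Nyquist; the tonic artifact will alias")
  }
  chans <- value_cols(rec)
  gains <- rep_len(gains, length(chans))
  out <- rec
  tonic <- amplitude * sin(2 * pi * stim_freq * rec$time)
  for (j in seq_along(chans)) {
    out[[chans[j]]] <- out[[chans[j]]] + gains[j] * tonic
  }
  onsets <- which(amplitude > 0 & dplyr::lag(amplitude, default = Inf) == 0)
  if (length(onsets) && transient$magnitude > 0) {
    for (i0 in onsets) {
      tt <- rec$time[i0:n] - rec$time[i0]
      pulse <- transient$magnitude * exp(-tt / transient$decay)
      for (ch in chans) out[[ch]][i0:n] <- out[[ch]][i0:n] + pulse
    }
  }
  if (!is.null(band_leak)) {
    leak_ch <- band_leak$channels %||% seq_along(chans)
    noise <- with_seed_maybe(seed, band_limited_noise(
      n, fs, band_leak$band[1], band_leak$band[2]))
    add <- band_leak$gain * amplitude * noise
    for (j in leak_ch) out[[chans[j]]] <- out[[chans[j]]] + add
  }
  ev <- lfp_events(rec)
  if (length(onsets)) {
    ev <- dplyr::arrange(dplyr::bind_rows(
      ev, tibble(time = rec$time[onsets], kind = "stim_transient")),
      .data$time)
  }
  attr(out, "events") <- ev
  out
}
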