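#' Simulate the full closed loop
#'
#' Runs the complete sense -> classify -> detect -> stimulate -> respond
#' loop on synthetic data, one FFT update at a time. Per update the
#' simulator: (1) reads the patient's momentary score (baseline minus the
#' accumulated stimulation relief) and gates the biomarker power by its
#' dichotomized state; (2) synthesizes one window of multichannel LFP and
#' adds stimulation artifacts from the current effective amplitude
#' (tonic tone at the stimulation frequency, onset transient, optional
#' band leak into a sensed band) *before* the FFT, so blanking and
#' averaging interact with artifacts realistically; (3) extracts band
#' powers, normalizes, applies the discriminant weights and trailing
#' average; (4) steps the detector state machine; (5) moves the effective
#' amplitude toward the new state's target at the ramp-limited slope; and
#' (6) relaxes the patient's relief toward its amplitude-dependent target
#' with the wash-in/wash-out time constants.
#'
#' @param patient A [patient_model()]; its baseline trace must cover
#'   `duration`.
#' @param biomarkers Tibble of [biomarker_spec()] rows.
#' @param sense A [sense_config()].
#' @param ld An [ld_config()] (typically from [fit_lda()] on a
#'   calibration run, with normalization fitted in the presence of the
#'   stimulation that will be used).
#' @param detector A [detector_config()]; must share `update_interval`
#'   with `sense`.
#' @param stim A [stim_config()].
#' @param duration Simulated seconds.
#' @param seed Integer seed controlling every noise source.
#' @param fs Sampling rate of the synthesized LFP (Hz).
#' @param n_channels Channels to synthesize (default: enough for all
#'   biomarkers and sensed features).
#' @param background_sd,background_exponent Broadband background
#'   parameters (see [generate_lfp()]).
#' @param initial_state Detector state at t = 0.
#' @return A `closed_loop_trace`: tibble `time`, `ld`, `state`, `amp_cmd`,
#'   `amp_eff`, `score`, `sym_state`, with the detector change log and all
#'   configurations attached as attributes. Convert with
#'   [as_state_trace()] / [as_symptom_trace()].
#' @export
simulate_closed_loop <- function(patient, biomarkers, sense, ld, detector,
                                 stim, duration, seed = NULL, fs = 500,
                                 n_channels = NULL, background_sd = 20,
                                 background_exponent = 1,
                                 initial_state = 0L) {
  if (abs(sense$update_interval - detector$update_interval) > 1e-12) {
    abort(paste0("inconsistent clocks: sense update_interval (",
                 sense$update_interval, " s) != detector update_interval (",
                 detector$update_interval, " s)"))
  }
  if (fs <= 2 * max(biomarkers$high)) {
    abort("`fs` must exceed twice the highest biomarker band edge")
  }
  dt <- sense$update_interval
  n_upd <- floor(duration / dt)
  if (n_upd < 1) abort("`duration` must cover at least one update")
  feat_info <- parse_feature_names(ld$features, sense$bands)
  if (anyNA(feat_info$band_low)) {
    abort("discriminant features must reference bands defined in the sense config")
  }
  n_ch <- n_channels %||% max(c(biomarkers$channel, feat_info$channel))
  N <- sense$window
  taper <- window_taper(N, sense$window_fun)
  bins <- band_bins(sense, fs)
  names(bins) <- sense$bands$label
  tonic_gain <- rep_len(stim$tonic_gain, n_ch)
  full_scale <- max(stim$amplitudes)
  stepped <- stim$ramp_mode == "stepped"
  base_t <- patient$baseline$time
  base_s <- patient$baseline$score
  cutoff <- patient$cutoff

  with_seed_maybe(seed, {
    st <- detector_init(initial_state)
    amp <- stim$amplitudes[st$state + 1L]
    relief <- 0
    buf <- numeric(0) # trailing raw-LD buffer
    last_onset <- -Inf
    rows_time <- (seq_len(n_upd)) * dt
    out <- matrix(NA_real_, n_upd, 6,
                  dimnames = list(NULL, c("ld", "state", "amp_cmd",
                                          "amp_eff", "score", "sym_state")))
    changes <- list()
    for (k in seq_len(n_upd)) {
      t_k <- rows_time[k]
      score <- min(max(hold_resample(base_t, base_s, t_k) - relief, 0), 10)
      sym <- as.integer(score >= cutoff)
      # -- synthesize one trailing window of LFP at the current state
      t_chunk <- t_k - (N:1) / fs
      sig <- matrix(0, N, n_ch)
      for (j in seq_len(n_ch)) {
        sig[, j] <- background_sd * pink_noise(N, fs, background_exponent)
      }
      for (i in seq_len(nrow(biomarkers))) {
        b <- biomarkers[i, ]
        pow <- if (sym > 0) b$power_high else b$power_low
        sig[, b$channel] <- sig[, b$channel] +
          sqrt(pow) * band_limited_noise(N, fs, b$low, b$high)
      }
      # -- stimulation artifacts from the current effective amplitude
      if (amp > 0) {
        tone <- amp * sin(2 * pi * stim$frequency * t_chunk)
        for (j in seq_len(n_ch)) {
          if (tonic_gain[j] != 0) sig[, j] <- sig[, j] + tonic_gain[j] * tone
        }
        if (!is.null(stim$band_leak) && stim$band_leak$gain != 0) {
          sig <- sig + stim$band_leak$gain * amp *
            band_limited_noise(N, fs, stim$band_leak$band[1],
                               stim$band_leak$band[2])
        }
      }
      if (stim$transient$magnitude > 0 && is.finite(last_onset)) {
        rel_t <- t_chunk - last_onset
        live <- rel_t >= 0
        if (any(live)) {
          sig <- sig + stim$transient$magnitude *
            exp(-pmax(rel_t, 0) / stim$transient$decay) * live
        }
      }
      # -- band-power features -> normalized -> weighted -> averaged
      raw <- 0
      for (i in seq_len(nrow(feat_info))) {
        p <- segment_periodogram(sig[, feat_info$channel[i]], taper)
        val <- mean(p[bins[[feat_info$band[i]]]])
        z <- (val - ld$norm$mean[i]) / ld$norm$sd[i]
        raw <- raw + ld$weights[i] * z
      }
      buf <- c(buf, raw)
      if (length(buf) > ld$avg_len) buf <- buf[-1]
      ld_k <- mean(buf)
      # -- detector, ramp, patient response
      res <- detector_step(st, ld_k, detector)
      st <- res$st
      if (!is.null(res$change)) {
        changes[[length(changes) + 1]] <-
          tibble(time = t_k, from = res$change$from, to = res$change$to,
                 cause = res$change$cause)
      }
      amp_prev <- amp
      amp <- ramp_step(amp, stim$amplitudes[st$state + 1L],
                       stim$ramp[st$state + 1L], full_scale, dt, stepped)
      if (amp_prev == 0 && amp > 0) last_onset <- t_k
      relief <- relief_step(relief,
                            if (full_scale > 0) {
                              patient$relief * amp / full_scale
                            } else 0,
                            dt, patient$tau_in, patient$tau_out)
      out[k, ] <- c(ld_k, st$state, stim$amplitudes[st$state + 1L], amp,
                    score, sym)
    }
    trace <- as_tibble(as.data.frame(out))
    trace <- dplyr::mutate(trace, state = as.integer(.data$state),
                           sym_state = as.integer(.data$sym_state))
    trace <- dplyr::bind_cols(tibble(time = rows_time), trace)
    structure(trace,
              class = c("closed_loop_trace", class(tibble())),
              changes = if (length(changes)) dplyr::bind_rows(changes)
                        else tibble(time = numeric(), from = integer(),
                                    to = integer(), cause = character()),
              cutoff = cutoff, update_interval = dt,
              configs = list(sense = sense, ld = ld, detector = detector,
                             stim = stim))
  })
}

#' Extract the detector state trace from a closed-loop run
#' @param x A `closed_loop_trace`.
#' @return A `state_trace` with the detector change log attached.
#' @export
as_state_trace <- function(x) {
  new_state_trace(tibble(time = x$time, state = x$state),
                  changes = attr(x, "changes", exact = TRUE))
}

#' Extract the modeled symptom trace from a closed-loop run
#' @param x A `closed_loop_trace`.
#' @return A `symptom_trace` of the modeled score and dichotomized state.
#' @export
as_symptom_trace <- function(x) {
  new_symptom_trace(tibble(time = x$time, score = x$score,
                           state = x$sym_state),
                    cutoff = attr(x, "cutoff", exact = TRUE),
                    dt = attr(x, "update_interval", exact = TRUE))
}

#' A packaged high signal-to-noise closed-loop scenario
#'
#' A reference scenario in which the biomarker separates symptom states
#' cleanly, artifact coupling is absent and the threshold sits at the
#' fitted class midpoint — the regime in which the detector state should
#' closely track the patient's symptom state. The scenario is built by the
#' same calibration workflow a clinician would follow: an open-loop
#' (0 mA) recording is synthesized from the baseline trace, features are
#' extracted and the discriminant is fitted against the dichotomized
#' symptom labels; the single threshold is the midpoint of the two class
#' means in LD units.
#'
#' @param duration Simulated seconds (default 600).
#' @param seed Seed for the calibration recording (the closed-loop run
#'   takes its own seed).
#' @param relief Maximal stimulation relief passed to the patient model.
#' @param tonic_gain,band_leak Artifact couplings, default off; supply
#'   values to build the artifact-contaminated variants of the scenario.
#' @param thresholds Optional override of the detector threshold(s).
#' @param ld_features,ld_weights Optional override of the fitted
#'   discriminant (e.g., to add a negative-weight stimulation-tracking
#'   feature); normalization stats for any extra feature are fitted on the
#'   calibration recording *with* a stimulation-on segment, mirroring the
#'   advice that features must be defined under the stimulation that will
#'   be used.
#' @param onset,termination,blanking,avg_len,ramp Control parameters.
#' @return A named list of arguments for [simulate_closed_loop()]; run it
#'   with `do.call(simulate_closed_loop, c(scenario, list(seed = 7)))`.
#' @export
high_snr_scenario <- function(duration = 600, seed = 42, relief = 1,
                              tonic_gain = 0, band_leak = NULL,
                              thresholds = NULL, ld_features = NULL,
                              ld_weights = NULL, onset = 2L,
                              termination = 2L, blanking = 0,
                              avg_len = 5L, ramp = 1) {
  fs <- 500
  update <- 0.5
  baseline <- generate_symptom_trace(duration + update, dt = update,
                                     cutoff = 5, baseline = 3,
                                     diurnal_amplitude = 0,
                                     flare_amplitude = 4,
                                     transition_rate = 1 / 150,
                                     noise_sd = 0.1, seed = seed)
  biomarkers <- biomarker_spec(1, c(4, 8), power_low = 25, power_high = 500)
  bands <- dplyr::bind_rows(spectral_bands(),
                            tibble(label = "stimband", low = 120, high = 140))
  sense <- sense_config(bands = bands, window = 256, update_interval = update)
  stim <- stim_config(c(0, 2), ramp = ramp, frequency = 130,
                      tonic_gain = tonic_gain, band_leak = band_leak)
  # calibration: open-loop recording + a stimulation-on replica so that
  # stimulation-band features have meaningful normalization stats
  calib_trace <- baseline
  rec <- generate_lfp(calib_trace, biomarkers, fs = fs, n_channels = 1,
                      seed = seed + 1)
  amp_on <- rep(stim$amplitudes[2], nrow(rec))
  rec_on <- inject_stim_artifacts(rec, amp_on, gains = tonic_gain,
                                  stim_freq = stim$frequency,
                                  transient = list(magnitude = 0, decay = 0.05),
                                  band_leak = band_leak, seed = seed + 2)
  feats_off <- compute_band_power(rec, sense)
  feats_on <- compute_band_power(rec_on, sense)
  fit <- fit_lda(feats_off, calib_trace, feature_names = "ch1_theta",
                 avg_len = avg_len)
  features <- ld_features %||% fit$features
  # Extra (non-fitted) features, e.g. a stimulation-band tracker, are
  # normalized clinician-style against the calibration pair: mean at the
  # stimulation-off level and sd equal to the on-off gap, so z ~ 0 when
  # stimulation is off and z ~ 1 when fully on.
  extra <- setdiff(features, fit$norm$feature)
  norm <- fit$norm
  for (f in extra) {
    gap <- mean(feats_on[[f]]) - mean(feats_off[[f]])
    if (!is.finite(gap) || gap <= 0) {
      abort(sprintf("feature '%s' does not respond to stimulation; cannot calibrate it", f))
    }
    norm <- dplyr::bind_rows(norm, tibble(feature = f,
                                          mean = mean(feats_off[[f]]),
                                          sd = gap))
  }
  if (is.null(ld_weights)) {
    if (length(features) == 2 && length(extra) == 1) {
      # negative feedback: weight the tracker so it cancels the
      # artifact-induced lift of the primary feature when stimulation is on
      lift <- (mean(feats_on[[features[1]]]) -
                 mean(feats_off[[features[1]]])) / fit$norm$sd[1]
      weights <- c(fit$weights[1], -fit$weights[1] * lift)
    } else {
      weights <- fit$weights
    }
  } else {
    weights <- ld_weights
  }
  thr <- thresholds %||% fit$training$midpoint
  ldc <- ld_config(features, weights, norm, thresholds = thr,
                   avg_len = avg_len)
  det <- detector_config(thr, update_interval = update, onset = onset,
                         termination = termination, blanking = blanking)
  pm <- patient_model(baseline, tau_in = 60, tau_out = 60, relief = relief)
  list(patient = pm, biomarkers = biomarkers, sense = sense, ld = ldc,
       detector = det, stim = stim, duration = duration, fs = fs,
       n_channels = 1)
}
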