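#' Stimulation configuration
#'
#' Maps detector states to stimulation amplitudes and describes ramping
#' and the sensing-side artifact coupling. State 0 is the designated "off"
#' state and must have amplitude 0. In a three-state "catch"
#' configuration, state 2 is also assigned amplitude 0 so that an
#' artifactually high LD turns stimulation off instead of locking it on.
#'
#' @param amplitudes Target amplitude (mA) per state, state 0 first;
#'   `amplitudes[1]` must be 0.
#' @param ramp Ramp rate per state: seconds to traverse the full amplitude
#'   scale (0 = instant step). Scalar values are recycled.
#' @param frequency Stimulation frequency (Hz, metadata + artifact tone).
#' @param pulse_width Pulse width (us, metadata for the energy proxy).
#' @param tonic_gain Tonic artifact gain per sense channel (uV/mA,
#'   recycled).
#' @param transient List `list(magnitude, decay)` for the onset transient
#'   (uV, s); magnitude 0 disables it.
#' @param band_leak `NULL`, or `list(band = c(low, high), gain)`:
#'   amplitude-proportional band-limited artifact into a sensed band
#'   (models cross-region stimulation contaminating the biomarker band).
#' @param ramp_mode `"linear"` (default) or `"stepped"` (amplitude jumps
#'   to target at the change instant; equivalent to ramp 0, provided as an
#'   explicit mode).
#' @return A `stim_config` list.
#' @export
stim_config <- function(amplitudes, ramp = 1, frequency = 130,
                        pulse_width = 60, tonic_gain = 0,
                        transient = list(magnitude = 0, decay = 0.05),
                        band_leak = NULL,
                        ramp_mode = c("linear", "stepped")) {
  ramp_mode <- match.arg(ramp_mode)
  if (any(amplitudes < 0)) abort("amplitudes must be >= 0")
  if (amplitudes[1] != 0) abort("state 0 is the off state and must have amplitude 0")
  if (any(ramp < 0)) abort("ramp rates must be >= 0")
  structure(list(amplitudes = as.numeric(amplitudes),
                 ramp = rep_len(as.numeric(ramp), length(amplitudes)),
                 frequency = frequency, pulse_width = pulse_width,
                 tonic_gain = tonic_gain, transient = transient,
                 band_leak = band_leak, ramp_mode = ramp_mode),
            class = "stim_config")
}

# Move the effective amplitude one step toward `target` at the
# slope-limited rate; the slope is full scale / ramp seconds for the
# current state, so a mid-ramp state change retargets from the current
# amplitude with no discontinuity.
ramp_step <- function(amp, target, ramp_s, full_scale, dt, stepped = FALSE) {
  if (stepped || ramp_s <= 0) return(target)
  max_step <- full_scale / ramp_s * dt
  amp + max(-max_step, min(max_step, target - amp))
}

#' Apply amplitude ramping to a detector state trace
#'
#' Converts the discrete state sequence into the continuous effective
#' amplitude the tissue sees: at every step the amplitude moves toward the
#' current state's target at constant slope (full amplitude scale divided
#' by the state's ramp rate), reversing immediately on state changes. With
#' ramp rate 2 s, a 1 s dwell in the stimulation-on state therefore peaks
#' at 50% of the programmed target.
#'
#' @param states A `state_trace` (or tibble with `time` and `state`).
#' @param cfg A [stim_config()].
#' @param dt Grid step in seconds (default: the state-trace spacing).
#' @return Tibble `time`, `state`, `amp_cmd` (the state's target) and
#'   `amp_eff` (slope-limited effective amplitude, mA).
#' @examples
#' st <- tibble::tibble(time = seq(0, 4, 0.1),
#'                      state = as.integer(time >= 1 & time < 2))
#' ramp <- apply_ramp(st, stim_config(c(0, 2), ramp = 2))
#' max(ramp$amp_eff) # 1 mA = 50% of target
#' @export
apply_ramp <- function(states, cfg, dt = NULL) {
  if (!nrow(states)) abort("empty state trace")
  dt <- dt %||% (if (nrow(states) > 1) diff(states$time[1:2]) else 1)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  s <- states$state + 1L
  if (max(s) > length(cfg$amplitudes)) {
    abort("state trace contains states without a configured amplitude")
  }
  full_scale <- max(cfg$amplitudes)
  stepped <- cfg$ramp_mode == "stepped"
  n <- nrow(states)
  amp <- numeric(n)
  amp[1] <- cfg$amplitudes[s[1]]
  if (n > 1) {
    for (i in 2:n) {
      amp[i] <- ramp_step(amp[i - 1], cfg$amplitudes[s[i - 1]],
                          cfg$ramp[s[i - 1]], full_scale, dt, stepped)
    }
  }
  tibble(time = states$time, state = states$state,
         amp_cmd = cfg$amplitudes[s], amp_eff = amp)
}

#' Total-energy proxy of a stimulation bout
#'
#' A battery-longevity surrogate in the TEED style: the time integral of
#' squared amplitude times stimulation frequency and pulse width, with
#' impedance normalized to 1. Lower is better for battery life.
#'
#' @param amplitude Effective amplitude series (mA): numeric vector, or
#'   the result of [apply_ramp()] (its `amp_eff` column is used).
#' @param cfg A [stim_config()] providing frequency and pulse width.
#' @param dt Sample spacing in seconds.
#' @return Tibble with `energy` (mA^2 Hz us s, total), `energy_per_hour`,
#'   and `duration` (s).
#' @export
energy_delivered <- function(amplitude, cfg, dt) {
  if (is.data.frame(amplitude)) amplitude <- amplitude$amp_eff
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  total <- sum(amplitude^2) * cfg$frequency * cfg$pulse_width * dt
  duration <- length(amplitude) * dt
  tibble(energy = total, energy_per_hour = total / duration * 3600,
         duration = duration)
}

#' Patient symptom-response model
#'
#' First-order wash-in/wash-out dynamics: stimulation builds up a pain
#' relief that relaxes toward `relief * amplitude / full_scale` with time
#' constant `tau_in` while the effect is growing and `tau_out` while it is
#' fading; the momentary score is the baseline trace minus the current
#' relief, clipped to \[0, 10\]. This is the simplest model exhibiting the
#' wash-in/wash-out asymmetry probed by open-loop testing.
#'
#' @param baseline A `symptom_trace` giving the un-stimulated score over
#'   time (its cutoff dichotomizes the modeled score too).
#' @param tau_in,tau_out Wash-in / wash-out time constants in seconds
#'   (> 0).
#' @param relief Maximal pain relief at full-scale amplitude (score
#'   units, >= 0).
#' @return A `patient_model` list.
#' @export
patient_model <- function(baseline, tau_in, tau_out, relief) {
  if (!inherits(baseline, "symptom_trace")) {
    abort("`baseline` must be a symptom_trace")
  }
  check_scalar(tau_in, "tau_in", lower = 0, strict_lower = TRUE)
  check_scalar(tau_out, "tau_out", lower = 0, strict_lower = TRUE)
  check_scalar(relief, "relief", lower = 0)
  structure(list(baseline = baseline, tau_in = tau_in, tau_out = tau_out,
                 relief = relief, cutoff = trace_cutoff(baseline)),
            class = "patient_model")
}

# Exact discretization of dr/dt = (target - r) / tau over one step.
relief_step <- function(r, target, dt, tau_in, tau_out) {
  tau <- if (target > r) tau_in else tau_out
  r + (target - r) * (1 - exp(-dt / tau))
}
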