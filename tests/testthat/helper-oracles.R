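# Independent reference implementations ("oracles") used to check the
# package's computational paths. These deliberately use direct, naive
# algorithms and share no code with the package internals.

# Direct DFT periodogram (one-sided, uV^2 per bin), computed from the
# definition of the DFT rather than stats::fft.
oracle_periodogram <- function(x, taper = rep(1, length(x))) {
  n <- length(x)
  xw <- (x - mean(x)) * taper
  t_idx <- 0:(n - 1)
  p <- vapply(0:(n %/% 2), function(k) {
    Mod(sum(xw * exp(-2i * pi * k * t_idx / n)))^2
  }, numeric(1)) / (n * sum(taper^2))
  p[2:(n %/% 2)] <- 2 * p[2:(n %/% 2)]
  p
}

# Total signal variance inside a frequency band, from a full-length FFT.
oracle_band_variance <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- fft(x - mean(x))
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  sum((Mod(X)^2 / n^2)[f >= lo & f < hi])
}

# Naive step-by-step detector reference simulator.
oracle_detector <- function(ld, t1, t2 = NA, onset = 1, term = 1,
                            onset2 = onset, term2 = term, blank_n = 0,
                            init = 0) {
  state <- init
  up1 <- down1 <- up2 <- down2 <- 0
  blank <- 0
  out <- integer(length(ld))
  for (i in seq_along(ld)) {
    if (blank > 0) {
      blank <- blank - 1
      out[i] <- state
      next
    }
    changed <- FALSE
    if (state == 0) {
      up1 <- if (ld[i] >= t1) up1 + 1 else 0
      if (up1 >= onset) { state <- 1; changed <- TRUE }
    } else if (state == 1) {
      if (!is.na(t2)) {
        up2 <- if (ld[i] >= t2) up2 + 1 else 0
        if (up2 >= onset2) { state <- 2; changed <- TRUE }
      }
      if (!changed) {
        down1 <- if (ld[i] < t1) down1 + 1 else 0
        if (down1 >= term) { state <- 0; changed <- TRUE }
      }
    } else {
      down2 <- if (ld[i] < t2) down2 + 1 else 0
      if (down2 >= term2) { state <- 1; changed <- TRUE }
    }
    if (changed) {
      up1 <- down1 <- up2 <- down2 <- 0
      blank <- blank_n
    }
    out[i] <- state
  }
  out
}

# Fine-substep Euler integration of the slope-limited amplitude ODE.
oracle_ramp <- function(states, amplitudes, ramp, dt, n_sub = 50) {
  full <- max(amplitudes)
  amp <- amplitudes[states[1] + 1]
  out <- numeric(length(states))
  out[1] <- amp
  for (i in seq_along(states)[-1]) {
    target <- amplitudes[states[i - 1] + 1]
    r <- ramp[states[i - 1] + 1]
    if (r <= 0) {
      amp <- target
    } else {
      step <- full / r * dt / n_sub
      for (s in seq_len(n_sub)) {
        amp <- amp + max(-step, min(step, target - amp))
      }
    }
    out[i] <- amp
  }
  out
}

# Hand-rolled symptom trace on a uniform grid (test fixture builder).
make_trace <- function(score, dt = 1, cutoff = 5) {
  cldbs:::new_symptom_trace(
    tibble::tibble(time = (seq_along(score) - 1) * dt, score = score,
                   state = as.integer(score >= cutoff)),
    cutoff = cutoff, dt = dt)
}

# Hand-rolled single/multi-channel recording (test fixture builder).
make_recording <- function(..., fs) {
  chans <- list(...)
  n <- length(chans[[1]])
  df <- tibble::tibble(time = (seq_len(n) - 1) / fs)
  for (i in seq_along(chans)) df[[paste0("ch", i)]] <- chans[[i]]
  cldbs:::new_lfp_recording(
    df, fs = fs, events = tibble::tibble(time = numeric(),
                                         kind = character()))
}
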