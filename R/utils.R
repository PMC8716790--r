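# Internal helpers shared across modules. All times are seconds from
# recording start; one clock convention package-wide.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state;
# seed = NULL means "use the current RNG stream".
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1)
    withr::with_seed(as.integer(seed), expr)
  }
}

# Previous-value hold: a report at time t[i] is valid until the next one.
# Values before the first report take the first value.
hold_resample <- function(times, values, at) {
  stats::approx(times, values, xout = at, method = "constant",
                f = 0, rule = 2)$y
}

# Band-limited unit-variance Gaussian noise via spectral masking: white
# noise -> FFT -> zero bins outside [low, high) Hz -> inverse -> rescale.
band_limited_noise <- function(n, fs, low, high) {
  if (n < 8) abort("band-limited noise needs at least 8 samples")
  x <- rnorm(n)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs) # fold to [0, fs/2]
  keep <- freqs >= low & freqs < high
  X[!keep] <- 0i
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s < .Machine$double.eps) abort("degenerate band: no spectral content retained")
  (y - mean(y)) / s
}

# 1/f^alpha-shaped broadband noise ("pink" for alpha = 1) with a fixed
# low-frequency shoulder at f0 Hz and expected unit variance. The
# deterministic normalization makes the spectral density at any fixed
# frequency independent of the realization length, so short synthesis
# chunks and long recordings have matching band statistics.
pink_noise <- function(n, fs, alpha = 1, f0 = 1) {
  x <- rnorm(n)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  w <- 1 / pmax(freqs, f0)^(alpha / 2)
  y <- Re(fft(X * w, inverse = TRUE)) / n
  y / sqrt(mean(w^2))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# Channel column names of a recording / feature tibble (everything but time).
value_cols <- function(x) setdiff(names(x), "time")

stop_if_nonuniform_time <- function(time, what = "trace") {
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) abort(sprintf("%s times must be strictly increasing", what))
    if (diff(range(dt)) > 1e-9 * max(dt)) {
      abort(sprintf("%s times must be uniformly spaced", what))
    }
  }
  invisible(time)
}
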