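#' Default spectral band definitions
#'
#' The conventional LFP band partition used for feature screening.
#' @return Tibble with columns `label`, `low`, `high` (Hz). Bands are
#'   half-open `[low, high)` on periodogram bin centers.
#' @export
spectral_bands <- function() {
  tibble(label = c("delta", "theta", "alpha", "beta", "gamma"),
         low = c(1, 4, 8, 13, 30),
         high = c(4, 8, 13, 30, 80))
}

#' Sensing configuration
#'
#' Describes the on-device spectral feature computation: which channels are
#' sensed, the FFT window, and how often a new power estimate is produced.
#' The update interval may exceed the window duration (sparse FFTs), which
#' devices use to average slowly-varying biomarkers on minute timescales.
#'
#' @param bands Tibble with `label`, `low`, `high` columns (Hz); defaults
#'   to [spectral_bands()]. Band edges are half-open `[low, high)` on bin
#'   centers, so adjacent bands never double-count a bin.
#' @param window FFT window length in samples; must be a power of two
#'   (device-faithful).
#' @param update_interval Seconds between successive FFT outputs (> 0).
#' @param window_fun `"hann"` (default) or `"rect"`.
#' @param channels Channel indices to sense (`NULL` = all channels of the
#'   recording).
#' @return A `sense_config` list.
#' @export
sense_config <- function(bands = spectral_bands(), window = 256,
                         update_interval = 0.5,
                         window_fun = c("hann", "rect"), channels = NULL) {
  window_fun <- match.arg(window_fun)
  check_scalar(window, "window", lower = 8)
  if (bitwAnd(as.integer(window), as.integer(window) - 1L) != 0L) {
    abort("`window` must be a power of two")
  }
  check_scalar(update_interval, "update_interval", lower = 0,
               strict_lower = TRUE)
  stopifnot(is.data.frame(bands),
            all(c("label", "low", "high") %in% names(bands)))
  if (any(bands$low < 0) || any(bands$high <= bands$low)) {
    abort("each band must satisfy 0 <= low < high")
  }
  structure(list(bands = as_tibble(bands), window = as.integer(window),
                 update_interval = update_interval, window_fun = window_fun,
                 channels = channels),
            class = "sense_config")
}

window_taper <- function(n, fun) {
  switch(fun,
         hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
         rect = rep(1, n),
         abort("unknown window function"))
}

# One-sided periodogram bin powers (uV^2 per bin) of a single mean-removed,
# tapered segment; bin k (0-based) is centered at k * fs / n.
segment_periodogram <- function(x, taper) {
  n <- length(x)
  xw <- (x - mean(x)) * taper
  X <- fft(xw)
  scale <- n * sum(taper^2)
  p <- Mod(X[seq_len(n %/% 2 + 1)])^2 / scale
  p[2:(n %/% 2)] <- 2 * p[2:(n %/% 2)]
  p
}

# Indices (into the one-sided periodogram) of bin centers in [low, high).
band_bins <- function(cfg, fs) {
  n <- cfg$window
  centers <- (0:(n %/% 2)) * fs / n
  nyq <- fs / 2
  purrr::pmap(cfg$bands, function(label, low, high) {
    if (high > nyq) {
      abort(sprintf("band '%s' [%g, %g) extends beyond Nyquist (%g Hz)",
                    label, low, high, nyq))
    }
    idx <- which(centers >= low & centers < high)
    if (!length(idx)) {
      abort(sprintf(
        "band '%s' [%g, %g) contains no periodogram bin at resolution %g Hz",
        label, low, high, fs / n))
    }
    idx
  })
}

#' Compute windowed band-power features
#'
#' Emulates the embedded spectral pipeline: every `update_interval` seconds
#' an FFT is taken over the trailing `window` samples of each sensed
#' channel and, per band, the mean of the periodogram bins whose centers
#' fall in `[low, high)` is reported (uV^2). The first output is produced
#' as soon as one full window of data is available.
#'
#' @param rec An `lfp_recording`.
#' @param cfg A [sense_config()].
#' @return A `feature_stream`: tibble with `time` plus one `chX_band`
#'   column per (channel, band), carrying the configuration as an
#'   attribute.
#' @examples
#' tr <- generate_symptom_trace(60, dt = 1, seed = 1)
#' rec <- generate_lfp(tr, biomarker_spec(1, c(4, 8), 25, 100), fs = 250,
#'                     seed = 2)
#' fs <- compute_band_power(rec, sense_config(window = 256,
#'                                            update_interval = 1))
#' @export
compute_band_power <- function(rec, cfg = sense_config()) {
  if (!inherits(rec, "lfp_recording")) abort("`rec` must be an lfp_recording")
  fs <- lfp_fs(rec)
  n <- nrow(rec)
  if (n < cfg$window) abort("recording shorter than one FFT window")
  chans <- value_cols(rec)
  sel <- cfg$channels %||% seq_along(chans)
  bins <- band_bins(cfg, fs)
  taper <- window_taper(cfg$window, cfg$window_fun)
  win_dur <- cfg$window / fs
  ui <- cfg$update_interval
  k0 <- ceiling(win_dur / ui - 1e-9)
  t_end <- rec$time[n] + 1 / fs
  ks <- k0:floor(t_end / ui + 1e-9)
  times <- ks * ui
  ends <- round(times * fs)
  ok <- ends <= n & ends >= cfg$window
  times <- times[ok]; ends <- ends[ok]
  if (!length(times)) abort("recording too short for the update interval")

  cols <- list(time = times)
  for (j in sel) {
    x <- rec[[chans[j]]]
    pow <- vapply(ends, function(e) {
      p <- segment_periodogram(x[(e - cfg$window + 1):e], taper)
      vapply(bins, function(idx) mean(p[idx]), numeric(1))
    }, numeric(nrow(cfg$bands)))
    pow <- if (is.null(dim(pow))) matrix(pow, nrow = 1) else pow
    for (b in seq_len(nrow(cfg$bands))) {
      cols[[paste0(chans[j], "_", cfg$bands$label[b])]] <- pow[b, ]
    }
  }
  new_feature_stream(as_tibble(cols), cfg)
}

new_feature_stream <- function(df, cfg) {
  structure(df, class = c("feature_stream", class(tibble())), config = cfg)
}

#' Sensing configuration of a feature stream
#' @param features A `feature_stream`.
#' @return The `sense_config` that produced it.
#' @export
feature_config <- function(features) attr(features, "config", exact = TRUE)

# Split "ch3_theta" -> channel 3, label "theta".
parse_feature_names <- function(nms, bands) {
  ch <- as.integer(sub("^ch(\\d+)_.*$", "\\1", nms))
  label <- sub("^ch\\d+_", "", nms)
  low <- bands$low[match(label, bands$label)]
  tibble(feature = nms, channel = ch, band = label, band_low = low)
}

#' Rank candidate features by symptom correlation
#'
#' The biomarker-discovery step: correlates every (channel, band) power
#' series against the symptom score (resampled to the feature clock by
#' previous-value hold — a pain report is valid until the next) and uses
#' the correlation magnitude as feature importance. Zero-variance features
#' get importance 0 and are flagged. Ties are broken by channel index, then
#' band low edge.
#'
#' @param features A `feature_stream`.
#' @param trace A `symptom_trace` overlapping the feature times.
#' @param method `"pearson"` (on the raw score, default) or `"spearman"`
#'   (rank correlation, invariant to monotone rescaling of the score).
#' @return A `feature_ranking` tibble: `feature`, `channel`, `band`,
#'   `correlation`, `importance`, `degenerate`, sorted by importance
#'   descending.
#' @export
rank_features <- function(features, trace,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (min(trace$time) > max(features$time) ||
      max(trace$time) < min(features$time)) {
    abort("feature times and symptom times do not overlap")
  }
  score <- hold_resample(trace$time, trace$score, features$time)
  cfg <- feature_config(features)
  nms <- value_cols(features)
  info <- parse_feature_names(nms, cfg$bands)
  res <- purrr::map_dfr(nms, function(nm) {
    x <- features[[nm]]
    if (sd(x) == 0 || sd(score) == 0) {
      tibble(feature = nm, correlation = NA_real_, importance = 0,
             degenerate = TRUE)
    } else {
      r <- cor(x, score, method = method)
      tibble(feature = nm, correlation = r, importance = abs(r),
             degenerate = FALSE)
    }
  })
  res <- dplyr::left_join(res, info, by = "feature")
  res <- dplyr::arrange(res, dplyr::desc(.data$importance), .data$channel,
                        .data$band_low)
  res <- dplyr::select(res, "feature", "channel", "band", "correlation",
                       "importance", "degenerate")
  structure(res, class = c("feature_ranking", class(tibble())),
            method = method)
}

#' Choose the smallest adequate FFT window
#'
#' Screens candidate Fourier window lengths for the minimum acceptable
#' frequency resolution: for each candidate, features are recomputed and
#' ranked against the symptom trace, and the smallest window whose top
#' feature importance reaches `frac` of the best across candidates is
#' retained. Equal importances therefore favour the smaller (cheaper,
#' faster-updating) window.
#'
#' @param rec An `lfp_recording`.
#' @param trace The symptom trace used for ranking.
#' @param candidates Integer vector of candidate window lengths (samples,
#'   powers of two).
#' @param frac Acceptance fraction of the best importance (default 0.95).
#' @param bands,update_interval,window_fun Passed to [sense_config()].
#' @return A `window_selection` list: `window` (the chosen length) and
#'   `report` (per-candidate importance table).
#' @export
select_window <- function(rec, trace, candidates, frac = 0.95,
                          bands = spectral_bands(), update_interval = 0.5,
                          window_fun = "hann") {
  if (!length(candidates)) abort("no candidate windows supplied")
  candidates <- sort(unique(as.integer(candidates)))
  fs <- lfp_fs(rec)
  report <- purrr::map_dfr(candidates, function(w) {
    tryCatch({
      cfg <- sense_config(bands = bands, window = w,
                          update_interval = max(update_interval, w / fs),
                          window_fun = window_fun)
      rk <- rank_features(compute_band_power(rec, cfg), trace)
      tibble(window = w, resolution_hz = fs / w,
             top_feature = rk$feature[1], importance = rk$importance[1],
             note = NA_character_)
    }, error = function(e) {
      # e.g. resolution too coarse for a band to contain any bin
      tibble(window = w, resolution_hz = fs / w,
             top_feature = NA_character_, importance = 0,
             note = conditionMessage(e))
    })
  })
  if (all(report$importance == 0)) {
    abort("all candidate windows are degenerate (importance 0)")
  }
  best <- max(report$importance)
  chosen <- min(report$window[report$importance >= frac * best])
  structure(list(window = chosen, report = report, frac = frac),
            class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat(sprintf("<window_selection> chosen window: %d samples (>= %.0f%% of best importance)\n",
              x$window, 100 * x$frac))
  print(x$report)
  invisible(x)
}
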