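# CSV traces with JSON sidecars: desk-scale data stays diff-able, and the
# sidecar carries units, class and provenance so a round trip is lossless.

trace_attr_names <- c("fs", "events", "units", "cutoff", "dt", "changes",
                      "update_interval", "thresholds")

#' Write a trace to CSV with a JSON sidecar
#'
#' Times and values are written at full double precision (lossless round
#' trip); the sidecar `<path>.json` records the trace class, units and
#' package-level attributes (sampling rate, cutoff, event/change logs),
#' plus a content hash for `--verify`-style reproducibility checks.
#'
#' @param x A package trace (symptom/LFP/feature/LD/state/closed-loop) or
#'   plain tibble with a `time` column.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, sidecar = TRUE) {
  df <- as_tibble(x)
  # %.17g guarantees a bit-exact double round trip; base R's strtod-based
  # reader parses it back with correct rounding
  out <- as.data.frame(purrr::map(df, function(v) {
    if (is.double(v)) sprintf("%.17g", v) else v
  }), optional = TRUE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (sidecar) {
    attrs <- purrr::compact(purrr::map(
      setNames(trace_attr_names, trace_attr_names),
      function(a) {
        v <- attr(x, a, exact = TRUE)
        if (is.data.frame(v)) as.data.frame(v) else v
      }))
    meta <- list(class = class(x)[1], attrs = attrs,
                 column_types = purrr::map(as_tibble(x), typeof),
                 hash = rlang::hash(as_tibble(x)))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Restores the trace class and attributes from the sidecar; a missing
#' sidecar is tolerated with a warning (a plain tibble is returned). A
#' non-monotone time column is an error.
#'
#' @param path CSV path.
#' @return The reconstructed trace.
#' @export
read_trace <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  if ("time" %in% names(df)) {
    if (is.unsorted(df$time, strictly = TRUE)) {
      abort("time column must be strictly increasing")
    }
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    warn(sprintf("no sidecar found at '%s'; returning a plain tibble", side))
    return(df)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (nm in names(meta$column_types)) {
    if (!nm %in% names(df)) next
    df[[nm]] <- switch(meta$column_types[[nm]],
                       integer = as.integer(df[[nm]]),
                       double = as.double(df[[nm]]),
                       df[[nm]])
  }
  for (a in names(meta$attrs)) {
    v <- meta$attrs[[a]]
    if (is.data.frame(v)) v <- as_tibble(v)
    attr(df, a) <- v
  }
  cls <- meta$class
  if (cls %in% c("symptom_trace", "lfp_recording", "feature_stream",
                 "ld_stream", "state_trace", "closed_loop_trace")) {
    class(df) <- c(cls, class(tibble()))
  }
  df
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    synthetic = list(duration = 600, dt = 0.5, cutoff = 5, baseline = 4,
                     diurnal_amplitude = 2, diurnal_period = 86400,
                     diurnal_phase = 0, flare_amplitude = 3,
                     transition_rate = 1 / 600, noise_sd = 0.5, fs = 500,
                     n_channels = 2, background_sd = 20,
                     background_exponent = 1, biomarkers = NULL),
    sense = list(window = 256, update_interval = 0.5, window_fun = "hann",
                 bands = NULL, channels = NULL),
    ld = list(features = NULL, weights = NULL, norm_mean = NULL,
              norm_sd = NULL, thresholds = NULL, avg_len = 1),
    detector = list(update_interval = 0.5, onset = 1, termination = 1,
                    blanking = 0, thresholds = NULL),
    stimulation = list(amplitudes = c(0, 2), ramp = 1, frequency = 130,
                       pulse_width = 60, tonic_gain = 0),
    tuning = list(percentiles = 50, lag_window = 10, tau_in = 60,
                  tau_out = 60, relief = 2, washin_noise_sd = 0))
}

merge_section <- function(user, defaults, path) {
  if (is.null(user)) return(defaults)
  user <- purrr::discard(user, function(v) length(v) == 0) # JSON/YAML nulls
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste0(path, ".", unknown, collapse = ", ")))
  }
  modifyList(defaults, user)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with nested sections (`synthetic`,
#' `sense`, `ld`, `detector`, `stimulation`, `tuning`, plus global `seed`
#' and `out_dir`), fills documented defaults, rejects unknown keys with a
#' field-path message, and cross-checks that every section sharing the
#' update-interval clock agrees on it.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return A validated `run_config` list with all defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be a .yaml/.yml or .json file")
  }
  validate_run_config(raw %||% list())
}

#' @rdname load_config
#' @param config A (possibly partial) configuration list.
#' @export
validate_run_config <- function(config) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration section(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (nm in setdiff(names(defaults), c("seed", "out_dir"))) {
    cfg[[nm]] <- merge_section(config[[nm]], defaults[[nm]], nm)
  }
  if (!is.null(config$seed)) cfg$seed <- as.integer(config$seed)
  if (!is.null(config$out_dir)) cfg$out_dir <- config$out_dir
  if (abs(cfg$sense$update_interval - cfg$detector$update_interval) > 1e-12) {
    abort(sprintf(
      "clock mismatch: sense.update_interval (%g) != detector.update_interval (%g)",
      cfg$sense$update_interval, cfg$detector$update_interval))
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#' @param config A `run_config` (or compatible list).
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Save or load a discriminant configuration as JSON
#'
#' The device-style interchange format: keys `features`, `weights`,
#' `norm_mean`, `norm_sd`, `thresholds`, `avg_len`.
#'
#' @param cfg An [ld_config()].
#' @param path JSON path.
#' @return `path` invisibly, or the reconstructed `ld_config`.
#' @export
save_ld_config <- function(cfg, path) {
  jsonlite::write_json(
    list(features = cfg$features, weights = cfg$weights,
         norm_mean = cfg$norm$mean, norm_sd = cfg$norm$sd,
         thresholds = cfg$thresholds, avg_len = cfg$avg_len),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_ld_config
#' @export
load_ld_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ld_config(x$features, x$weights,
            tibble(feature = x$features, mean = x$norm_mean,
                   sd = x$norm_sd),
            thresholds = if (length(x$thresholds)) x$thresholds else NULL,
            avg_len = x$avg_len)
}
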