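#' Normalize band-power features
#'
#' The embedded classifier expects each input feature scaled to mean 0 and
#' standard deviation 1 (the device default), so that no feature dominates
#' the discriminant through sheer power scale. With `stats = "fit"` the
#' normalization constants are estimated from the stream itself; supplying
#' a stats table applies a fixed, previously fitted transform (as a device
#' would at run time).
#'
#' @param features A `feature_stream` (or tibble with a `time` column).
#' @param stats `"fit"`, or a tibble with columns `feature`, `mean`, `sd`.
#' @return The normalized stream (same class), with the stats attached as
#'   attribute `"norm"` (retrieve with [norm_stats()]).
#' @examples
#' fs <- tibble::tibble(time = 1:5, ch1_theta = c(1, 4, 2, 8, 5))
#' z <- normalize_features(fs)
#' colMeans(z[-1]) # ~0
#' @export
normalize_features <- function(features, stats = "fit") {
  nms <- value_cols(features)
  if (identical(stats, "fit")) {
    stats <- purrr::map_dfr(nms, function(nm) {
      s <- sd(features[[nm]])
      if (!is.finite(s) || s == 0) {
        abort(sprintf("feature '%s' has zero variance; cannot fit normalization", nm))
      }
      tibble(feature = nm, mean = mean(features[[nm]]), sd = s)
    })
  } else {
    stopifnot(is.data.frame(stats),
              all(c("feature", "mean", "sd") %in% names(stats)))
    if (any(stats$sd <= 0)) abort("normalization sds must be positive")
  }
  out <- features
  for (nm in nms) {
    row <- match(nm, stats$feature)
    if (is.na(row)) abort(sprintf("no normalization stats for feature '%s'", nm))
    out[[nm]] <- (features[[nm]] - stats$mean[row]) / stats$sd[row]
  }
  attr(out, "norm") <- stats
  out
}

#' Normalization constants attached to a stream
#' @param x A stream returned by [normalize_features()].
#' @return Tibble with `feature`, `mean`, `sd`.
#' @export
norm_stats <- function(x) attr(x, "norm", exact = TRUE)

#' Linear discriminant configuration
#'
#' The full parameter set of the embedded classifier: which features feed
#' the discriminant (at most two, matching the devices), their signed
#' weights, per-feature normalization constants, the detector threshold(s)
#' in LD units, and how many successive FFT outputs are averaged (trailing,
#' causal) before thresholding.
#'
#' @param features Character vector of 1 or 2 feature column names.
#' @param weights Signed weights, one per feature; at least one nonzero. A
#'   negative weight on a stimulation-band feature implements the
#'   stimulation-tracking negative-feedback strategy.
#' @param norm Tibble `feature`, `mean`, `sd` (sd > 0).
#' @param thresholds `NULL`, or 1--2 ascending thresholds in LD units.
#' @param avg_len Trailing moving-average length in updates (>= 1).
#' @return An `ld_config` list.
#' @export
ld_config <- function(features, weights, norm, thresholds = NULL,
                      avg_len = 1) {
  if (length(features) < 1 || length(features) > 2) {
    abort("the embedded discriminant accepts 1 or 2 input features")
  }
  if (length(weights) != length(features)) {
    abort("`weights` must match `features` in length")
  }
  if (all(weights == 0)) abort("at least one weight must be nonzero")
  stopifnot(is.data.frame(norm),
            all(c("feature", "mean", "sd") %in% names(norm)))
  if (!all(features %in% norm$feature)) {
    abort("`norm` must provide stats for every feature")
  }
  if (any(norm$sd <= 0)) abort("normalization sds must be positive")
  if (!is.null(thresholds)) {
    if (length(thresholds) > 2) abort("at most 2 thresholds are supported")
    if (is.unsorted(thresholds, strictly = TRUE)) {
      abort("thresholds must be strictly increasing")
    }
  }
  check_scalar(avg_len, "avg_len", lower = 1)
  structure(list(features = features, weights = as.numeric(weights),
                 norm = as_tibble(norm)[match(features, norm$feature), ],
                 thresholds = thresholds, avg_len = as.integer(avg_len)),
            class = "ld_config")
}

#' Fit Fisher linear-discriminant weights from labeled features
#'
#' The classifier-programming step: fits the normalization constants
#' (mean 0, sd 1) on the supplied stream, then computes the Fisher
#' discriminant direction — pooled within-class covariance inverse times
#' the class-mean difference — which maximizes between-class separation
#' among linear projections. Weights are scaled to unit norm (so
#' thresholds are comparable across fits) and signed so the high-symptom
#' class has the higher mean LD.
#'
#' @param features A `feature_stream` with 1 or 2 feature columns (subset
#'   with `feature_names` if the stream carries more).
#' @param labels Binary vector (0/1) with one label per update, or a
#'   `symptom_trace` whose state is resampled to the feature clock by
#'   previous-value hold.
#' @param feature_names Optional: which columns to use (1 or 2).
#' @param avg_len,thresholds Stored in the returned config (see
#'   [ld_config()]).
#' @return An `lda_fit` (also an `ld_config`) with training diagnostics;
#'   see [tidy.lda_fit()] and [glance.lda_fit()].
#' @export
fit_lda <- function(features, labels, feature_names = NULL, avg_len = 1,
                    thresholds = NULL) {
  nms <- feature_names %||% value_cols(features)
  if (length(nms) > 2) {
    abort("the embedded discriminant accepts at most 2 features; pick them with `feature_names`")
  }
  if (inherits(labels, "symptom_trace")) {
    labels <- hold_resample(labels$time, labels$state, features$time)
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    abort("`labels` must provide one label per update")
  }
  if (length(unique(labels)) < 2) {
    abort("both symptom classes must be present to fit the discriminant")
  }
  norm_str <- normalize_features(features[c("time", nms)], stats = "fit")
  Z <- as.matrix(as_tibble(norm_str)[nms])
  m0 <- colMeans(Z[labels == 0, , drop = FALSE])
  m1 <- colMeans(Z[labels == 1, , drop = FALSE])
  d <- m1 - m0
  if (sqrt(sum(d^2)) < 1e-12) {
    abort("identical class means: no separation to fit")
  }
  n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  S0 <- stats::cov(Z[labels == 0, , drop = FALSE])
  S1 <- stats::cov(Z[labels == 1, , drop = FALSE])
  Sw <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  w <- tryCatch(solve(Sw, d), error = function(e) {
    abort("singular pooled covariance: features are collinear")
  })
  w <- w / sqrt(sum(w^2))
  if (sum(w * d) < 0) w <- -w # high-symptom class gets the higher LD
  cfg <- ld_config(nms, w, norm_stats(norm_str), thresholds = thresholds,
                   avg_len = avg_len)
  ld <- drop(Z %*% w)
  mid <- (mean(ld[labels == 1]) + mean(ld[labels == 0])) / 2
  cfg$training <- list(
    n0 = n0, n1 = n1,
    class_means = c(mean(ld[labels == 0]), mean(ld[labels == 1])),
    midpoint = mid,
    accuracy = mean((ld >= mid) == (labels == 1)),
    fisher_ratio = (mean(ld[labels == 1]) - mean(ld[labels == 0]))^2 /
      (((n0 - 1) * var(ld[labels == 0]) + (n1 - 1) * var(ld[labels == 1])) /
         (n0 + n1 - 2)))
  class(cfg) <- c("lda_fit", class(cfg))
  cfg
}

#' @export
print.ld_config <- function(x, ...) {
  cat("<ld_config>\n  features:", paste(x$features, collapse = ", "),
      "\n  weights: ", paste(signif(x$weights, 4), collapse = ", "),
      "\n  avg_len: ", x$avg_len, "\n")
  if (!is.null(x$thresholds)) {
    cat("  thresholds:", paste(signif(x$thresholds, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted discriminant
#' @param x An `lda_fit`.
#' @param ... Unused.
#' @return One row per feature: `term`, `weight`, `norm_mean`, `norm_sd`.
#' @export
tidy.lda_fit <- function(x, ...) {
  tibble(term = x$features, weight = x$weights,
         norm_mean = x$norm$mean, norm_sd = x$norm$sd)
}

#' One-row summary of a fitted discriminant
#' @param x An `lda_fit`.
#' @param ... Unused.
#' @return Tibble with class sizes, class-mean LD separation, Fisher
#'   ratio, midpoint threshold and training accuracy at that threshold.
#' @export
glance.lda_fit <- function(x, ...) {
  tr <- x$training
  tibble(n0 = tr$n0, n1 = tr$n1,
         ld_mean_low = tr$class_means[1], ld_mean_high = tr$class_means[2],
         fisher_ratio = tr$fisher_ratio, midpoint = tr$midpoint,
         training_accuracy = tr$accuracy)
}

# Trailing (causal) moving average with partial windows at the start;
# written as an explicit mean over the trailing buffer so that streaming
# (closed-loop) computation is bit-identical to batch.
trailing_mean <- function(x, len) {
  if (len <= 1) return(x)
  vapply(seq_along(x), function(i) mean(x[max(1, i - len + 1):i]), numeric(1))
}

#' Compute the streaming linear-discriminant output
#'
#' Per update: normalize the configured features with the stored constants,
#' form the weighted sum, then apply the trailing moving average of
#' `avg_len` updates. This is the value the device compares against its
#' threshold(s).
#'
#' @param features A `feature_stream` containing the configured features.
#' @param cfg An [ld_config()] / [fit_lda()] result.
#' @return An `ld_stream`: tibble `time`, `ld`, plus the normalized
#'   features as `z_*` columns; thresholds (if any) travel as an attribute.
#' @export
ld_output <- function(features, cfg) {
  if (!inherits(cfg, "ld_config")) abort("`cfg` must be an ld_config")
  missing <- setdiff(cfg$features, names(features))
  if (length(missing)) {
    abort(paste("features absent from stream:", paste(missing, collapse = ", ")))
  }
  z <- purrr::map2(cfg$features, seq_along(cfg$features), function(nm, i) {
    (features[[nm]] - cfg$norm$mean[i]) / cfg$norm$sd[i]
  })
  raw <- Reduce(`+`, purrr::map2(z, cfg$weights, `*`))
  out <- tibble(time = features$time, ld = trailing_mean(raw, cfg$avg_len))
  for (i in seq_along(cfg$features)) {
    out[[paste0("z_", cfg$features[i])]] <- z[[i]]
  }
  structure(out, class = c("ld_stream", class(tibble())),
            thresholds = cfg$thresholds,
            update_interval = if (nrow(out) > 1) diff(out$time[1:2]) else NA_real_)
}
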