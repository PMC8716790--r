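test_that("a 6 Hz tone concentrates power in theta, not beta", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  rec <- make_recording(10 * sin(2 * pi * 6 * t), fs = fs)
  fe <- compute_band_power(rec, sense_config(window = 256,
                                             update_interval = 1))
  expect_gt(mean(fe$ch1_theta) / mean(fe$ch1_beta), 100)
})

test_that("band powers match an independent DFT periodogram oracle", {
  fs <- 128
  bands <- tibble::tibble(label = c("lo", "mid", "hi"),
                          low = c(4, 20, 50), high = c(12, 40, 60))
  withr::with_seed(7, x <- rnorm(6 * fs))
  rec <- make_recording(x, fs = fs)
  for (wf in c("rect", "hann")) {
    w <- 64
    cfg <- sense_config(bands = bands, window = w, update_interval = 1,
                        window_fun = wf)
    fe <- compute_band_power(rec, cfg)
    taper <- if (wf == "rect") rep(1, w) else {
      0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
    }
    centers <- (0:(w %/% 2)) * fs / w
    for (k in seq_len(nrow(fe))) {
      e <- round(fe$time[k] * fs)
      p <- oracle_periodogram(x[(e - w + 1):e], taper)
      for (b in seq_len(nrow(bands))) {
        expected <- mean(p[centers >= bands$low[b] &
                             centers < bands$high[b]])
        got <- fe[[paste0("ch1_", bands$label[b])]][k]
        expect_equal(got, expected, tolerance = 1e-9)
      }
    }
  }
})

test_that("single-bin band powers sum to the windowed variance (Parseval)", {
  fs <- 128
  w <- 128
  withr::with_seed(8, x <- rnorm(w))
  rec <- make_recording(x, fs = fs)
  df <- fs / w
  # one band per periodogram bin below Nyquist; the Nyquist bin itself is
  # taken from the oracle and added to complete the partition
  bands <- tibble::tibble(label = paste0("b", 0:(w / 2 - 1)),
                          low = (0:(w / 2 - 1)) * df - df / 2,
                          high = (0:(w / 2 - 1)) * df + df / 2)
  bands$low[1] <- 0
  cfg <- sense_config(bands = bands, window = w, update_interval = w / fs,
                      window_fun = "rect")
  fe <- compute_band_power(rec, cfg)
  nyquist_bin <- oracle_periodogram(x)[w / 2 + 1]
  total <- sum(as.numeric(fe[1, -1])) + nyquist_bin
  expect_equal(total, mean((x - mean(x))^2), tolerance = 1e-9)
})

test_that("adding an orthogonal-band tone barely moves theta power", {
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  withr::with_seed(9, base <- rnorm(length(t), sd = 5))
  rec_a <- make_recording(base, fs = fs)
  rec_b <- make_recording(base + 20 * sin(2 * pi * 40 * t), fs = fs)
  cfg <- sense_config(window = 256, update_interval = 1)
  pa <- compute_band_power(rec_a, cfg)$ch1_theta
  pb <- compute_band_power(rec_b, cfg)$ch1_theta
  expect_lt(abs(mean(pb) - mean(pa)) / mean(pa), 0.01)
})

test_that("a feature equal to the score has correlation one", {
  tr <- generate_symptom_trace(300, dt = 1, seed = 14)
  rec <- generate_lfp(tr, fs = 250, n_channels = 1, seed = 15)
  fe <- compute_band_power(rec, sense_config(window = 256,
                                             update_interval = 1))
  fe$ch1_theta <- stats::approx(tr$time, tr$score, xout = fe$time,
                                method = "constant", f = 0, rule = 2)$y
  rk <- rank_features(fe, tr)
  expect_equal(rk$correlation[rk$feature == "ch1_theta"], 1)
  expect_equal(rk$feature[1], "ch1_theta")
})

test_that("a permuted feature falls below the permutation-null bound", {
  tr <- generate_symptom_trace(400, dt = 1, seed = 16)
  rec <- generate_lfp(tr, biomarker_spec(1, c(4, 8), 25, 400), fs = 250,
                      n_channels = 1, seed = 17)
  fe <- compute_band_power(rec, sense_config(window = 256,
                                             update_interval = 1))
  withr::with_seed(18, fe$ch1_beta <- sample(fe$ch1_beta))
  rk <- rank_features(fe, tr)
  # permutation-null oracle for |cor| of the shuffled feature
  score <- stats::approx(tr$time, tr$score, xout = fe$time,
                         method = "constant", f = 0, rule = 2)$y
  null_imp <- withr::with_seed(19, vapply(1:200, function(i) {
    abs(cor(sample(fe$ch1_beta), score))
  }, numeric(1)))
  expect_lt(rk$importance[rk$feature == "ch1_beta"],
            quantile(null_imp, 0.95) + 0.05)
  expect_gt(rk$importance[1], quantile(null_imp, 0.95))
})

test_that("the constructed biomarker ranks first among 4 channels x 5 bands", {
  tr <- generate_symptom_trace(400, dt = 1, baseline = 3,
                               diurnal_amplitude = 0, flare_amplitude = 4,
                               transition_rate = 1 / 100, noise_sd = 0.1,
                               seed = 20)
  rec <- generate_lfp(tr, biomarker_spec(2, c(4, 8), 25, 400), fs = 250,
                      n_channels = 4, background_sd = 5, seed = 21)
  fe <- compute_band_power(rec, sense_config(window = 256,
                                             update_interval = 1))
  rk <- rank_features(fe, tr)
  expect_equal(nrow(rk), 20)
  expect_equal(rk$feature[1], "ch2_theta")
})

test_that("zero-variance features are flagged with importance zero", {
  fe <- tibble::tibble(time = 1:50, ch1_theta = rnorm(50), ch1_beta = 1)
  fe <- cldbs:::new_feature_stream(fe, sense_config())
  tr <- make_trace(runif(50, 0, 10), dt = 1)
  rk <- rank_features(fe, tr)
  row <- rk[rk$feature == "ch1_beta", ]
  expect_true(row$degenerate)
  expect_equal(row$importance, 0)
})

test_that("rank correlation is invariant to monotone score rescaling", {
  withr::with_seed(23, {
    fe <- tibble::tibble(time = 1:200, ch1_theta = rnorm(200),
                         ch1_beta = rnorm(200))
  })
  fe <- cldbs:::new_feature_stream(fe, sense_config())
  score <- (fe$ch1_theta - min(fe$ch1_theta)) /
    diff(range(fe$ch1_theta)) * 10
  tr1 <- make_trace(score, dt = 1)
  tr2 <- make_trace(10 * (score / 10)^3, dt = 1) # strictly monotone map
  r1 <- rank_features(fe, tr1, method = "spearman")
  r2 <- rank_features(fe, tr2, method = "spearman")
  expect_equal(r1$correlation, r2$correlation)
})

test_that("window screening keeps the finest window that resolves the band", {
  fs <- 256
  tr <- generate_symptom_trace(400, dt = 1, baseline = 3,
                               diurnal_amplitude = 0, flare_amplitude = 4,
                               transition_rate = 1 / 100, noise_sd = 0.1,
                               seed = 24)
  rec <- generate_lfp(tr, biomarker_spec(1, c(4, 8), 25, 400), fs = fs,
                      n_channels = 1, background_sd = 5, seed = 25)
  # 32 samples -> 8 Hz bins: theta [4, 8) holds no bin center and is
  # reported degenerate; 256 samples -> 1 Hz resolution wins
  sel <- select_window(rec, tr, candidates = c(32, 256),
                       update_interval = 1)
  expect_equal(sel$window, 256)
  expect_equal(sel$report$importance[sel$report$window == 32], 0)
})

test_that("equal importance favours the smaller window; singleton passes through", {
  fs <- 256
  tr <- generate_symptom_trace(300, dt = 1, baseline = 3,
                               diurnal_amplitude = 0, flare_amplitude = 4,
                               transition_rate = 1 / 100, noise_sd = 0.1,
                               seed = 26)
  rec <- generate_lfp(tr, biomarker_spec(1, c(4, 8), 25, 400), fs = fs,
                      n_channels = 1, background_sd = 5, seed = 27)
  sel1 <- select_window(rec, tr, candidates = 512, update_interval = 2)
  expect_equal(sel1$window, 512)
  # the stated rule: the smallest window within `frac` of the best
  # importance wins, so equal importances favour the smaller window
  sel2 <- select_window(rec, tr, candidates = c(256, 512),
                        update_interval = 2)
  rpt <- sel2$report
  expect_equal(sel2$window,
               min(rpt$window[rpt$importance >= 0.95 * max(rpt$importance)]))
  expect_equal(nrow(rpt), 2)
})
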