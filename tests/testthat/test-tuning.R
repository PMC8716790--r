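test_that("an extreme percentile threshold sits at the maximum", {
  ld <- tibble::tibble(time = 1:100, ld = as.numeric(1:100))
  rep100 <- select_threshold(ld, percentiles = 100)
  expect_equal(unname(rep100$thresholds), 100)
  # with >= comparison only the single maximal update is "above"
  cfg <- detector_config(rep100$thresholds[[1]], update_interval = 1)
  dc <- duty_cycle(run_detector(ld, cfg))
  expect_equal(dc$fraction[dc$state == 1L], 1 / 100)
})

test_that("two percentiles give ordered thresholds and a sane report", {
  withr::with_seed(70, ld <- rnorm(5000))
  rep2 <- select_threshold(ld, percentiles = c(25, 75))
  expect_lt(rep2$thresholds[[1]], rep2$thresholds[[2]])
  expect_equal(rep2$predicted_duty$predicted_above, c(0.75, 0.25))
  expect_true(!is.unsorted(rep2$reference$ld))
  expect_equal(sum(rep2$histogram$count), 5000)
  expect_match(rep2$convention, "linear interpolation")
})

test_that("threshold selection validates its inputs", {
  expect_error(select_threshold(rnorm(50)), "at least 100")
  expect_error(select_threshold(rnorm(200), percentiles = c(75, 25)),
               "increasing")
  expect_error(select_threshold(rnorm(200), percentiles = 0), "0, 100")
})

test_that("a 50th-percentile threshold halves occupancy on an independent realization", {
  # stationary AR(1) LD streams; threshold from realization A applied to B
  ar1 <- function(n, phi = 0.8) {
    x <- numeric(n)
    e <- rnorm(n)
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
    x
  }
  withr::with_seed(71, {
    a <- ar1(10000)
    b <- ar1(10000)
  })
  thr <- select_threshold(a, percentiles = 50)$thresholds[[1]]
  cfg <- detector_config(thr, update_interval = 1)
  dc <- duty_cycle(run_detector(b, cfg))
  expect_equal(dc$fraction[dc$state == 1L], 0.5, tolerance = 0.1)
})

test_that("same-stream occupancy equals (100 - p)/100 exactly (CDF identity)", {
  withr::with_seed(72, ld <- rnorm(2000))
  for (p in c(30, 50, 80)) {
    thr <- select_threshold(ld, percentiles = p)$thresholds[[1]]
    cfg <- detector_config(thr, update_interval = 1)
    dc <- duty_cycle(run_detector(ld, cfg))
    above <- dc$fraction[dc$state == 1L]
    expect_equal(above, (100 - p) / 100, tolerance = 1.5 / 2000)
  }
})

test_that("detection scoring handles perfect, inverted and chance detectors", {
  withr::with_seed(73, sym <- rbinom(2000, 1, 0.5))
  tr <- make_trace(ifelse(sym == 1, 8, 2), dt = 1)
  as_states <- function(s) cldbs:::new_state_trace(
    tibble::tibble(time = tr$time, state = as.integer(s)),
    changes = tibble::tibble())
  perfect <- evaluate_detection(as_states(sym), tr)
  expect_equal(perfect$agreement, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$false_positive_rate, 0)
  expect_equal(perfect$latency, 0)
  inverted <- evaluate_detection(as_states(1 - sym), tr)
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$false_positive_rate, 1)
  withr::with_seed(74, rand <- rbinom(2000, 1, 0.5))
  chance <- evaluate_detection(as_states(rand), tr)
  expect_equal(chance$agreement, 0.5, tolerance = 0.05)
})

test_that("noiseless wash-in/wash-out recovery is exact", {
  base <- generate_symptom_trace(1200, dt = 1, baseline = 7,
                                 diurnal_amplitude = 0,
                                 flare_amplitude = 0, transition_rate = 0,
                                 noise_sd = 0)
  pm <- patient_model(base, tau_in = 60, tau_out = 90, relief = 3)
  fit <- washin_washout(pm, protocol = tibble::tibble(
    time = c(0, 100, 700), amplitude = c(0, 1, 0)))
  expect_equal(fit$tau_in, 60, tolerance = 1e-6)
  expect_equal(fit$tau_out, 90, tolerance = 1e-6)
  expect_true(fit$converged_in && fit$converged_out)
})

test_that("symmetric time constants give symmetric estimates", {
  base <- generate_symptom_trace(1500, dt = 1, baseline = 6,
                                 diurnal_amplitude = 0,
                                 flare_amplitude = 0, transition_rate = 0,
                                 noise_sd = 0)
  pm <- patient_model(base, tau_in = 120, tau_out = 120, relief = 2)
  fit <- washin_washout(pm, protocol = tibble::tibble(
    time = c(0, 100, 800), amplitude = c(0, 2, 0)))
  expect_equal(fit$tau_in, fit$tau_out, tolerance = 1e-6)
})

test_that("noisy wash-in estimates are unbiased within 10% over 20 seeds", {
  base <- generate_symptom_trace(1800, dt = 1, baseline = 7,
                                 diurnal_amplitude = 0,
                                 flare_amplitude = 0, transition_rate = 0,
                                 noise_sd = 0)
  pm <- patient_model(base, tau_in = 120, tau_out = 120, relief = 3)
  prot <- tibble::tibble(time = c(0, 300, 1000), amplitude = c(0, 1, 0))
  errs <- vapply(1:20, function(s) {
    fit <- washin_washout(pm, protocol = prot, noise_sd = 0.3, seed = s)
    abs(fit$tau_in - 120) / 120
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})

test_that("wash estimates sharpen as the step duration grows", {
  tau <- 30
  mean_rel_err <- function(phase) {
    total <- 100 + 2 * phase
    base <- generate_symptom_trace(total, dt = 1, baseline = 7,
                                   diurnal_amplitude = 0,
                                   flare_amplitude = 0,
                                   transition_rate = 0, noise_sd = 0)
    pm <- patient_model(base, tau_in = tau, tau_out = tau, relief = 3)
    prot <- tibble::tibble(time = c(0, 50, 50 + phase),
                           amplitude = c(0, 1, 0))
    est <- vapply(1:30, function(s) {
      washin_washout(pm, protocol = prot, noise_sd = 0.5, seed = s)$tau_in
    }, numeric(1))
    mean(abs(est - tau) / tau)
  }
  # phases of 2, 5 and 20 time constants
  errs <- vapply(c(60, 150, 600), mean_rel_err, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("a one-cell grid search returns that cell", {
  scn <- high_snr_scenario(duration = 150, seed = 42)
  gs <- grid_search(scn, grid = list(onset = 2), seed = 5)
  expect_equal(nrow(gs$results), 1)
  expect_equal(glance(gs)$onset, 2)
  expect_true(tidy(gs)$chosen)
})

test_that("a lower threshold percentile never delivers less energy", {
  scn <- high_snr_scenario(duration = 300, seed = 42)
  gs <- grid_search(scn, grid = list(percentile = c(30, 80)), seed = 5)
  res <- gs$results
  expect_gte(res$energy[res$percentile == 30],
             res$energy[res$percentile == 80])
})

test_that("grid search is reproducible and picks a high-agreement cell", {
  scn <- high_snr_scenario(duration = 300, seed = 42)
  grid <- list(onset = c(1, 2), termination = c(1, 2))
  g1 <- grid_search(scn, grid = grid, seed = 6)
  g2 <- grid_search(scn, grid = grid, seed = 6)
  expect_identical(g1$results, g2$results)
  expect_identical(g1$chosen, g2$chosen)
  expect_gt(glance(g1)$agreement, 0.9)
})

test_that("grid search enforces its cell cap and axis names", {
  scn <- high_snr_scenario(duration = 60, seed = 42)
  expect_error(grid_search(scn, grid = list(bogus = 1)), "unknown grid axes")
  expect_error(grid_search(scn, grid = list(onset = 1:30,
                                            termination = 1:30),
                           cap = 500), "cap")
})
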