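test_that("fitted normalization yields mean 0 and sd 1 per feature", {
  withr::with_seed(30, {
    fe <- tibble::tibble(time = 1:500,
                         ch1_theta = rexp(500, rate = 0.01),
                         ch2_beta = rnorm(500, mean = 40, sd = 7))
  })
  z <- normalize_features(fe)
  for (nm in c("ch1_theta", "ch2_beta")) {
    expect_lt(abs(mean(z[[nm]])), 1e-10)
    expect_lt(abs(sd(z[[nm]]) - 1), 1e-10)
  }
  expect_equal(sort(norm_stats(z)$feature), sort(c("ch1_theta", "ch2_beta")))
})

test_that("supplied (0, 1) stats are the identity transform", {
  fe <- tibble::tibble(time = 1:10, ch1_theta = rnorm(10))
  stats <- tibble::tibble(feature = "ch1_theta", mean = 0, sd = 1)
  z <- normalize_features(fe, stats)
  expect_identical(z$ch1_theta, fe$ch1_theta)
})

test_that("zero-variance features cannot be normalization-fitted", {
  fe <- tibble::tibble(time = 1:10, ch1_theta = rep(2, 10))
  expect_error(normalize_features(fe), "zero variance")
})

test_that("separation along one axis puts negligible weight on the other", {
  withr::with_seed(31, {
    n <- 5000
    labels <- rep(0:1, each = n / 2)
    fe <- tibble::tibble(time = 1:n,
                         f1 = rnorm(n, mean = 2 * labels),
                         f2 = rnorm(n))
  })
  fit <- fit_lda(fe, labels)
  expect_lt(abs(fit$weights[2]), 0.05)
  expect_gt(fit$weights[1], 0.99)
  # closed-form Fisher solution: w proportional to Sigma^-1 (mu1 - mu0) = (2, 0)
  expect_gt(abs(sum(fit$weights * c(1, 0))), 0.99)
})

test_that("identical class means raise an error", {
  withr::with_seed(32, {
    fe <- tibble::tibble(time = 1:200, f1 = rep(rnorm(100), 2))
  })
  labels <- rep(0:1, each = 100)
  expect_error(fit_lda(fe, labels), "separation")
})

test_that("single-class input and >2 features are rejected", {
  fe <- tibble::tibble(time = 1:20, f1 = rnorm(20))
  expect_error(fit_lda(fe, rep(1, 20)), "both symptom classes")
  fe3 <- tibble::tibble(time = 1:20, a = rnorm(20), b = rnorm(20),
                        c = rnorm(20))
  expect_error(fit_lda(fe3, rep(0:1, 10)), "at most 2")
})

test_that("fitted weights recover the generating direction", {
  d <- c(2, 1) / sqrt(5)
  withr::with_seed(33, {
    n <- 10000
    labels <- rep(0:1, each = n / 2)
    shift <- 1.5 * labels
    fe <- tibble::tibble(time = 1:n,
                         f1 = rnorm(n) + shift * d[1],
                         f2 = rnorm(n) + shift * d[2])
  })
  fit <- fit_lda(fe, labels)
  expect_gt(abs(sum(fit$weights * d)), 0.99)
  expect_equal(sqrt(sum(fit$weights^2)), 1, tolerance = 1e-12)
  # sign convention: high-symptom class has the higher LD mean
  expect_gt(fit$training$class_means[2], fit$training$class_means[1])
})

test_that("Fisher weights agree with MASS::lda as an independent cross-check", {
  skip_if_not_installed("MASS")
  withr::with_seed(34, {
    n <- 2000
    labels <- rep(0:1, each = n / 2)
    fe <- tibble::tibble(time = 1:n,
                         f1 = rnorm(n, mean = labels, sd = 1),
                         f2 = 0.5 * rnorm(n) + 0.8 * labels)
  })
  fit <- fit_lda(fe, labels)
  z <- scale(as.matrix(fe[c("f1", "f2")]))
  m <- MASS::lda(z, grouping = labels)
  ref <- drop(m$scaling) / sqrt(sum(m$scaling^2))
  expect_gt(abs(sum(fit$weights * ref)), 0.9999)
})

test_that("weights (1, 0) project onto the first normalized feature", {
  withr::with_seed(35, {
    fe <- tibble::tibble(time = 1:100, f1 = rnorm(100, 5, 2),
                         f2 = rnorm(100))
  })
  norm <- norm_stats(normalize_features(fe))
  cfg <- ld_config(c("f1", "f2"), c(1, 0), norm)
  out <- ld_output(fe, cfg)
  expect_equal(out$ld, (fe$f1 - norm$mean[1]) / norm$sd[1])
})

test_that("trailing averaging reduces white-feature variance by ~1/L", {
  withr::with_seed(36, {
    fe <- tibble::tibble(time = 1:20000, f1 = rnorm(20000))
  })
  norm <- tibble::tibble(feature = "f1", mean = 0, sd = 1)
  v1 <- var(ld_output(fe, ld_config("f1", 1, norm, avg_len = 1))$ld)
  L <- 8
  vL <- var(ld_output(fe, ld_config("f1", 1, norm, avg_len = L))$ld[-(1:L)])
  expect_equal(vL / v1, 1 / L, tolerance = 0.15)
})

test_that("a negative-weight stimulation feature strictly lowers the LD", {
  withr::with_seed(37, {
    fe <- tibble::tibble(time = 1:100, f1 = rnorm(100),
                         stim = runif(100, 1, 2)) # stimulation on: positive
  })
  norm <- tibble::tibble(feature = c("f1", "stim"), mean = c(0, 0),
                         sd = c(1, 1))
  with_neg <- ld_output(fe, ld_config(c("f1", "stim"), c(1, -0.5), norm))
  without <- ld_output(fe, ld_config(c("f1", "stim"), c(1, 0), norm))
  expect_true(all(with_neg$ld < without$ld))
})

test_that("the LD stream is invariant to raw-feature rescaling after refit", {
  withr::with_seed(38, {
    fe <- tibble::tibble(time = 1:300, f1 = rexp(300), f2 = rnorm(300, 4))
  })
  labels <- rep(0:1, 150)
  fe_scaled <- fe
  fe_scaled$f1 <- fe$f1 * 7.3
  a <- ld_output(fe, fit_lda(fe, labels))
  b <- ld_output(fe_scaled, fit_lda(fe_scaled, labels))
  expect_equal(a$ld, b$ld, tolerance = 1e-9)
})

test_that("Fisher training accuracy beats any single-feature threshold rule", {
  # brute-force threshold sweep oracle on a small correlated-feature case
  withr::with_seed(39, {
    n <- 400
    labels <- rep(0:1, each = n / 2)
    f1 <- rnorm(n) + 1.2 * labels
    f2 <- 0.7 * f1 + rnorm(n) * 0.5 + 0.4 * labels
    fe <- tibble::tibble(time = 1:n, f1 = f1, f2 = f2)
  })
  fit <- fit_lda(fe, labels)
  best_single <- max(vapply(c("f1", "f2"), function(nm) {
    x <- fe[[nm]]
    max(vapply(sort(unique(x)), function(th) {
      max(mean((x >= th) == labels), mean((x < th) == labels))
    }, numeric(1)))
  }, numeric(1)))
  # Fisher LD with its own best threshold
  z <- scale(as.matrix(fe[c("f1", "f2")]))
  ld <- drop(z %*% fit$weights)
  best_ld <- max(vapply(sort(unique(ld)), function(th) {
    mean((ld >= th) == labels)
  }, numeric(1)))
  expect_gte(best_ld, best_single - 0.02)
})

test_that("streaming LD computation equals batch bit-for-bit", {
  withr::with_seed(40, {
    fe <- tibble::tibble(time = 1:500, f1 = rnorm(500), f2 = rexp(500))
  })
  norm <- tibble::tibble(feature = c("f1", "f2"), mean = c(0, 1),
                         sd = c(1, 2))
  cfg <- ld_config(c("f1", "f2"), c(0.8, -0.6), norm, avg_len = 7)
  batch <- ld_output(fe, cfg)$ld
  # incremental recomputation with a trailing buffer, as a device would
  buf <- numeric(0)
  stream <- vapply(seq_len(nrow(fe)), function(i) {
    z1 <- (fe$f1[i] - 0) / 1
    z2 <- (fe$f2[i] - 1) / 2
    buf <<- c(buf, 0.8 * z1 - 0.6 * z2)
    if (length(buf) > 7) buf <<- buf[-1]
    mean(buf)
  }, numeric(1))
  expect_identical(batch, stream)
})

test_that("ld_config validation catches malformed configurations", {
  norm <- tibble::tibble(feature = c("a", "b"), mean = c(0, 0), sd = c(1, 1))
  expect_error(ld_config(c("a", "b", "c"), c(1, 1, 1), norm), "1 or 2")
  expect_error(ld_config(c("a", "b"), c(0, 0), norm), "nonzero")
  expect_error(ld_config("a", 1, norm, thresholds = c(2, 1)), "increasing")
  expect_error(ld_config("a", 1, tibble::tibble(feature = "a", mean = 0,
                                                sd = 0)), "positive")
  expect_error(ld_output(tibble::tibble(time = 1, x = 1),
                         ld_config("a", 1, norm[1, ])), "absent")
})
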