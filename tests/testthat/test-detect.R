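test_that("adaptive threshold follows both branches and their coincidence", {
  # mu = 0.2, sigma = 0.1 (sigma < mu): kappa * mu * (1 - sigma^2)
  x <- c(0.1, 0.2, 0.3)  # mu = 0.2, population sd = sqrt(0.02/3)
  mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
  expect_equal(compute_threshold(x, 1), mu * (1 - sg^2))
  # second branch: sigma > mu
  y <- c(-0.4, 0.1, 0.6)  # mu = 0.1, sd > mu
  mu <- mean(y); sg <- sqrt(mean((y - mu)^2))
  expect_gt(sg, mu)
  expect_equal(compute_threshold(y, 1), sg * (1 - mu^2))
  expect_error(compute_threshold(numeric(0), 1), "input error")
})

test_that("threshold branches coincide at sigma == mu", {
  # two-point signal {0, 2m} has mu = m and population sd = m
  for (m in c(0.1, 0.3, 0.9)) {
    z <- c(0, 2 * m)
    expect_equal(mean(z), pop_sd_oracle(z))
    expect_equal(compute_threshold(z, 2), 2 * m * (1 - m^2))
  }
})

test_that("apply_threshold keeps strictly greater heights in order", {
  cand <- candidate_peaks(c(10L, 20L, 30L), c(0.1, 0.9, 0.5))
  kept <- apply_threshold(cand, 0.4)
  expect_identical(kept$indices, c(20L, 30L))
  expect_equal(kept$heights, c(0.9, 0.5))
  expect_length(apply_threshold(cand, 1)$indices, 0L)
  expect_identical(apply_threshold(cand, -Inf)$indices, cand$indices)
  # strictness at the boundary
  expect_length(apply_threshold(candidate_peaks(1L, 0.4), 0.4)$indices, 0L)
})

test_that("refractory enforcement keeps the taller of close candidates", {
  cand <- candidate_peaks(c(100L, 150L), c(1.0, 2.0))
  expect_identical(enforce_refractory(cand, 200)$indices, 150L)
  cand <- candidate_peaks(c(100L, 400L), c(1.0, 2.0))
  expect_identical(enforce_refractory(cand, 200)$indices, c(100L, 400L))
  # tie keeps the earlier candidate
  cand <- candidate_peaks(c(100L, 150L), c(1.0, 1.0))
  expect_identical(enforce_refractory(cand, 200)$indices, 100L)
  # cluster: exactly one survivor, the global maximum (brute-force check)
  set.seed(13)
  for (k in 1:10) {
    idx <- sort(sample(1000:1150, 5))
    h <- runif(5)
    out <- enforce_refractory(candidate_peaks(idx, h), 200)
    expect_length(out$indices, 1L)
    expect_equal(out$heights, max(h))
  }
})

test_that("refractory output is always separated by >= the refractory period", {
  set.seed(14)
  for (k in 1:10) {
    idx <- sort(sample.int(5000, 60))
    out <- enforce_refractory(candidate_peaks(idx, runif(60)), 150)
    if (length(out$indices) > 1L)
      expect_true(all(diff(out$indices) >= 150))
  }
})

test_that("R localization refines to the absolute filtered extremum", {
  f <- numeric(1000)
  f[497] <- -2   # true extremum is negative: |f| handles polarity
  f[505] <- 1
  cand <- candidate_peaks(500L, 1.0)
  expect_identical(localize_r_peaks(cand, f, 100)$r_samples, 497L)
  expect_identical(localize_r_peaks(cand, f, 0)$r_samples, 500L)
  # ties resolve leftmost
  g <- numeric(100); g[40] <- 1; g[60] <- 1
  expect_identical(localize_r_peaks(candidate_peaks(50L, 1), g, 30)$r_samples,
                   40L)
})

test_that("the full detector finds every beat of a clean recording", {
  g <- generate_record(synth_config(duration_s = 30, heart_rate_bpm = 60,
                                    rr_jitter_frac = 0, seed = 21))
  expect_length(g$annotations$r_samples, 30L)
  dets <- detect_qrs(g$record)
  expect_length(dets$r_samples, 30L)
  # every detection within 13 ms of ground truth
  offs <- abs(dets$r_samples - g$annotations$r_samples) / g$record$fs
  expect_lt(max(offs), 0.013)
})

test_that("flat or degenerate leads are rejected", {
  rec <- ecg_record("flat", 1000, list(i = numeric(2000)))
  expect_error(detect_qrs(rec), "degenerate input")
  rec <- ecg_record("short", 1000, list(i = rnorm(150)))
  expect_error(detect_qrs(rec), "input error")
})

test_that("tall sharp T waves produce no false positives at T locations", {
  g <- generate_record(scenario_config("tall-T", seed = 22))
  dets <- detect_qrs(g$record)
  counts <- match_beats(dets, g$annotations, 150)
  expect_identical(counts$fp, 0L)
  expect_identical(counts$fn, 0L)
  # specifically: no detection near any T center (R + 200 ms)
  t_centers <- g$annotations$r_samples + 200L
  expect_false(any(abs(outer(dets$r_samples, t_centers, "-")) <= 50))
})

test_that("detection is scale-invariant and deterministic", {
  g <- generate_record(synth_config(duration_s = 20, seed = 23,
                                    white_noise_sd = 0.02))
  d1 <- detect_qrs(g$record)
  d2 <- detect_qrs(g$record)
  expect_identical(d1$r_samples, d2$r_samples)
  for (c in c(1e-3, 0.2, 50)) {
    scaled <- ecg_record(g$record$record_id, g$record$fs,
                         list(ii = c * g$record$samples$ii))
    expect_identical(detect_qrs(scaled)$r_samples, d1$r_samples)
  }
})

test_that("detection count is non-increasing in kappa", {
  g <- generate_record(scenario_config("low-SNR", seed = 24))
  n_prev <- Inf
  for (k in c(0.1, 0.25, 0.5, 1, 2, 4, 8)) {
    n <- length(detect_qrs(g$record, cfg = detector_config(kappa = k))$r_samples)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detector configuration validates its fields", {
  expect_error(detector_config(kappa = -1), "parameter error")
  expect_error(detector_config(band_low = 20, band_high = 16),
               "parameter error")
  expect_error(detector_config(refractory_s = 0), "parameter error")
  cfg <- detector_config()
  expect_s3_class(cfg, "detector_config")
  expect_identical(cfg$band_low, 5)
  expect_identical(cfg$band_high, 16)
})
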