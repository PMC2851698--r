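delta <- 1 / 256

test_that("rll measures the sampled arc length", {
  # constant trace: pure time-axis length (5 * 256 - 1) / 256
  expect_equal(rll(rep(3, 1280), delta), 1279 / 256)
  expect_error(rll(rep(0, 100), delta), "expected 1280 samples")

  # invariant under level shifts, strictly increasing under amplitude scaling
  t5 <- (0:1279) / 256
  w <- sin(2 * pi * 0.25 * t5)
  expect_equal(rll(w + 10, delta), rll(w, delta))
  expect_gt(rll(2 * w, delta), rll(w, delta))

  # brute-force per-step oracle on random windows
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(1280, sd = runif(1, 0.01, 1))
    oracle <- 0
    for (j in 2:1280) oracle <- oracle + sqrt(delta^2 + (x[j] - x[j - 1])^2)
    expect_equal(rll(x, delta), oracle, tolerance = 1e-12)
  }

  # converges to the continuous arc length of a smooth curve
  arc <- stats::integrate(function(t) sqrt(1 + (2 * pi * 0.25 * cos(2 * pi * 0.25 * t))^2),
                          0, 1280 / 256, rel.tol = 1e-10)$value
  expect_lt(abs(rll(w, delta) - arc) / arc, 1e-3)
})

test_that("the shift-averaged profile matches its brute-force composition", {
  fs <- 256
  set.seed(22)
  x <- as.numeric(stats::filter(rnorm(12 * fs), rep(1 / 32, 32), sides = 2))
  x[is.na(x)] <- 0
  prof <- rll_profile(x, fs)
  expect_equal(prof$t, 0:6)
  for (t in prof$t) {
    vals <- vapply(seq(0, 1, by = 0.1), function(s) {
      i0 <- round((t + s) * fs)
      rll(x[(i0 + 1):(i0 + 5 * fs)], 1 / fs)
    }, numeric(1))
    expect_equal(prof$rll_avg[prof$t == t], mean(vals), tolerance = 1e-12)
  }

  # constant trace: every second equals the flat-window value
  pc <- rll_profile(rep(1, 12 * fs), fs)
  expect_true(all(abs(pc$rll_avg - 1279 / 256) < 1e-12))

  # 1-s-periodic breathing: profile is constant over t
  pp <- rll_profile(sin(2 * pi * (0:(12 * fs - 1)) / fs), fs)
  expect_lt(diff(range(pp$rll_avg)), 1e-9)

  expect_error(rll_profile(rep(0, 100), fs), "too short")
})

test_that("trimmed statistics are robust and match an independent oracle", {
  expect_error(fit_resp_threshold(tibble::tibble(rll_avg = rnorm(10))),
               "at least 20")
  expect_warning(
    thr0 <- fit_resp_threshold(tibble::tibble(rll_avg = rep(5, 30))),
    "degenerate")
  expect_equal(thr0$mu_trim, 5)
  expect_equal(thr0$sigma_trim, 0)
  expect_gt(thr0$psi_upper, thr0$psi_lower)

  a <- qnorm(0.95)
  consistency <- sqrt(1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1))
  set.seed(23)
  for (i in 1:100) {
    x <- rnorm(sample(30:200, 1))
    thr <- fit_resp_threshold(tibble::tibble(rll_avg = x))
    k <- floor(0.05 * length(x))
    core <- sort(x)[(k + 1):(length(x) - k)]
    expect_equal(thr$mu_trim, mean(x, trim = 0.05))
    expect_equal(thr$mu_trim, mean(core))
    expect_equal(thr$sigma_trim, sd(core) / consistency)
    expect_equal(thr$psi_lower, thr$mu_trim - 3 * thr$sigma_trim)
    expect_equal(thr$psi_upper, thr$mu_trim + 3 * thr$sigma_trim)
  }

  # 5% gross outliers barely move the trimmed mean (relative change < 1%)
  set.seed(24)
  x <- rnorm(200, mean = 8, sd = 0.3)
  xo <- c(x[1:190], rep(100, 10))
  mu_clean <- fit_resp_threshold(tibble::tibble(rll_avg = x))$mu_trim
  mu_cont <- fit_resp_threshold(tibble::tibble(rll_avg = xo))$mu_trim
  expect_lt(abs(mu_cont - mu_clean) / mu_clean, 0.01)
})

test_that("flagging is strict and covers deep breaths", {
  thr <- fit_resp_threshold(tibble::tibble(rll_avg = rnorm(100, 8, 0.2)))
  prof <- tibble::tibble(t = 0:2,
                         rll_avg = c(thr$psi_upper, thr$psi_lower,
                                     thr$psi_upper + 1e-9))
  fl <- flag_irregular_breaths(prof, thr)
  expect_equal(fl$flag, c(FALSE, FALSE, TRUE))   # boundary not flagged

  # every simulated deep inspiration overlaps at least one flagged second
  base <- simulate_recording(scenario_config(block = "A", seed = 51L))
  thr2 <- fit_resp_threshold(rll_profile(base))
  db <- c(30, 60, 90)
  rec <- simulate_recording(scenario_config(block = "A",
                                            deep_breath_times_s = db,
                                            seed = 52L))
  fl2 <- flag_irregular_breaths(rll_profile(rec), thr2)
  for (tb in db) {
    expect_true(any(fl2$flag & fl2$t < tb + 8 & fl2$t + 5 > tb))
  }
})

test_that("baseline-like breathing is almost never flagged", {
  # thresholds fit on the session's four pooled quiet-rest trials, as the
  # respiration model is refit per session from all baseline signals
  pool <- dplyr::bind_rows(lapply(61:64, function(s)
    rll_profile(simulate_recording(scenario_config(block = "A", seed = s)))))
  thr <- fit_resp_threshold(pool)
  flagged <- unlist(lapply(65:70, function(s) {
    rec <- simulate_recording(scenario_config(block = "A", duration_s = 120,
                                              spontaneous_rate_per_min = 0,
                                              seed = s))
    flag_irregular_breaths(rll_profile(rec), thr)$flag
  }))
  expect_lte(mean(flagged), 0.01)
})
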