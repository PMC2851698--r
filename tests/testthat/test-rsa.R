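make_pulse_train <- function(rate_bpm, dur_s, fs = 256) {
  # constant-rate pulsatile waveform with the generator's pulse shape
  t <- (0:(dur_s * fs - 1)) / fs
  exp(3 * (cos(2 * pi * rate_bpm / 60 * t) - 1))
}

test_that("heart rate is recovered from the pulse waveform", {
  bvp <- make_pulse_train(60, 30)
  hr <- hr_from_bvp(bvp, 256)
  expect_length(hr, length(bvp))
  interior <- (5 * 256):(25 * 256)
  expect_lt(max(abs(hr[interior] - 60)), 0.5)

  # a rate step 60 -> 75 bpm appears as two plateaus
  bvp2 <- c(make_pulse_train(60, 15), make_pulse_train(75, 15))
  hr2 <- hr_from_bvp(bvp2, 256)
  expect_lt(abs(median(hr2[(5 * 256):(10 * 256)]) - 60), 1)
  expect_lt(abs(median(hr2[(25 * 256):(29 * 256)]) - 75), 1)

  expect_error(hr_from_bvp(rep(0.5, 2560), 256), "fewer than 2")

  # simulator ground truth: mean absolute error under 2 bpm
  rec <- rest_recording()
  hr3 <- hr_from_bvp(rec)
  expect_lt(mean(abs(hr3 - attr(rec, "extras")$hr_true)), 2)
})

test_that("standardisation yields exact z-scores and rejects constants", {
  rec <- rest_recording()
  cs <- cardio_series(rec)
  expect_equal(nrow(cs), nrow(rec) - 1L)
  expect_lt(abs(mean(cs$hr_z)), 1e-9)
  expect_lt(abs(sd(cs$hr_z) - 1), 1e-9)
  expect_lt(abs(mean(cs$resp_z)), 1e-9)
  expect_lt(abs(sd(cs$resp_z) - 1), 1e-9)

  # relative change matches its elementwise definition
  hr <- attr(rec, "extras")$hr_true
  cs2 <- cardio_series(rec, hr = hr)
  n <- length(hr)
  expect_equal(cs2$hr_rel, (hr[-1] - hr[-n]) / hr[-n])
  expect_equal(cs2$resp_diff, diff(rec$resp))

  # constant heart rate has zero-variance relative change
  expect_error(cardio_series(rec, hr = rep(70, nrow(rec))), "zero-variance")
})

test_that("window count follows the ceiling formula", {
  expect_equal(n_corr_windows(10, 256), 9L)        # ceil(10 - 1/256) - 1
  expect_equal(n_corr_windows(130, 256), 129L)
  rec <- simulate_recording(scenario_config(block = "A", duration_s = 10,
                                            spontaneous_rate_per_min = 0,
                                            seed = 9L))
  curves <- corr_curves(cardio_series(rec))
  expect_equal(max(curves$window), 9L)
  expect_equal(attr(curves, "n_points"), 513L)
  expect_equal(range(curves$lag_s), c(-1, 1))
})

test_that("cross-correlation curves behave like correlations", {
  # identical channels: the zero-lag value is near 1 and essentially the
  # curve maximum (the peak is a plateau for smooth signals, so the exact
  # argmax among near-ties is not asserted)
  cs <- rest_cardio()
  cs$resp_z <- cs$hr_z
  curves <- corr_curves(cs)
  by_win <- split(curves, curves$window)
  peak_lags <- vapply(by_win, function(d) d$lag_s[which.max(d$value)], numeric(1))
  vals0 <- vapply(by_win, function(d) d$value[d$lag_s == 0], numeric(1))
  maxs <- vapply(by_win, function(d) max(d$value), numeric(1))
  expect_true(all(abs(peak_lags) <= 0.5))
  expect_gt(median(vals0 / maxs), 0.9)
  expect_lt(abs(mean(vals0) - 1), 0.15)

  # lagged sums match a brute-force loop
  set.seed(31)
  x <- rnorm(100)
  y <- rnorm(100)
  got <- edrclass:::lagged_xcorr(x, y, 20)
  lags <- -20:20
  oracle <- vapply(lags, function(l) {
    t <- seq_len(100)
    keep <- t + l >= 1 & t + l <= 100
    sum(x[t[keep]] * y[t[keep] + l]) / (100 - abs(l))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)

  # independent white channels decorrelate as windows grow
  set.seed(32)
  mx <- replicate(100, {
    max(abs(edrclass:::lagged_xcorr(rnorm(512), rnorm(512), 256)))
  })
  expect_lt(mean(mx), 0.2)
})

test_that("Fourier fitting is exact at full harmonic capacity", {
  expect_error(fit_fourier(rnorm(10), K = 0), "at least 1")
  fc <- fit_fourier(rep(2.5, 101), K = 512)
  expect_equal(fc$mu, 2.5)
  expect_lt(max(abs(c(fc$alpha, fc$beta))), 1e-12)
  expect_equal(fc$k_eff, 50L)            # capacity cap floor((n - 1) / 2)

  n <- 513
  x <- (0:(n - 1)) / n
  fc2 <- fit_fourier(cos(2 * pi * x), K = 512)
  expect_equal(fc2$alpha[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(fc2$alpha[-1])), 1e-12)
  expect_lt(max(abs(fc2$beta)), 1e-12)

  # random curves: reconstruction matches spectral-truncation inverse FFT
  set.seed(33)
  for (i in 1:100) {
    v <- rnorm(513)
    fc3 <- fit_fourier(v, K = 512)
    expect_lt(fc3$max_resid, 1e-8)
    K <- sample(1:256, 1)
    fck <- fit_fourier(v, K = K)
    X <- fft(v)
    X[(K + 2):(513 - K)] <- 0
    oracle <- Re(fft(X, inverse = TRUE)) / 513
    expect_equal(fck$fitted, oracle, tolerance = 1e-9)
  }
})

test_that("the resting model is deterministic, ordered and degenerate-safe", {
  mod <- rest_model()
  expect_true(all(mod$u_curve >= mod$m_curve))
  expect_true(all(mod$m_curve >= mod$l_curve))
  expect_gte(mod$theta, 0)
  expect_equal(mod$u_curve, mod$m_curve + mod$theta * mod$s_curve)

  # mean curve equals the pointwise mean of the fitted curves (linearity)
  X <- curves_matrix(rest_curves())
  fits <- t(apply(X, 1, function(v) fit_fourier(v, K = 512)$fitted))
  expect_equal(mod$m_curve, colMeans(fits), tolerance = 1e-9)

  mod2 <- fit_resting_model(rest_curves(), n_boot = 300, seed = 42L)
  expect_identical(mod$theta, mod2$theta)

  expect_error(fit_resting_model(X[1:3, ]), "too few")
  expect_warning(fit_resting_model(X[1:10, ], n_boot = 20, seed = 1),
                 "fewer than 25")
  # identical curves exercise the epsilon floor
  expect_warning(
    mod3 <- fit_resting_model(X[rep(1, 30), ], n_boot = 20, seed = 1),
    "epsilon floor")
  expect_true(is.finite(mod3$theta))
})

test_that("a single bootstrap resample reproduces a direct computation", {
  X <- curves_matrix(rest_curves())
  M <- nrow(X)
  mod <- fit_resting_model(X, n_boot = 1, seed = 99L)
  fits <- t(apply(X, 1, function(v) fit_fourier(v, K = 512)$fitted))
  set.seed(99L)
  idx <- sample.int(M, M - 1, replace = TRUE)
  m_i <- colMeans(fits[idx, ])
  s_i <- apply(fits[idx, ], 2, sd)
  j <- sample.int(M, 1)
  d_direct <- max(abs((fits[j, ] - m_i) / pmax(s_i, 1e-12)))
  expect_equal(mod$d_star, d_direct)
  expect_equal(mod$theta, d_direct)
})

test_that("theta tightens as alpha grows", {
  X <- curves_matrix(rest_curves())
  thetas <- vapply(c(0.01, 0.05, 0.2), function(a)
    fit_resting_model(X, alpha_level = a, n_boot = 300, seed = 7L)$theta,
    numeric(1))
  expect_true(all(diff(thetas) <= 0))
})

test_that("membership testing standardises against the resting mean", {
  mod <- rest_model()
  self <- test_membership(mod, mod$m_curve)
  expect_equal(self$d_max, 0)
  expect_equal(self$indicator, 0L)

  out <- test_membership(mod, mod$m_curve + (mod$theta + 1) * mod$s_curve)
  expect_equal(out$indicator, 1L)
  expect_gt(out$d_max, mod$theta)

  expect_error(test_membership(mod, rnorm(10)), "length")
  expect_error(indicator_track(list(), rest_cardio()), "resting_model")

  # tidy/glance expose the band geometry
  td <- tidy(mod)
  expect_equal(nrow(td), 513L)
  expect_true(all(td$upper >= td$lower))
  expect_equal(glance(mod)$theta, mod$theta)
})

test_that("the indicator track is mostly quiet on resting data", {
  mod <- rest_model()
  rec2 <- simulate_recording(scenario_config(block = "A", duration_s = 60,
                                             spontaneous_rate_per_min = 0,
                                             seed = 102L))
  tr <- indicator_track(mod, cardio_series(rec2))
  expect_equal(nrow(tr), 59L)
  expect_lt(mean(tr$indicator), 0.2)
})
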