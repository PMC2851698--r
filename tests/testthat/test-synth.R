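test_that("the generator is a deterministic function of its seed", {
  cfg <- scenario_config(block = "C", seed = 5L)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$eda, r2$eda)
  expect_identical(r1$resp, r2$resp)
  expect_identical(r1$bvp, r2$bvp)
  expect_identical(annotations(r1), annotations(r2))
  r3 <- simulate_recording(scenario_config(block = "C", seed = 6L))
  expect_false(identical(r1$eda, r3$eda))
})

test_that("with no events and no noise the EDA is pure negative drift", {
  rec <- simulate_recording(
    scenario_config(block = "A", duration_s = 40,
                    spontaneous_rate_per_min = 0, seed = 2L),
    quiet_params())
  expect_true(all(diff(rec$eda) <= 0))
  expect_equal(nrow(annotations(rec)), 0L)
})

test_that("a single phasic event reproduces its closed-form amplitude", {
  # bi-exponential with unit-normalised peak: signal peak over the drifting
  # tonic baseline equals the drawn amplitude up to the drift across the rise
  rec <- simulate_recording(
    scenario_config(block = "A", duration_s = 60,
                    spontaneous_rate_per_min = 0,
                    spontaneous_times_s = 20, spontaneous_amps_uS = 0.3,
                    seed = 3L),
    quiet_params())
  ann <- annotations(rec)
  expect_equal(nrow(ann), 1L)
  onset_i <- round(ann$edr_onset_s * 256) + 1
  rise <- max(rec$eda) - rec$eda[onset_i]
  expect_lt(abs(rise - 0.3) / 0.3, 0.05)
  # peak lands at the analytic peak time of the kernel
  tp <- edr_peak_time(1.5, 4.0)
  expect_lt(abs(rec$time[which.max(rec$eda)] - (ann$edr_onset_s + tp)), 0.1)
})

test_that("the fixture suite reproduces the protocol structure", {
  suite <- fixture_suite()
  expect_length(suite, 8L)
  expect_setequal(names(suite),
                  paste0(rep(c("A", "B", "C", "D"), 2),
                         rep(c("_silence", "_noise"), each = 4)))
  expect_equal(duration(suite$A_silence), 130)
  expect_equal(duration(suite$C_noise), 130)
  expect_equal(duration(suite$B_silence), 220)
  expect_equal(duration(suite$D_noise), 220)
  # block C startle schedule
  cs <- annotations(suite$C_silence)
  expect_equal(sort(cs$onset_s[cs$kind == "startle"]), c(20, 45, 65, 90, 110))
  # block D (silence) uses schedule 3
  ds <- annotations(suite$D_silence)
  expect_equal(sort(ds$onset_s[ds$kind == "startle"]), c(10, 31, 72, 150, 189))
})

test_that("spontaneous event counts follow the configured Poisson rate", {
  # refractory thinning off so counts are raw Poisson draws
  pp <- physio_params(min_event_gap_s = 0)
  counts <- vapply(1:100, function(s) {
    rec <- simulate_recording(
      scenario_config(block = "A", duration_s = 60, seed = 1000L + s), pp)
    sum(annotations(rec)$kind == "spontaneous_edr")
  }, numeric(1))
  lambda <- 7.5 / 60 * (52 - 3)   # events fall in [3 s, T - 8 s]
  # chi-squared goodness of fit on pooled count bins
  breaks <- c(-Inf, qpois(c(0.2, 0.4, 0.6, 0.8), lambda), Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(c(0, ppois(qpois(c(0.2, 0.4, 0.6, 0.8), lambda), lambda), 1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("resting heart rate is respiration-coupled and voluntary windows decorrelate", {
  cs <- rest_cardio()
  fs <- 256
  n_win <- floor(duration(rest_recording())) - 2
  win_corr <- vapply(seq_len(n_win), function(m) {
    i <- ((m - 1) * fs + 1):((m + 1) * fs)
    cor(cs$hr_z[i], cs$resp_z[i])
  }, numeric(1))
  expect_gt(median(abs(win_corr)), 0.5)

  # strongly decorrelated benchmark: windows mostly inside voluntary
  # decorrelation episodes fall below the resting 5th percentile of |corr|
  b <- make_benchmark(seed = 3L, decorr_strength = 1, n_pairs = 20)
  csb <- cardio_series(b$rec)
  dw <- attr(b$rec, "extras")$decorr_windows
  in_decorr <- function(m) {    # >= 75% of the 2-s window decorrelated
    any(pmin(dw$end, m + 1) - pmax(dw$start, m - 1) >= 1.5)
  }
  wins <- seq_len(floor(duration(b$rec)) - 2)
  corr_b <- vapply(wins, function(m) {
    i <- ((m - 1) * fs + 1):((m + 1) * fs)
    cor(csb$hr_z[i], csb$resp_z[i])
  }, numeric(1))
  covered <- vapply(wins, in_decorr, logical(1))
  expect_gt(sum(covered), 5)
  rest_q05 <- quantile(abs(win_corr), 0.05)
  expect_lt(median(abs(corr_b[covered])), rest_q05)
})

test_that("coincident scheduled events warn but both apply", {
  cfg <- scenario_config(block = "A", duration_s = 60,
                         deep_breath_times_s = 20,
                         startle_times_s = 20,
                         spontaneous_rate_per_min = 0, seed = 4L)
  expect_warning(rec <- simulate_recording(cfg), "coincident")
  expect_setequal(annotations(rec)$kind, c("deep_breath", "startle"))
})
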