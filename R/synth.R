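#' Scenario configuration for the synthetic generator
#'
#' Mirrors the four experimental blocks: A quiet rest, B music imagery
#' (alternating 20-s rest/imagery periods), C rest with auditory startles,
#' D imagery with startles.  Durations default to 130 s (A/C) and 220 s
#' (B/D); block C startles land at 20, 45, 65, 90 and 110 s and block D
#' follows one of four published schedules (see [startle_schedules]).
#'
#' @param block One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param duration_s Trial length in seconds; defaults by block.
#' @param startle_times_s Startle presentation times; defaults by block.
#' @param imagery_period_s Length of the alternating rest/imagery periods
#'   (subjects are cued every 20 s).
#' @param imagery_rate_per_min Poisson rate of imagery-driven EDRs within
#'   imagery periods.
#' @param deep_breath_times_s Times of cued deep inspirations.
#' @param spontaneous_rate_per_min Rate of non-specific EDRs (the average
#'   population generates about 7.5 per minute).
#' @param background_noise If `TRUE`, the trial is run "with background
#'   noise": startle reactivity is enhanced (amplitude multiplier in
#'   [physio_params()]).
#' @param seed Integer seed; the whole recording is a deterministic function
#'   of `(cfg, pp)`.
#' @param imagery_times_s,spontaneous_times_s Optional explicit event times
#'   overriding the Poisson draws (used by benchmark builders that need
#'   exactly balanced classes).
#' @param spontaneous_amps_uS Optional explicit amplitudes (uS) for the
#'   events in `spontaneous_times_s`, overriding the random draw (used by
#'   the calibration recording's graded-amplitude reactions).
#' @param spontaneous_latency_s Optional explicit stimulus-to-EDR latencies
#'   for the events in `spontaneous_times_s`, overriding the random draw.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(block = c("A", "B", "C", "D"),
                            duration_s = NULL,
                            startle_times_s = NULL,
                            imagery_period_s = 20,
                            imagery_rate_per_min = 6,
                            deep_breath_times_s = numeric(),
                            spontaneous_rate_per_min = 7.5,
                            background_noise = FALSE,
                            seed = 1L,
                            imagery_times_s = NULL,
                            spontaneous_times_s = NULL,
                            spontaneous_amps_uS = NULL,
                            spontaneous_latency_s = NULL) {
  block <- match.arg(block)
  if (is.null(duration_s)) duration_s <- if (block %in% c("A", "C")) 130 else 220
  if (is.null(startle_times_s)) {
    startle_times_s <- switch(block,
      C = startle_schedules$C,
      D = startle_schedules$D[[3L]],
      numeric())
  }
  if (any(startle_times_s < 0 | startle_times_s > duration_s)) {
    abort("startle times must lie within the trial duration.")
  }
  if (spontaneous_rate_per_min < 0) abort("`spontaneous_rate_per_min` must be >= 0.")
  structure(list(
    block = block, duration_s = duration_s,
    startle_times_s = startle_times_s,
    imagery_period_s = imagery_period_s,
    imagery_rate_per_min = imagery_rate_per_min,
    deep_breath_times_s = deep_breath_times_s,
    spontaneous_rate_per_min = spontaneous_rate_per_min,
    background_noise = background_noise,
    seed = as.integer(seed),
    imagery_times_s = imagery_times_s,
    spontaneous_times_s = spontaneous_times_s,
    spontaneous_amps_uS = spontaneous_amps_uS,
    spontaneous_latency_s = spontaneous_latency_s
  ), class = "scenario_config")
}

#' Published startle schedules
#'
#' Block C uses a single schedule; block D has four alternative schedules,
#' one per trial.
#' @export
startle_schedules <- list(
  C = c(20, 45, 65, 90, 110),
  D = list(
    c(31, 88, 111, 149, 191),
    c(28, 82, 91, 128, 151),
    c(10, 31, 72, 150, 189),
    c(14, 89, 111, 170, 190)
  )
)

#' Physiological parameters of the synthetic generator
#'
#' Defaults emulate resting adult physiology as the classifier assumes it:
#' quasi-periodic breathing near 0.25 Hz, a heart rate of ~70 bpm whose
#' fluctuations follow respiration (respiratory sinus arrhythmia, RSA), a
#' slowly falling tonic EDA level with bi-exponential phasic reactions, and
#' band-limited sensor noise.  Voluntary events transiently replace the RSA
#' coupling with an independent heart-rate oscillation (`decorr_strength`
#' scales how completely); involuntary events keep heart rate phase-locked
#' to respiration, with at most a small respiration-independent startle
#' transient (`startle_hr_bump_bpm`, magnitude deliberately exposed as a
#' parameter since it is not well quantified).
#'
#' @param resp_freq_hz Mean breathing frequency (Hz).
#' @param resp_freq_jitter Relative SD of the slow frequency modulation.
#' @param resp_amp Breathing amplitude in belt units.
#' @param resp_amp_jitter Relative SD of the slow amplitude modulation.
#' @param deep_breath_gain Amplitude multiplier at the peak of a deep breath.
#' @param deep_breath_freq_gain Frequency multiplier at the peak of a deep
#'   breath (breathing slows).
#' @param deep_breath_span_s Duration of the deep-breath envelope.
#' @param hr_base_bpm Mean heart rate.
#' @param rsa_gain_bpm Peak-to-mean RSA excursion in bpm.
#' @param hr_noise_bpm SD of slow non-respiratory heart-rate noise.
#' @param decorr_strength In `[0, 1]`: 0 leaves voluntary events with intact
#'   RSA (indistinguishable from rest), 1 fully replaces the coupling.
#' @param pert_smooth_s Correlation time of the independent smooth
#'   heart-rate fluctuation that replaces the RSA coupling during voluntary
#'   decorrelation windows (power-matched to the RSA oscillation).
#' @param edr_latency_s Range of stimulus-to-EDR-onset latency (1.3-2.5 s).
#' @param hr_latency_s Range of stimulus-to-heart-rate-response latency
#'   (0.25-2 s); sets the onset of the startle heart-rate transient.
#' @param decorr_span_s The decorrelation of a voluntary event begins this
#'   long (drawn uniformly) before the EDR onset -- mirroring the lead of
#'   the cardiac response over the sudomotor one -- and ends 1 s after it.
#' @param edr_amp_uS Range of phasic EDR amplitudes; the floor keeps every
#'   generated event a bona fide EDR (> 0.05 uS within 5 s).
#' @param edr_rise_s,edr_decay_s Time constants of the bi-exponential
#'   sudomotor impulse response.
#' @param tonic_start_uS,tonic_drift_uS_per_s Tonic EDA level and its
#'   (negative) drift.
#' @param noise_sd Named per-channel sensor-noise SDs (`eda`, `resp`, `bvp`).
#' @param noise_smooth_s Sensor noise is band-limited by a moving average of
#'   this length.
#' @param startle_hr_bump_bpm,startle_hr_span_s Magnitude and duration of the
#'   respiration-correlated startle heart-rate transient.
#' @param noise_startle_gain Startle EDR amplitude multiplier under the
#'   background-noise condition.
#' @param min_event_gap_s Refractory gap between successive EDR events;
#'   near-coincident sudomotor responses superpose and are scored as one.
#' @param bvp_sharpness Shape constant of the pulsatile BVP waveform.
#' @return A list of class `physio_params`.
#' @export
physio_params <- function(resp_freq_hz = 0.25, resp_freq_jitter = 0.08,
                          resp_amp = 1, resp_amp_jitter = 0.10,
                          deep_breath_gain = 2.5, deep_breath_freq_gain = 0.6,
                          deep_breath_span_s = 8,
                          hr_base_bpm = 70, rsa_gain_bpm = 5,
                          hr_noise_bpm = 0.3,
                          decorr_strength = 1,
                          pert_smooth_s = 1.2,
                          edr_latency_s = c(1.3, 2.5),
                          hr_latency_s = c(0.25, 2.0),
                          decorr_span_s = c(0.25, 2.0),
                          edr_amp_uS = c(0.05, 1.0),
                          edr_rise_s = 1.5, edr_decay_s = 4.0,
                          tonic_start_uS = 2, tonic_drift_uS_per_s = -0.001,
                          noise_sd = c(eda = 0.001, resp = 0.005, bvp = 0.01),
                          noise_smooth_s = 0.25,
                          startle_hr_bump_bpm = 1.5, startle_hr_span_s = 3,
                          noise_startle_gain = 1.3,
                          min_event_gap_s = 5,
                          bvp_sharpness = 3) {
  stopifnot(edr_amp_uS[1] >= 0.05, edr_rise_s > 0, edr_decay_s > edr_rise_s,
            decorr_strength >= 0, decorr_strength <= 1,
            tonic_drift_uS_per_s <= 0)
  structure(as.list(environment()), class = "physio_params")
}

# deterministic sub-stream seed (kept below 2^31)
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + 7 * k) %% 2147483645L + 1L
}

# centred moving average (cumsum-based; windows truncated at the edges)
smooth_ma <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h1 <- k %/% 2L
  h2 <- k - 1L - h1
  lo <- pmax(0L, seq_len(n) - 1L - h1)
  hi <- pmin(n, seq_len(n) + h2)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# band-limited zero-mean unit-SD noise; the moving average is applied twice
# (triangular kernel) so the path is smooth at sample scale and its
# sample-to-sample increments stay far below the physiological signals'
slow_noise <- function(n, fs, smooth_s) {
  k <- round(smooth_s * fs)
  z <- smooth_ma(smooth_ma(rnorm(n), k), k)
  z <- z - mean(z)
  s <- sd(z)
  if (s > 0) z / s else z
}

# raised-cosine bump on [t0, t1], peak 1 in the middle
hann_bump <- function(time, t0, t1) {
  w <- numeric(length(time))
  i <- time >= t0 & time <= t1
  w[i] <- 0.5 * (1 - cos(2 * pi * (time[i] - t0) / (t1 - t0)))
  w
}

# plateau window on [t0, t1] with cosine ramps of length `ramp`
plateau_window <- function(time, t0, t1, ramp = 0.25) {
  w <- numeric(length(time))
  i <- time >= t0 & time <= t1
  ti <- time[i]
  wi <- rep(1, length(ti))
  r0 <- ti < t0 + ramp
  wi[r0] <- 0.5 * (1 - cos(pi * (ti[r0] - t0) / ramp))
  r1 <- ti > t1 - ramp
  wi[r1] <- pmin(wi[r1], 0.5 * (1 - cos(pi * (t1 - ti[r1]) / ramp)))
  w[i] <- wi
  w
}

#' Bi-exponential EDR impulse response
#'
#' Difference of exponentials with the given rise and decay time constants,
#' normalised to unit peak, evaluated at times `t` (seconds from EDR onset;
#' zero for `t < 0`).
#' @param t Times in seconds relative to onset.
#' @param rise_s,decay_s Time constants.
#' @return Numeric vector, peak value 1.
#' @export
edr_shape <- function(t, rise_s = 1.5, decay_s = 4.0) {
  tp <- edr_peak_time(rise_s, decay_s)
  peak <- exp(-tp / decay_s) - exp(-tp / rise_s)
  out <- numeric(length(t))
  i <- t >= 0
  out[i] <- (exp(-t[i] / decay_s) - exp(-t[i] / rise_s)) / peak
  out
}

#' @rdname edr_shape
#' @export
edr_peak_time <- function(rise_s = 1.5, decay_s = 4.0) {
  rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
}

#' Rest/imagery period structure of an imagery block
#'
#' @param duration_s Trial length.
#' @param period_s Cue period (default 20 s); the trial starts at rest.
#' @return Tibble with `start`, `end`, `state` (`"rest"`/`"imagery"`).
#' @export
imagery_periods <- function(duration_s, period_s = 20) {
  starts <- seq(0, duration_s - 1e-9, by = period_s)
  tibble(
    start = starts,
    end = pmin(starts + period_s, duration_s),
    state = rep_len(c("rest", "imagery"), length(starts))
  )
}

draw_poisson_times <- function(rate_per_s, windows) {
  # homogeneous Poisson process restricted to the union of windows
  if (rate_per_s <= 0 || nrow(windows) == 0L) return(numeric())
  unlist(lapply(seq_len(nrow(windows)), function(i) {
    len <- windows$end[i] - windows$start[i]
    if (len <= 0) return(numeric())
    k <- rpois(1, rate_per_s * len)
    sort(runif(k, windows$start[i], windows$end[i]))
  }))
}

#' Simulate an annotated synthetic recording
#'
#' Builds the three channels sample by sample: EDA as a negatively drifting
#' tonic level plus bi-exponential phasic reactions at imagery, startle,
#' deep-breath and spontaneous events; respiration as a
#' frequency/amplitude-jittered sinusoid with deep breaths as transiently
#' amplified, slowed cycles; BVP as a pulse train whose instantaneous rate
#' follows the respiratory oscillation at rest (RSA) and is replaced by an
#' independent oscillation over a short window before each voluntary EDR.
#' Every generated EDR is recorded in the annotation table with its truth
#' label, its actual EDR onset (stimulus + latency) and both the drawn
#' amplitude and the realised noiseless rise within 5 s of onset.
#'
#' @param cfg A [scenario_config()].
#' @param pp A [physio_params()].
#' @return An [recording()]; ground-truth auxiliaries (noiseless channels,
#'   true heart-rate profile, decorrelation windows) are kept in the
#'   `extras` attribute.
#' @export
simulate_recording <- function(cfg = scenario_config(), pp = physio_params()) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(pp, "physio_params"))
  fs <- 256
  T <- cfg$duration_s
  n <- round(fs * T)
  time <- (seq_len(n) - 1) / fs

  ## ---- event schedule -------------------------------------------------
  set.seed(sub_seed(cfg$seed, 0L))
  add_event <- function(stim, kind) {
    tibble(kind = kind, stim_s = stim)
  }
  fixed <- dplyr::bind_rows(
    tibble(kind = character(), stim_s = numeric()),
    if (length(cfg$startle_times_s)) add_event(cfg$startle_times_s, "startle"),
    if (length(cfg$deep_breath_times_s)) add_event(cfg$deep_breath_times_s, "deep_breath"),
    if (!is.null(cfg$imagery_times_s)) add_event(cfg$imagery_times_s, "imagery"),
    if (!is.null(cfg$spontaneous_times_s)) add_event(cfg$spontaneous_times_s, "spontaneous_edr")
  )
  if (nrow(fixed) > 0L && any(duplicated(fixed$stim_s))) {
    warn("coincident scheduled events (e.g. deep breath and startle at the same time); both applied.")
  }
  # Poisson-driven events, thinned to the refractory gap against kept events
  windows_imagery <- if (cfg$block %in% c("B", "D") && is.null(cfg$imagery_times_s)) {
    dplyr::filter(imagery_periods(T, cfg$imagery_period_s), .data$state == "imagery")
  } else tibble(start = numeric(), end = numeric())
  cand <- dplyr::bind_rows(
    add_event(draw_poisson_times(cfg$imagery_rate_per_min / 60, windows_imagery), "imagery"),
    if (is.null(cfg$spontaneous_times_s))
      add_event(draw_poisson_times(cfg$spontaneous_rate_per_min / 60,
                                   tibble(start = 3, end = max(3, T - 8))),
                "spontaneous_edr")
  )
  events <- fixed
  if (nrow(cand) > 0L) {
    cand <- dplyr::arrange(cand, .data$stim_s)
    for (i in seq_len(nrow(cand))) {
      if (nrow(events) == 0L ||
          all(abs(events$stim_s - cand$stim_s[i]) >= pp$min_event_gap_s)) {
        events <- dplyr::bind_rows(events, cand[i, ])
      }
    }
  }
  events <- dplyr::arrange(events, .data$stim_s)
  m <- nrow(events)
  if (m > 0L) {
    events$edr_latency <- runif(m, pp$edr_latency_s[1], pp$edr_latency_s[2])
    if (!is.null(cfg$spontaneous_latency_s)) {
      sp <- which(events$kind == "spontaneous_edr")
      events$edr_latency[sp] <- cfg$spontaneous_latency_s[
        match(events$stim_s[sp], cfg$spontaneous_times_s)]
    }
    events$edr_onset <- events$stim_s + events$edr_latency
    events$amp <- runif(m, pp$edr_amp_uS[1], pp$edr_amp_uS[2])
    if (!is.null(cfg$spontaneous_amps_uS)) {
      sp <- which(events$kind == "spontaneous_edr")
      events$amp[sp] <- cfg$spontaneous_amps_uS[
        match(events$stim_s[sp], cfg$spontaneous_times_s)]
    }
    if (cfg$background_noise) {
      events$amp <- events$amp *
        ifelse(events$kind == "startle", pp$noise_startle_gain, 1)
    }
    events$hr_latency <- runif(m, pp$hr_latency_s[1], pp$hr_latency_s[2])
    # drop EDRs that cannot fit in the trial (stimulus annotation retained)
    events$has_edr <- events$edr_onset > 0.5 & events$edr_onset < T - 1.5
  }

  ## ---- respiration ----------------------------------------------------
  set.seed(sub_seed(cfg$seed, 1L))
  fj <- slow_noise(n, fs, 3) * pp$resp_freq_jitter
  aj <- slow_noise(n, fs, 3) * pp$resp_amp_jitter
  freq <- pp$resp_freq_hz * (1 + fj)
  amp_env <- pp$resp_amp * (1 + aj)
  if (m > 0L) {
    for (i in which(events$kind == "deep_breath")) {
      wb <- hann_bump(time, events$stim_s[i], events$stim_s[i] + pp$deep_breath_span_s)
      amp_env <- amp_env * (1 + (pp$deep_breath_gain - 1) * wb)
      freq <- freq * (1 - (1 - pp$deep_breath_freq_gain) * wb)
    }
  }
  phase <- cumsum(freq) / fs
  s_resp <- sin(2 * pi * phase)        # unit-amplitude respiratory oscillation
  resp_clean <- amp_env * s_resp
  resp <- resp_clean +
    pp$noise_sd[["resp"]] * slow_noise(n, fs, pp$noise_smooth_s)

  ## ---- heart rate and BVP ---------------------------------------------
  set.seed(sub_seed(cfg$seed, 2L))
  hr <- pp$hr_base_bpm + pp$rsa_gain_bpm * s_resp +
    pp$hr_noise_bpm * slow_noise(n, fs, 2)
  # respiration-independent smooth fluctuation, power-matched to the RSA
  # oscillation (rms of a unit sinusoid), substituted in voluntary windows
  pert <- slow_noise(n, fs, pp$pert_smooth_s) / sqrt(2)
  decorr <- tibble(start = numeric(), end = numeric())
  if (m > 0L) {
    for (i in seq_len(m)) {
      kind <- events$kind[i]
      stim <- events$stim_s[i]
      if (kind == "imagery" && events$has_edr[i] && pp$decorr_strength > 0) {
        d0 <- events$edr_onset[i] - runif(1, pp$decorr_span_s[1], pp$decorr_span_s[2])
        d1 <- events$edr_onset[i] + 1
        wd <- plateau_window(time, d0, d1)
        hr <- hr + pp$decorr_strength * wd * pp$rsa_gain_bpm * (pert - s_resp)
        decorr <- dplyr::bind_rows(decorr, tibble(start = d0, end = d1))
      } else if (kind == "startle" && pp$startle_hr_bump_bpm > 0) {
        hr <- hr + pp$startle_hr_bump_bpm *
          hann_bump(time, stim + 0.25, stim + 0.25 + pp$startle_hr_span_s)
      }
    }
  }
  cphase <- cumsum(hr / 60) / fs
  bvp_clean <- exp(pp$bvp_sharpness * (cos(2 * pi * cphase) - 1))
  bvp <- bvp_clean + pp$noise_sd[["bvp"]] * slow_noise(n, fs, pp$noise_smooth_s)

  ## ---- EDA -------------------------------------------------------------
  set.seed(sub_seed(cfg$seed, 3L))
  eda_clean <- pp$tonic_start_uS + pp$tonic_drift_uS_per_s * time
  if (m > 0L) {
    for (i in which(events$has_edr)) {
      i0 <- floor(events$edr_onset[i] * fs) + 1
      i1 <- min(n, i0 + 30 * fs)
      tt <- time[i0:i1] - events$edr_onset[i]
      eda_clean[i0:i1] <- eda_clean[i0:i1] +
        events$amp[i] * edr_shape(tt, pp$edr_rise_s, pp$edr_decay_s)
    }
  }
  eda <- eda_clean + pp$noise_sd[["eda"]] * slow_noise(n, fs, pp$noise_smooth_s)

  ## ---- annotations -----------------------------------------------------
  ann <- NULL
  if (m > 0L) {
    rise <- rep(NA_real_, m)
    for (i in which(events$has_edr)) {
      i0 <- floor(events$edr_onset[i] * fs) + 1
      i1 <- min(n, i0 + 5 * fs)
      rise[i] <- max(eda_clean[i0:i1]) - eda_clean[i0]
    }
    ann <- tibble(
      kind = events$kind, onset_s = events$stim_s, duration_s = 0,
      edr_onset_s = ifelse(events$has_edr, events$edr_onset, NA_real_),
      amp_uS = ifelse(events$has_edr, events$amp, NA_real_),
      rise_uS = rise
    )
  }
  rec <- recording(eda, resp, bvp, fs = fs, annotations = ann,
                   extras = list(hr_true = hr, eda_clean = eda_clean,
                                 resp_clean = resp_clean,
                                 decorr_windows = decorr,
                                 block = cfg$block,
                                 background_noise = cfg$background_noise,
                                 seed = cfg$seed))
  rec
}

#' Build the eight-recording fixture suite
#'
#' One recording per block A-D under each of the two noise conditions,
#' with the published durations and startle schedules (block D uses
#' schedule 3 in silence and schedule 1 with background noise).
#'
#' @param seed Integer master seed; per-fixture seeds are derived from it.
#' @param pp A [physio_params()].
#' @return Named list of 8 recordings, e.g. `A_silence`, `D_noise`.
#' @export
make_fixture_suite <- function(seed = 1L, pp = physio_params()) {
  grid <- expand.grid(block = c("A", "B", "C", "D"),
                      noise = c(FALSE, TRUE), stringsAsFactors = FALSE)
  out <- purrr::pmap(grid, function(block, noise) {
    startles <- if (block == "D") {
      startle_schedules$D[[if (noise) 1L else 3L]]
    } else NULL
    cfg <- scenario_config(block = block, startle_times_s = startles,
                           background_noise = noise,
                           seed = sub_seed(seed, 10L + 4L * noise +
                                             match(block, c("A", "B", "C", "D"))))
    simulate_recording(cfg, pp)
  })
  names(out) <- paste0(grid$block, ifelse(grid$noise, "_noise", "_silence"))
  out
}

#' Build a threshold-calibration recording
#'
#' A quiet-rest trial containing exactly five EDRs of graded amplitude
#' spanning the detectable range (0.05 to 1 uS), well separated on a clean
#' tonic background -- the signal on which the detection threshold is
#' calibrated by ROC analysis.  Amplitudes are graded and onsets staggered
#' at sub-second phases relative to the one-second analysis grid, so the
#' sweep sees windowed first-difference statistics spanning the whole
#' detectable range from barely detectable reactions up to large ones.
#'
#' @param seed Integer seed.
#' @param pp A [physio_params()].
#' @param amps_uS The five reaction amplitudes.
#' @param latencies_s The five stimulus-to-onset latencies (their fractional
#'   parts set the onset phases on the analysis grid).
#' @return An annotated [recording()].
#' @export
make_calibration_recording <- function(seed = 1L, pp = physio_params(),
                                       amps_uS = c(0.05, 0.07, 0.1, 0.3, 1.0),
                                       latencies_s = c(1.5, 1.7, 1.9, 2.1, 2.3)) {
  cfg <- scenario_config(block = "A", spontaneous_rate_per_min = 0,
                         spontaneous_times_s = c(18, 42, 66, 90, 114),
                         spontaneous_amps_uS = amps_uS,
                         spontaneous_latency_s = latencies_s,
                         seed = sub_seed(seed, 33L))
  simulate_recording(cfg, pp)
}

#' Build a balanced voluntary/involuntary benchmark
#'
#' Alternates explicitly scheduled voluntary (imagery) and involuntary
#' (spontaneous) EDR events on a quiet background, so the event-level class
#' balance is exactly 50/50 and the heart-rate decorrelation preceding
#' voluntary events is the only discriminating signal.  A matching
#' quiet-rest baseline recording (spontaneous events only) is returned for
#' threshold calibration and resting-model fitting.
#'
#' @param seed Integer seed.
#' @param decorr_strength Passed to [physio_params()]; 0 makes voluntary
#'   events physiologically identical to involuntary ones.
#' @param n_pairs Number of voluntary/involuntary event pairs.
#' @param spacing_s Time between successive events.
#' @param pp Base [physio_params()] (its `decorr_strength` is overridden).
#' @return List with elements `rec` (the benchmark recording) and
#'   `baseline` (a 130-s block-A recording).
#' @export
make_benchmark <- function(seed = 1L, decorr_strength = 1, n_pairs = 20,
                           spacing_s = 16, pp = physio_params()) {
  pp$decorr_strength <- decorr_strength
  dur <- spacing_s * (2 * n_pairs) + spacing_s
  vol <- spacing_s * seq(1, 2 * n_pairs - 1, by = 2)
  invol <- spacing_s * seq(2, 2 * n_pairs, by = 2)
  cfg <- scenario_config(block = "A", duration_s = dur,
                         spontaneous_rate_per_min = 0,
                         imagery_times_s = vol, spontaneous_times_s = invol,
                         seed = sub_seed(seed, 1L))
  base_cfg <- scenario_config(block = "A", seed = sub_seed(seed, 2L))
  list(rec = simulate_recording(cfg, pp),
       baseline = simulate_recording(base_cfg, pp))
}
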