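#' Detector configuration
#'
#' The detector slides non-overlapping one-second windows over the EDA
#' trace and compares the mean of the first differences within each window
#' (`C`, in microsiemens per sample) against the threshold `D`: a window
#' with `C >= D` is part of an EDR.  The published threshold for clean
#' 256-Hz recordings is `D = 4e-4`; for other signal scales `D` should be
#' recalibrated with [calibrate_threshold()].  Flagged runs are merged into
#' events and validated against an amplitude floor: a detection whose EDA
#' rise within `min_edr_window_s` of onset is below `min_edr_amp_uS` is
#' discarded.
#'
#' @param window_s Analysis window length in seconds.
#' @param D Detection threshold on the windowed first-difference mean.
#' @param min_edr_amp_uS Amplitude floor for validating a detection (an EDR
#'   is an increase of over 0.02 uS within five seconds; the stricter
#'   working definition 0.05 uS is also in use in the field).
#' @param min_edr_window_s Rise window for the amplitude validation.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(window_s = 1, D = 4e-4, min_edr_amp_uS = 0.02,
                            min_edr_window_s = 5) {
  stopifnot(window_s > 0, D > 0, min_edr_amp_uS > 0, min_edr_window_s > 0)
  structure(list(window_s = window_s, D = D,
                 min_edr_amp_uS = min_edr_amp_uS,
                 min_edr_window_s = min_edr_window_s),
            class = "detector_config")
}

#' Windowed first-difference mean of an EDA segment
#'
#' @param eda_window Numeric vector of EDA samples (one analysis window).
#' @return The arithmetic mean of the successive differences, in
#'   microsiemens per sample.
#' @export
#' @examples
#' window_stat(rep(2, 256))                   # constant -> 0
#' window_stat(2 + (0:255) / 256)             # 1 uS/s ramp -> 1/256
window_stat <- function(eda_window) {
  if (length(eda_window) < 2L) abort("window must contain at least 2 samples.")
  mean(diff(eda_window))
}

window_stats_all <- function(eda, fs, window_s) {
  w <- round(fs * window_s)
  if (w < 2L) abort("analysis window shorter than 2 samples.")
  n_win <- floor(length(eda) / w)
  if (n_win < 1L) return(tibble(window = integer(), t_start = numeric(), C = numeric()))
  # mean first difference within window k = (eda[kw] - eda[(k-1)w + 1]) / (w - 1)
  starts <- (seq_len(n_win) - 1L) * w + 1L
  ends <- starts + w - 1L
  tibble(window = seq_len(n_win),
         t_start = (starts - 1L) / fs,
         C = (eda[ends] - eda[starts]) / (w - 1L))
}

#' Detect electrodermal reactions
#'
#' Flags every analysis window with `C >= D`, merges consecutive flagged
#' windows into one event whose onset is the first flagged window's start,
#' measures the amplitude as the peak-minus-onset EDA rise within
#' `min_edr_window_s` of onset, and discards events below the amplitude
#' floor.
#'
#' @param rec An [recording()].
#' @param cfg A [detector_config()].
#' @return Tibble with one row per detected event: `onset_s`, `flag_end_s`
#'   (end of the last merged flagged window), `amplitude_uS`, and the
#'   analysis segment bounds `seg_start_s = onset_s - 2`,
#'   `seg_end_s = onset_s + 1` used by the cardiorespiratory filter.
#' @export
detect_edr <- function(rec, cfg = detector_config()) {
  fs <- sampling_rate(rec)
  ws <- window_stats_all(rec$eda, fs, cfg$window_s)
  flagged <- ws$C >= cfg$D
  if (!any(flagged)) {
    return(tibble(onset_s = numeric(), flag_end_s = numeric(),
                  amplitude_uS = numeric(), seg_start_s = numeric(),
                  seg_end_s = numeric()))
  }
  runs <- rle(flagged)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- runs$values
  events <- tibble(
    onset_s = ws$t_start[run_start[keep]],
    flag_end_s = ws$t_start[run_end[keep]] + cfg$window_s
  )
  # trough-to-peak amplitude: the largest rise from a running minimum over
  # the flagged span plus the rise window that follows it; the scan starts
  # one analysis window early so the response's foot is included
  events$amplitude_uS <- purrr::map2_dbl(
    events$onset_s, events$flag_end_s, function(on, fe) {
      i0 <- max(1L, round((on - cfg$window_s) * fs) + 1L)
      i1 <- min(nrow(rec), round(fe * fs) + round(cfg$min_edr_window_s * fs))
      seg <- rec$eda[i0:i1]
      max(seg - cummin(seg))
    })
  events <- dplyr::filter(events, .data$amplitude_uS >= cfg$min_edr_amp_uS)
  events$seg_start_s <- events$onset_s - 2
  events$seg_end_s <- events$onset_s + 1
  events
}

# truth intervals: the rising limb [edr_onset, edr_onset + t_peak] of each
# annotated EDR.  With `min_rise_uS` > 0, events whose realised rise in the
# compound trace stays below the floor are dropped: superposition on the
# decay of a preceding reaction can cancel the rise, and a trace that never
# increases by the defining amount contains no EDR to detect.
rising_limbs <- function(rec, min_rise_uS = 0, pp_rise = 1.5, pp_decay = 4.0) {
  ann <- annotations(rec)
  ann <- ann[!is.na(ann$edr_onset_s), , drop = FALSE]
  if (min_rise_uS > 0 && "rise_uS" %in% names(ann)) {
    ann <- ann[is.na(ann$rise_uS) | ann$rise_uS >= min_rise_uS, , drop = FALSE]
  }
  tibble(start = ann$edr_onset_s,
         end = ann$edr_onset_s + edr_peak_time(pp_rise, pp_decay))
}

overlaps_any <- function(t0, t1, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(t0)))
  purrr::map2_lgl(t0, t1, function(a, b) {
    any(intervals$start < b & intervals$end > a)
  })
}

#' Calibrate the detection threshold by ROC analysis
#'
#' Sweeps `D` over a logarithmic grid and scores each candidate by
#' per-window sensitivity plus specificity against the annotated rising
#' limbs of the true EDRs (any window overlapping a rising limb counts as
#' positive).  Returns the candidate maximising the sum; ties are broken
#' toward the larger threshold (fewer false positives).
#'
#' @param rec An annotated [recording()] containing at least one true EDR.
#' @param truth Optional tibble of rising limbs (`start`, `end`); defaults
#'   to the recording's annotations with realised rises of at least
#'   `min_rise_uS`.
#' @param grid Candidate thresholds (default `10^seq(-6, -2, length 161)`).
#' @param window_s Analysis window length.
#' @param min_rise_uS Realised-rise floor defining a true EDR (0.05 uS
#'   within 5 s); sub-threshold reactions are scored neither as positive
#'   nor as negative windows.
#' @return The calibrated threshold `D` (scalar).
#' @export
calibrate_threshold <- function(rec, truth = NULL,
                                grid = 10^seq(-6, -2, length.out = 161),
                                window_s = 1, min_rise_uS = 0.05) {
  if (is.null(truth)) truth <- rising_limbs(rec, min_rise_uS)
  if (nrow(truth) == 0L) abort("threshold calibration needs at least one true EDR.")
  fs <- sampling_rate(rec)
  ws <- window_stats_all(rec$eda, fs, window_s)
  pos <- overlaps_any(ws$t_start, ws$t_start + window_s, truth)
  if (!any(pos)) abort("no analysis window overlaps a true EDR rising limb.")
  neg <- !overlaps_any(ws$t_start, ws$t_start + window_s, rising_limbs(rec))
  score <- purrr::map_dbl(grid, function(D) {
    flag <- ws$C >= D
    sens <- mean(flag[pos])
    spec <- if (any(neg)) mean(!flag[neg]) else 1
    sens + spec
  })
  best <- which(score == max(score))
  grid[max(best)]
}

#' Score detection against simulator ground truth
#'
#' Sensitivity is event-level: a true EDR (realised rise of at least
#' `min_rise_uS` within 5 s) counts as detected when at least one validated
#' detection's flagged-window span overlaps its rising limb.  Specificity
#' is window-level on the amplitude-validated detections, with a one-window
#' guard collar around the rising limb of every annotated event (including
#' sub-threshold ones): negative windows are those clear of every collar,
#' and a false positive is a flagged window of a validated detection
#' landing on a negative window.
#'
#' @param rec An annotated [recording()].
#' @param events Detections from [detect_edr()].
#' @param window_s Analysis window length used for detection.
#' @param min_rise_uS Realised-rise floor defining a true EDR.
#' @param valid_horizon_s Amplitude-validation rise window; windows this
#'   close before a limb can validate through the upcoming reaction and are
#'   therefore excluded from the negatives.
#' @return One-row tibble: `n_true`, `n_detected`, `sensitivity`,
#'   `specificity` (both in `[0, 1]`).
#' @export
detection_performance <- function(rec, events, window_s = 1,
                                  min_rise_uS = 0.05, valid_horizon_s = 5) {
  limbs <- rising_limbs(rec, min_rise_uS)
  fs <- sampling_rate(rec)
  n_true <- nrow(limbs)
  hit <- if (n_true > 0L) {
    purrr::map_lgl(seq_len(n_true), function(i) {
      any(events$onset_s < limbs$end[i] & events$flag_end_s > limbs$start[i])
    })
  } else logical()
  all_limbs <- rising_limbs(rec)
  guards <- tibble(start = all_limbs$start - window_s - valid_horizon_s,
                   end = all_limbs$end + window_s)
  ws_t <- window_stats_all(rec$eda, fs, window_s)$t_start
  negative <- !overlaps_any(ws_t, ws_t + window_s, guards)
  flagged_w <- rep(FALSE, length(ws_t))
  for (i in seq_len(nrow(events))) {
    flagged_w <- flagged_w |
      (ws_t >= events$onset_s[i] - 1e-9 & ws_t < events$flag_end_s[i] - 1e-9)
  }
  fp <- sum(flagged_w & negative)
  tibble(
    n_true = n_true,
    n_detected = nrow(events),
    sensitivity = if (n_true > 0L) mean(hit) else NA_real_,
    specificity = if (any(negative)) 1 - fp / sum(negative) else NA_real_
  )
}
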