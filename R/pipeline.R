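#' Classify detected EDRs as voluntary or involuntary
#'
#' Sequential screening, as in the two-filter design: (1) if a flagged
#' irregular-breath window (covering `[t, t + 5]` s) overlaps the five
#' seconds preceding the EDR onset, the reaction is attributed to
#' respiration and labelled voluntary (deep inspirations are intentional
#' acts); (2) otherwise the indicator track of the cardiorespiratory
#' filter is consulted over the analysis segment `[onset - 2, onset + 1]`
#' and the reaction is voluntary when the indicator is raised anywhere in
#' the segment, involuntary otherwise.  Events whose segment does not fit
#' inside the trial are excluded (returned with `predicted_label = NA` and
#' `cause = "excluded"`).
#'
#' @param events Detections from [detect_edr()].
#' @param resp_flags Flagged profile from [flag_irregular_breaths()].
#' @param track Indicator track from [indicator_track()].
#' @param duration_s Trial length in seconds.
#' @param resp_lookback_s How far before onset a respiration flag may start
#'   counting (5 s: EDR latency after an inspiration).
#' @param resp_window_s Window covered by one respiration flag.
#' @return `events` with `predicted_label` and `cause`
#'   (`"respiration"`/`"cardio"`/`"none"`/`"excluded"`) added.
#' @export
classify_edr <- function(events, resp_flags, track, duration_s,
                         resp_lookback_s = 5, resp_window_s = 5) {
  n <- nrow(events)
  predicted <- character(n)
  cause <- character(n)
  flagged_t <- resp_flags$t[resp_flags$flag]
  for (i in seq_len(n)) {
    on <- events$onset_s[i]
    if (on < 2 || on + 1 > duration_s) {
      predicted[i] <- NA_character_
      cause[i] <- "excluded"
      next
    }
    resp_hit <- any(flagged_t < on & flagged_t + resp_window_s > on - resp_lookback_s)
    if (resp_hit) {
      predicted[i] <- "voluntary"
      cause[i] <- "respiration"
      next
    }
    seg <- c(on - 2, on + 1)
    hit <- any(track$indicator == 1L &
                 track$t_start < seg[2] & track$t_end > seg[1])
    predicted[i] <- if (hit) "voluntary" else "involuntary"
    cause[i] <- if (hit) "cardio" else "none"
  }
  events$predicted_label <- predicted
  events$cause <- cause
  events
}

#' Attach ground-truth labels to detected events
#'
#' Each detection is matched to the annotated EDR whose onset is nearest
#' within a tolerance; unmatched detections fall back to the compliance
#' assumption: reactions during imagery periods are voluntary, reactions
#' during rest are involuntary.
#'
#' @param events Detections from [detect_edr()].
#' @param rec The annotated [recording()].
#' @param tol_s Matching tolerance between detection onset and true EDR
#'   onset.
#' @return `events` with `truth_label` and matched `kind` added.
#' @export
assign_truth <- function(events, rec, tol_s = 2.5) {
  ann <- annotations(rec)
  ann <- ann[!is.na(ann$edr_onset_s), , drop = FALSE]
  periods <- imagery_periods(duration(rec))
  events$truth_label <- NA_character_
  events$kind <- NA_character_
  for (i in seq_len(nrow(events))) {
    if (nrow(ann) > 0L) {
      d <- abs(ann$edr_onset_s - events$onset_s[i])
      j <- which.min(d)
      if (d[j] <= tol_s) {
        events$truth_label[i] <- ann$truth_label[j]
        events$kind[i] <- ann$kind[j]
        next
      }
    }
    in_imagery <- any(periods$state == "imagery" &
                        periods$start <= events$onset_s[i] &
                        periods$end > events$onset_s[i])
    events$truth_label[i] <- if (in_imagery) "voluntary" else "involuntary"
    events$kind[i] <- "unmatched"
  }
  events
}

#' Confusion counts and predictive values
#'
#' Voluntary is the positive class.  Ratios with a zero denominator are
#' reported as `NA`, never 0.  `naive_accuracy` is the accuracy of calling
#' every EDR voluntary (the prevalence of the positive class), the
#' no-classifier baseline.
#'
#' @param events Tibble with `truth_label` and `predicted_label`
#'   (`"voluntary"`/`"involuntary"`); rows with `NA` predictions are
#'   dropped with a message.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `ppv`, `npv`,
#'   `accuracy`, `naive_accuracy`, `n`.
#' @export
evaluate_events <- function(events) {
  if (nrow(events) == 0L) abort("no events to evaluate.")
  keep <- !is.na(events$predicted_label) & !is.na(events$truth_label)
  if (!all(keep)) {
    message(sum(!keep), " event(s) excluded from evaluation (no label).")
    events <- events[keep, , drop = FALSE]
  }
  if (nrow(events) == 0L) abort("no labelled events to evaluate.")
  truth_pos <- events$truth_label == "voluntary"
  pred_pos <- events$predicted_label == "voluntary"
  tp <- sum(truth_pos & pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn),
         accuracy = ratio(tp + tn, tp + tn + fp + fn),
         naive_accuracy = mean(truth_pos),
         n = nrow(events))
}

#' Compare classification accuracy between noise conditions
#'
#' Pearson chi-squared test (df = 1, no continuity correction) on the 2x2
#' table of correct/incorrect classifications in trials run in silence
#' versus with background noise.
#'
#' @param events_silence,events_noise Classified, truth-labelled event
#'   tibbles for the two conditions.
#' @return One-row tibble: `chi2`, `p`, `df`, and the table counts.
#' @export
compare_noise_conditions <- function(events_silence, events_noise) {
  if (nrow(events_silence) == 0L || nrow(events_noise) == 0L) {
    abort("both conditions need at least one classified event.")
  }
  correct <- function(ev) {
    ev <- ev[!is.na(ev$predicted_label), , drop = FALSE]
    c(sum(ev$predicted_label == ev$truth_label),
      sum(ev$predicted_label != ev$truth_label))
  }
  tab <- rbind(silence = correct(events_silence),
               noise = correct(events_noise))
  colnames(tab) <- c("correct", "incorrect")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(chi2 = unname(ht$statistic), p = unname(ht$p.value),
         df = unname(ht$parameter),
         silence_correct = tab[1, 1], silence_incorrect = tab[1, 2],
         noise_correct = tab[2, 1], noise_incorrect = tab[2, 2])
}

#' Run the full classifier on one recording
#'
#' Composes the stages end to end: calibrate the detection threshold on the
#' annotated baseline (quiet rest), fit the respiratory threshold on the
#' baseline RLL profile and the resting curve model on the baseline
#' cross-correlation curves, then detect, screen and classify every EDR of
#' the test recording and score the result against its ground truth.
#' Deterministic given the inputs and `seed`.
#'
#' @param rec The annotated test [recording()].
#' @param baseline_rec An annotated quiet-rest [recording()] of at least
#'   30 s from the same session.
#' @param cfg A [detector_config()]; its `D` is replaced by the calibrated
#'   threshold unless `calibrate = FALSE`.
#' @param n_boot,alpha_level,seed Bootstrap settings for
#'   [fit_resting_model()].
#' @param calibrate Recalibrate `D` on the baseline by ROC analysis.
#' @param model Optional prefitted [fit_resting_model()] (skips refitting,
#'   e.g. when classifying several trials of one session).
#' @return List: `events` (classified + truth-labelled), `report`
#'   (from [evaluate_events()]), `model`, `resp_threshold`, `D`.
#' @export
run_pipeline <- function(rec, baseline_rec, cfg = detector_config(),
                         n_boot = 1000, alpha_level = 0.05, seed = 1L,
                         calibrate = TRUE, model = NULL) {
  if (duration(baseline_rec) < 30) {
    abort("baseline recording must be at least 30 s to fit the resting model.")
  }
  if (calibrate) cfg$D <- calibrate_threshold(baseline_rec)
  thr <- fit_resp_threshold(rll_profile(baseline_rec))
  if (is.null(model)) {
    model <- fit_resting_model(corr_curves(cardio_series(baseline_rec)),
                               alpha_level = alpha_level, n_boot = n_boot,
                               seed = seed)
  }
  events <- detect_edr(rec, cfg)
  if (nrow(events) == 0L) {
    return(list(events = events, report = NULL, model = model,
                resp_threshold = thr, D = cfg$D))
  }
  flags <- flag_irregular_breaths(rll_profile(rec), thr)
  track <- indicator_track(model, cardio_series(rec))
  events <- classify_edr(events, flags, track, duration(rec))
  events <- assign_truth(events, rec)
  list(events = events, report = evaluate_events(events), model = model,
       resp_threshold = thr, D = cfg$D)
}
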