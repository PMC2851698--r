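#' Respiration length line of one window
#'
#' Sum of the Euclidean distances between successive sample points of the
#' respiration trace in the (time, amplitude) plane, i.e. the arc length of
#' the sampled curve over a five-second window: each step contributes
#' `sqrt(delta^2 + (r[i+1] - r[i])^2)` with `delta = 1/f` the sampling
#' interval.  The RLL combines respiration rate and amplitude; suppressed
#' breathing shortens it, a deep inspiration lengthens it.
#'
#' @param resp_window Respiration samples covering one window.
#' @param delta Sampling interval in seconds.
#' @param window_s Expected window length (seconds); the sample count must
#'   match `round(window_s / delta)`.
#' @return Arc length (time measured in seconds, amplitude in belt units).
#' @export
#' @examples
#' rll(rep(0, 1280), 1 / 256)   # flat trace: pure time-axis length ~ 4.9961
rll <- function(resp_window, delta, window_s = 5) {
  if (length(resp_window) != round(window_s / delta)) {
    abort(sprintf("expected %d samples for a %g-s window at delta = %g.",
                  round(window_s / delta), window_s, delta))
  }
  sum(sqrt(delta^2 + diff(resp_window)^2))
}

#' Shift-averaged RLL profile
#'
#' For each whole second `t`, the five-second RLL is recomputed from
#' windows starting at `t, t + 0.1, ..., t + 1.0` s and averaged, damping
#' the dependence of a single RLL measurement on its starting point on the
#' curvilinear breathing trace.  (The recomputation is done 10 more times
#' after the first, so 11 windows enter each average.)
#'
#' @param resp Respiration samples (or an [recording()], from which the
#'   `resp` channel is taken).
#' @param fs Sampling rate in Hz (ignored when `resp` is a recording).
#' @param window_s RLL window length, 5 s.
#' @param n_shifts Number of additional shifted windows, 10.
#' @param shift_s Shift increment, 0.1 s.
#' @return Tibble with columns `t` (whole seconds, starting at 0) and
#'   `rll_avg`.
#' @export
rll_profile <- function(resp, fs = 256, window_s = 5, n_shifts = 10,
                        shift_s = 0.1) {
  if (inherits(resp, "edr_recording")) {
    fs <- sampling_rate(resp)
    resp <- resp$resp
  }
  delta <- 1 / fs
  need <- window_s + n_shifts * shift_s
  T_total <- length(resp) / fs
  if (T_total < need) {
    abort(sprintf("series too short: need at least %g s, got %g s.", need, T_total))
  }
  w <- round(window_s * fs)
  t_max <- floor(T_total - window_s - n_shifts * shift_s)
  ts <- 0:t_max
  shifts <- seq(0, by = shift_s, length.out = n_shifts + 1L)
  # arc length per step, once; window sums via cumulative sums
  step <- sqrt(delta^2 + diff(resp)^2)
  cstep <- c(0, cumsum(step))
  rll_at <- function(start_s) {
    i0 <- round(start_s * fs)             # 0-based first sample of window
    cstep[i0 + w] - cstep[i0 + 1]         # sum over the w - 1 in-window steps
  }
  avg <- purrr::map_dbl(ts, function(t) mean(purrr::map_dbl(t + shifts, rll_at)))
  tibble(t = as.numeric(ts), rll_avg = avg)
}

#' Robust respiratory threshold from baseline breathing
#'
#' Trims the lowest and highest 5% of the baseline `rll_avg` values,
#' computes the mean and standard deviation of the remainder, and sets the
#' two-sided respiratory threshold `psi = mu_trim +/- 3 sigma_trim`.
#'
#' @param baseline_profile Tibble from [rll_profile()] computed on quiet
#'   baseline breathing (at least 20 values).
#' @param trim_frac Fraction trimmed from each tail.
#' @param k Band half-width in trimmed SDs.
#' @return One-row tibble of class `resp_threshold`: `mu_trim`,
#'   `sigma_trim`, `psi_lower`, `psi_upper`, `trim_frac`.
#' @export
fit_resp_threshold <- function(baseline_profile, trim_frac = 0.05, k = 3) {
  x <- baseline_profile$rll_avg
  if (length(x) < 20L) abort("need at least 20 baseline RLL values to fit the threshold.")
  stats <- trimmed_stats(x, trim_frac)
  sigma <- stats$sigma
  if (sigma == 0) {
    warn("degenerate respiratory threshold: trimmed SD is zero; widening by machine epsilon.")
    sigma <- .Machine$double.eps
  }
  out <- tibble(mu_trim = stats$mu, sigma_trim = stats$sigma,
                psi_lower = stats$mu - k * sigma,
                psi_upper = stats$mu + k * sigma,
                trim_frac = trim_frac)
  class(out) <- c("resp_threshold", class(out))
  out
}

# two-sided trimmed moments: drop floor(trim * n) values from each tail.
# The raw SD of the trimmed sample is biased low (for a Gaussian, two-sided
# 5% trimming shrinks it to ~0.789 sigma); as is conventional for robust
# scale estimators, it is rescaled to be consistent with sigma under
# normality, so the +/- 3 sigma_trim band has its nominal coverage.
trimmed_stats <- function(x, trim = 0.05) {
  n <- length(x)
  k <- floor(trim * n)
  xs <- sort(x)
  core <- xs[seq.int(k + 1L, n - k)]
  a <- stats::qnorm(1 - trim)
  consistency <- sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
  list(mu = mean(core),
       sigma = if (length(core) > 1L) sd(core) / consistency else 0)
}

#' Flag seconds containing an irregular breath
#'
#' A second `t` is flagged when its averaged RLL falls strictly outside
#' `[psi_lower, psi_upper]`; the flag covers the five-second window of
#' respiration starting at `t`.
#'
#' @param profile Tibble from [rll_profile()].
#' @param thr A [fit_resp_threshold()] result.
#' @return `profile` with logical column `flag` added.
#' @export
flag_irregular_breaths <- function(profile, thr) {
  stopifnot(inherits(thr, "resp_threshold"))
  dplyr::mutate(profile,
                flag = .data$rll_avg < thr$psi_lower |
                       .data$rll_avg > thr$psi_upper)
}
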