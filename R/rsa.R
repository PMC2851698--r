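#' Instantaneous heart rate from the blood volume pulse
#'
#' Locates pulse peaks (local maxima at least `min_sep_s` apart with
#' prominence of at least a quarter of the signal's interquartile range),
#' converts each interbeat interval to rate (`HR = 60 / IBI` bpm), places
#' the rate at the interval midpoint, interpolates linearly onto the
#' sampling grid and applies a short moving average to remove residual
#' beat-by-beat structure; leading and trailing samples are extended from
#' the nearest defined value.
#'
#' @param bvp BVP samples (or an [recording()]).
#' @param fs Sampling rate in Hz (ignored when `bvp` is a recording).
#' @param min_sep_s Minimum peak separation (0.33 s allows rates to 180 bpm).
#' @param prominence_frac Minimum peak prominence as a fraction of the IQR.
#' @param smooth_s Moving-average length.
#' @return Numeric HR series in bpm, same length as `bvp`.
#' @export
hr_from_bvp <- function(bvp, fs = 256, min_sep_s = 0.33,
                        prominence_frac = 0.25, smooth_s = 0.5) {
  if (inherits(bvp, "edr_recording")) {
    fs <- sampling_rate(bvp)
    bvp <- bvp$bvp
  }
  peaks <- find_pulse_peaks(bvp, fs, min_sep_s, prominence_frac)
  if (length(peaks) < 2L) abort("fewer than 2 detectable pulse peaks in the BVP signal.")
  rate <- 60 * fs / diff(peaks)
  mid <- (head(peaks, -1L) + tail(peaks, -1L)) / 2
  hr <- if (length(rate) == 1L) {
    rep(rate, length(bvp))
  } else {
    stats::approx(mid, rate, xout = seq_along(bvp), rule = 2)$y
  }
  smooth_ma(hr, round(smooth_s * fs))
}

find_pulse_peaks <- function(x, fs, min_sep_s = 0.33, prominence_frac = 0.25) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer())
  # enforce minimum separation first (keeping the higher of a close pair);
  # this bounds the prominence scans to one per surviving candidate
  min_sep <- round(min_sep_s * fs)
  if (length(cand) > 1L) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer()
    for (i in ord) {
      if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  prom_floor <- prominence_frac * stats::IQR(x)
  cand[purrr::map_lgl(cand, function(i) peak_prominence(x, i, cand) >= prom_floor)]
}

# classical prominence: height above the higher of the two valley minima
# between this peak and the nearest higher ground on each side
peak_prominence <- function(x, i, cand) {
  n <- length(x)
  left <- if (any(x[seq_len(i - 1L)] > x[i])) {
    j <- max(which(x[seq_len(i - 1L)] > x[i]))
    min(x[j:i])
  } else min(x[1:i])
  right <- if (any(x[seq.int(i, n)] > x[i])) {
    j <- i - 1L + min(which(x[seq.int(i, n)] > x[i]))
    min(x[i:j])
  } else min(x[i:n])
  x[i] - max(left, right)
}

#' Standardised cardiorespiratory change series
#'
#' Computes the forward relative heart-rate change
#' `HR'(t) = (HR(t + delta) - HR(t)) / HR(t)` and the respiration first
#' difference `R'(t)`, and z-scores both over the full trial to zero mean
#' and unit variance (`HR_z`, `R_z`).
#'
#' @param rec An [recording()].
#' @param hr Optional precomputed HR series (bpm); extracted from the BVP
#'   channel by default.
#' @return Tibble of class `cardio_series` with columns `time`, `hr_bpm`,
#'   `hr_rel`, `resp_diff`, `hr_z`, `resp_z` (one row per first-difference
#'   sample, i.e. one fewer than the recording) and attributes `fs`,
#'   `delta`.
#' @export
cardio_series <- function(rec, hr = NULL) {
  fs <- sampling_rate(rec)
  if (is.null(hr)) hr <- hr_from_bvp(rec$bvp, fs)
  if (any(hr <= 0)) abort("non-positive heart rate.")
  n <- nrow(rec)
  hr_rel <- (hr[-1] - hr[-n]) / hr[-n]
  resp_diff <- diff(rec$resp)
  if (sd(hr_rel) == 0 || sd(resp_diff) == 0) {
    abort("zero-variance channel: cannot standardise a constant series.")
  }
  out <- tibble(
    time = rec$time[-n],
    hr_bpm = hr[-n],
    hr_rel = hr_rel,
    resp_diff = resp_diff,
    hr_z = as.numeric(scale(hr_rel)),
    resp_z = as.numeric(scale(resp_diff))
  )
  attr(out, "fs") <- fs
  attr(out, "delta") <- 1 / fs
  class(out) <- c("cardio_series", class(tibble()))
  out
}

#' Number of two-second correlation windows in a trial
#'
#' `M = ceiling(T - delta) - 1` windows; window `m` spans
#' `[m - 1, m + 1]` seconds, a two-second sliding window with 50% overlap.
#'
#' @param T_s Trial duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return Integer window count.
#' @export
n_corr_windows <- function(T_s, fs = 256) {
  as.integer(ceiling(T_s - 1 / fs) - 1)
}

# lagged cross-correlation sums via FFT; returns sum_t x[t] * y[t + tau]
# for tau = -max_lag..max_lag, divided by the overlap count n - |tau|
lagged_xcorr <- function(x, y, max_lag) {
  n <- length(x)
  stopifnot(length(y) == n, max_lag < n)
  N <- stats::nextn(n + max_lag, 2)
  X <- fft(c(x, numeric(N - n)))
  Y <- fft(c(y, numeric(N - n)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / N
  # cc[m + 1] = sum_t x[t] y[t + m] (mod N); no wrap for |m| <= max_lag
  lags <- (-max_lag):max_lag
  vals <- cc[ifelse(lags >= 0, lags, N + lags) + 1L]
  vals / (n - abs(lags))
}

#' Windowed cross-correlation curves
#'
#' For each window `m` (spanning `[m - 1, m + 1]` s), the normalised
#' cross-correlation between the standardised heart-rate change and
#' respiration change series is evaluated over lags `tau` of up to one
#' second in either direction on the sampling grid:
#' `rho_m(tau) = sum_t HR_z(t) R_z(t + tau) / n_overlap(tau)`, both series
#' restricted to the window.  One curve of `2 fs + 1` points per window.
#'
#' @param cs A [cardio_series()].
#' @param max_lag_s Maximum lag in seconds.
#' @return Long tibble with columns `window`, `t_start`, `t_end`, `lag_s`,
#'   `value`; attribute `n_points` gives the curve length.
#' @export
corr_curves <- function(cs, max_lag_s = 1) {
  fs <- attr(cs, "fs", exact = TRUE)
  n <- nrow(cs)
  T_s <- (n + 1) / fs
  if (T_s < 2) abort("trial shorter than one 2-s correlation window.")
  M <- n_corr_windows(T_s, fs)
  max_lag <- round(max_lag_s * fs)
  curves <- purrr::map(seq_len(M), function(m) {
    i0 <- (m - 1L) * fs + 1L
    i1 <- min(n, (m + 1L) * fs)
    lagged_xcorr(cs$hr_z[i0:i1], cs$resp_z[i0:i1], max_lag)
  })
  out <- tibble(
    window = rep(seq_len(M), each = 2L * max_lag + 1L),
    t_start = rep(seq_len(M) - 1, each = 2L * max_lag + 1L),
    lag_s = rep(seq(-max_lag, max_lag) / fs, times = M),
    value = unlist(curves)
  )
  out$t_end <- out$t_start + 2
  attr(out, "n_points") <- 2L * max_lag + 1L
  attr(out, "fs") <- fs
  out[c("window", "t_start", "t_end", "lag_s", "value")]
}

# long curve tibble -> windows x points matrix
curves_matrix <- function(curves) {
  npt <- attr(curves, "n_points", exact = TRUE) %||%
    sum(curves$window == curves$window[1])
  matrix(curves$value, ncol = npt, byrow = TRUE,
         dimnames = list(unique(curves$window), NULL))
}

#' Finite Fourier representation of a correlation curve
#'
#' Fits `f(x) = mu + sum_k alpha_k cos(2 pi k x / P) + beta_k sin(2 pi k x / P)`
#' over the curve's own support (period `P` = curve length) by discrete
#' Fourier transform.  The requested number of harmonics `K` (512 by
#' default) is capped at `floor((n_points - 1) / 2)`, the harmonic capacity
#' of the sampled curve; at the cap the reconstruction is exact for curves
#' with an odd number of points.
#'
#' @param values Curve samples.
#' @param K Requested harmonics.
#' @return List of class `fourier_curve`: `mu`, `alpha`, `beta`, `k_eff`,
#'   `n_points`, `fitted` (reconstruction on the sample grid),
#'   `max_resid` (max abs reconstruction error).
#' @export
fit_fourier <- function(values, K = 512) {
  if (K < 1) abort("`K` must be at least 1.")
  n <- length(values)
  if (n < 3L) abort("need at least 3 points to fit a Fourier curve.")
  k_eff <- min(as.integer(K), (n - 1L) %/% 2L)
  X <- fft(values)
  mu <- Re(X[1]) / n
  ks <- seq_len(k_eff)
  alpha <- 2 * Re(X[ks + 1L]) / n
  beta <- -2 * Im(X[ks + 1L]) / n
  fitted <- fourier_eval(mu, alpha, beta, n)
  structure(list(mu = mu, alpha = alpha, beta = beta, k_eff = k_eff,
                 n_points = n, fitted = fitted,
                 max_resid = max(abs(fitted - values))),
            class = "fourier_curve")
}

# evaluate the truncated Fourier sum on the original sample grid;
# the harmonic basis is cached per (n, k_eff) since curve geometry repeats
fourier_basis_cache <- new.env(parent = emptyenv())

fourier_basis <- function(n, k_eff) {
  key <- paste0(n, "_", k_eff)
  b <- fourier_basis_cache[[key]]
  if (is.null(b)) {
    x <- (seq_len(n) - 1L) / n
    ang <- 2 * pi * outer(x, seq_len(k_eff))
    b <- list(cos = cos(ang), sin = sin(ang))
    fourier_basis_cache[[key]] <- b
  }
  b
}

fourier_eval <- function(mu, alpha, beta, n) {
  if (length(alpha) == 0L) return(rep(mu, n))
  b <- fourier_basis(n, length(alpha))
  drop(mu + b$cos %*% alpha + b$sin %*% beta)
}

#' @export
print.fourier_curve <- function(x, ...) {
  cat(sprintf("<fourier_curve: %d points, %d harmonics, max residual %.3g>\n",
              x$n_points, x$k_eff, x$max_resid))
  invisible(x)
}

# coefficient vector W = (mu, alpha_1..K, beta_1..K)
fourier_w <- function(fc) c(fc$mu, fc$alpha, fc$beta)
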