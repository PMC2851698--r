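#' Fit the resting cardiorespiratory curve model with bootstrap prediction bands
#'
#' Each resting cross-correlation curve is represented by its finite
#' Fourier sum; the coefficient vectors are averaged into `W_bar`, giving
#' the mean curve `M(t)`, and the variability curve `S(t)` is the pointwise
#' sample standard deviation of the fitted curves around `M(t)`.  The band
#' constant `theta` is calibrated by bootstrap: each of `n_boot` resamples
#' draws `M - 1` curves with replacement, recomputes the resample's mean
#' and variability curves, and records the standardised deviations
#' `D_ij(t) = (C_j(t) - M_i(t)) / S_i(t)` of its curves.  By default
#' `theta` is the empirical `1 - alpha_level` quantile (order statistic,
#' type "higher") of the per-curve maxima `max_t |D_ij(t)|`, so a single
#' curve drawn from the resting population falls inside the prediction
#' bands `U = M + theta S`, `L = M - theta S` with probability
#' `1 - alpha_level`.  Setting `family_wise = TRUE` instead takes the
#' quantile of the per-resample maxima over all `M - 1` curves jointly,
#' which bounds the worst curve of a whole resample and is far more
#' conservative for single-segment testing.
#'
#' @param curves Long curve tibble from [corr_curves()] (or a numeric
#'   matrix, one row per curve).
#' @param K Requested Fourier harmonics (capped at the curves' capacity).
#' @param alpha_level Band miscoverage probability (0.05).
#' @param n_boot Number of bootstrap resamples (1000).
#' @param seed Integer seed for the bootstrap.
#' @param family_wise Calibrate `theta` on per-resample maxima over all
#'   curves rather than per-curve maxima.
#' @return Object of class `resting_model`: `w_bar`, `m_curve`, `s_curve`,
#'   `theta`, `u_curve`, `l_curve`, `alpha_level`, `n_boot`, `n_curves`,
#'   `k_eff`, `lag_s`, `d_star` (the bootstrap maxima theta was drawn
#'   from).
#' @export
fit_resting_model <- function(curves, K = 512, alpha_level = 0.05,
                              n_boot = 1000, seed = 1L, family_wise = FALSE) {
  X <- if (is.matrix(curves)) curves else curves_matrix(curves)
  M <- nrow(X)
  if (M < 5L) abort("too few resting curves (need at least 5).")
  if (M < 25L) warn("fewer than 25 resting curves; the band model may be unreliable.")
  lag_s <- if (!is.matrix(curves) && "lag_s" %in% names(curves)) {
    curves$lag_s[curves$window == curves$window[1]]
  } else seq_len(ncol(X))
  fits <- apply(X, 1L, fit_fourier, K = K, simplify = FALSE)
  k_eff <- fits[[1]]$k_eff
  W <- do.call(rbind, lapply(fits, fourier_w))        # M x (2 k_eff + 1)
  Fhat <- do.call(rbind, lapply(fits, `[[`, "fitted")) # fitted curves
  w_bar <- colMeans(W)
  m_curve <- fourier_eval(w_bar[1], w_bar[1 + seq_len(k_eff)],
                          w_bar[1 + k_eff + seq_len(k_eff)], ncol(X))
  s_curve <- pointwise_sd(Fhat, m_curve)
  s_curve <- floor_sd(s_curve)

  set.seed(seed)
  d_star <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(M, M - 1L, replace = TRUE)
    Fi <- Fhat[idx, , drop = FALSE]
    m_i <- colMeans(Fi)
    s_i <- floor_sd(pointwise_sd(Fi, m_i), quiet = TRUE)
    if (family_wise) {
      dev <- abs(sweep(sweep(Fi, 2L, m_i, "-"), 2L, s_i, "/"))
      d_star[i] <- max(dev)
    } else {
      # a randomly drawn curve from the population acts as the predictive draw
      j <- sample.int(M, 1L)
      d_star[i] <- max(abs((Fhat[j, ] - m_i) / s_i))
    }
  }
  theta <- sort(d_star)[ceiling((1 - alpha_level) * n_boot)]
  structure(list(
    w_bar = w_bar, m_curve = m_curve, s_curve = s_curve, theta = theta,
    u_curve = m_curve + theta * s_curve, l_curve = m_curve - theta * s_curve,
    alpha_level = alpha_level, n_boot = n_boot, n_curves = M,
    k_eff = k_eff, lag_s = lag_s, d_star = d_star,
    family_wise = family_wise, seed = seed
  ), class = "resting_model")
}

pointwise_sd <- function(X, center) {
  n <- nrow(X)
  if (n < 2L) return(numeric(ncol(X)))
  sqrt(pmax(0, colSums(sweep(X, 2L, center, "-")^2) / (n - 1L)))
}

floor_sd <- function(s, eps = 1e-12, quiet = FALSE) {
  if (any(s < eps)) {
    if (!quiet) warn("variability curve touches zero; applying epsilon floor.")
    s <- pmax(s, eps)
  }
  s
}

#' Test a correlation curve for resting-model membership
#'
#' Fits the Fourier representation `Q(s)` of the test curve, forms the
#' standardised difference `D(s) = (Q(s) - M(s)) / S(s)` against the
#' resting mean and variability curves, and raises the indicator when
#' `max |D|` exceeds `theta` (equivalently, when the curve leaves the
#' prediction bands).
#'
#' @param model A [fit_resting_model()].
#' @param curve Numeric curve (same length as the model curves), or a
#'   one-window slice of a [corr_curves()] tibble.
#' @return One-row tibble: `d_max`, `indicator` (1 = outside the bands,
#'   i.e. non-resting), and the standardised difference curve as the
#'   list-column `d_curve`.
#' @export
test_membership <- function(model, curve) {
  stopifnot(inherits(model, "resting_model"))
  if (is.data.frame(curve)) {
    stopifnot(length(unique(curve$window)) == 1L)
    curve <- curve$value
  }
  if (length(curve) != length(model$m_curve)) {
    abort("test curve length does not match the model curves.")
  }
  fc <- fit_fourier(curve, K = model$k_eff)
  d <- (fc$fitted - model$m_curve) / model$s_curve
  d_max <- max(abs(d))
  tibble(d_max = d_max,
         indicator = as.integer(d_max > model$theta),
         d_curve = list(tibble(lag_s = model$lag_s, d = d)))
}

#' Indicator track over a whole trial
#'
#' Applies the membership test to every two-second sliding window of the
#' trial; the indicator pulse of window `m` spans `[m - 1, m + 1]` s.
#'
#' @param model A [fit_resting_model()].
#' @param cs A [cardio_series()] (or a precomputed [corr_curves()] tibble).
#' @return Tibble with one row per window: `window`, `t_start`, `t_end`,
#'   `d_max`, `indicator`.
#' @export
indicator_track <- function(model, cs) {
  stopifnot(inherits(model, "resting_model"))
  curves <- if (inherits(cs, "cardio_series")) corr_curves(cs) else cs
  X <- curves_matrix(curves)
  res <- purrr::map_dbl(seq_len(nrow(X)), function(i) {
    fc <- fit_fourier(X[i, ], K = model$k_eff)
    max(abs((fc$fitted - model$m_curve) / model$s_curve))
  })
  meta <- dplyr::distinct(curves[c("window", "t_start", "t_end")])
  tibble(window = meta$window, t_start = meta$t_start, t_end = meta$t_end,
         d_max = res, indicator = as.integer(res > model$theta))
}

#' @export
print.resting_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Resting cardiorespiratory curve model\n",
    "  curves: %d (%d points each, %d harmonics)\n",
    "  bootstrap: %d resamples of M - 1 curves%s\n",
    "  theta = %.4g at alpha = %g\n"),
    x$n_curves, length(x$m_curve), x$k_eff, x$n_boot,
    if (x$family_wise) " (family-wise maxima)" else "",
    x$theta, x$alpha_level))
  invisible(x)
}

#' Tidy the fitted resting model
#'
#' @param x A [fit_resting_model()].
#' @param ... Unused.
#' @return One row per curve point: `lag_s`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @method tidy resting_model
#' @export
tidy.resting_model <- function(x, ...) {
  tibble(lag_s = x$lag_s, mean = x$m_curve, sd = x$s_curve,
         lower = x$l_curve, upper = x$u_curve)
}

#' @rdname tidy.resting_model
#' @return `glance()`: one row with `theta`, `alpha_level`, `n_boot`,
#'   `n_curves`, `k_eff`.
#' @method glance resting_model
#' @export
glance.resting_model <- function(x, ...) {
  tibble(theta = x$theta, alpha_level = x$alpha_level, n_boot = x$n_boot,
         n_curves = x$n_curves, k_eff = x$k_eff)
}

#' Plot the resting model's prediction bands
#'
#' @param object A [fit_resting_model()].
#' @param ... Unused.
#' @return A ggplot: mean curve with the `M +/- theta S` band over lag.
#' @method autoplot resting_model
#' @export
autoplot.resting_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue4") +
    ggplot2::labs(x = "lag (s)", y = "cross-correlation",
                  title = sprintf("Resting model: %d curves, theta = %.3g",
                                  object$n_curves, object$theta)) +
    ggplot2::theme_minimal()
}
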