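#' Threshold-crossing miniature-event detector
#'
#' Simple plumbing detector: events are negative threshold crossings of the
#' smoothed trace at `k_sd` times the baseline SD, with a refractory gap.
#' Intended for synthetic and well-isolated data; it makes no attempt at
#' template matching or overlapping-event resolution.
#'
#' @param rec A [recording].
#' @param k_sd Detection threshold in baseline SDs (default 5).
#' @param min_sep_ms Minimum separation between event peaks in ms (default 5).
#' @param window_ms Extraction window: `c(pre, post)` around the event peak
#'   in ms (default `c(1, 8)`).
#' @param smooth_n Binomial smoothing order used for detection (default 20).
#'
#' @return List with `times` (peak times in ms), `waveforms` (matrix, events
#'   x samples, raw trace, peak-aligned), `peak_index`.
#' @export
detect_mini_events <- function(rec, k_sd = 5, min_sep_ms = 5,
                               window_ms = c(1, 8), smooth_n = 20) {
  stopifnot(inherits(rec, "recording"))
  xs <- binomial_smooth(rec$samples, smooth_n)
  bl_sd <- stats::sd(xs)          # conservative: includes events
  bl_sd <- stats::sd(xs[abs(xs - stats::median(xs)) < 3 * bl_sd])
  thr <- stats::median(xs) - k_sd * bl_sd
  below <- xs < thr
  if (!any(below)) return(list(times = numeric(0),
                               waveforms = matrix(0, 0, 0), peak_index = 0L))
  rate <- rec$rate
  starts <- which(diff(c(FALSE, below)) == 1)
  ends <- which(diff(c(below, FALSE)) == -1)
  peaks <- mapply(function(s, e) s - 1 + which.min(xs[s:e]), starts, ends)
  keep <- c(TRUE, diff(peaks) / rate >= min_sep_ms)
  peaks <- peaks[keep]
  pre_n <- round(window_ms[1] * rate); post_n <- round(window_ms[2] * rate)
  ok <- peaks - pre_n >= 1 & peaks + post_n <= length(xs)
  peaks <- peaks[ok]
  W <- t(vapply(peaks, function(p) rec$samples[(p - pre_n):(p + post_n)],
                numeric(pre_n + post_n + 1)))
  list(times = (peaks - 1) / rate, waveforms = W, peak_index = pre_n + 1L)
}

#' Summary statistics of a miniature-event table
#'
#' @param events Event table (see [read_event_table]).
#' @param duration_ms Recording duration in ms.
#' @return List with `mean_amplitude` (pA), `mean_charge` (pC),
#'   `frequency` (Hz), `rise_10_90` (ms), `decay_tau` (ms), `n_events`.
#'   With zero events the frequency is 0 and the means are NA.
#' @export
mini_stats <- function(events, duration_ms) {
  stopifnot(duration_ms > 0)
  n <- nrow(events)
  if (n == 0)
    return(list(mean_amplitude = NA_real_, mean_charge = NA_real_,
                frequency = 0, rise_10_90 = NA_real_, decay_tau = NA_real_,
                n_events = 0L))
  list(mean_amplitude = mean(events$amplitude),
       mean_charge = mean(events$charge),
       frequency = n / (duration_ms / 1000),
       rise_10_90 = mean(events$rise_10_90),
       decay_tau = mean(events$decay_tau),
       n_events = n)
}

#' Peak-scaled non-stationary fluctuation analysis of mEPSC decays
#'
#' The mean event waveform is scaled to each event's peak; the residual
#' variance across events is computed at every sample of the decay, the
#' (mean amplitude, variance) points are pooled into `bins` equal-width
#' mean-amplitude bins, and the parabola
#' \deqn{\sigma^2(\bar I) = i\,\bar I - \bar I^2/N + b}
#' is fitted by weighted least squares (weights = points per bin; the
#' baseline variance b is fitted, not pre-subtracted). The unitary current i
#' and the number of channels open at the peak N follow from the linear and
#' quadratic coefficients; the single-channel conductance is
#' `g = i / |v_hold - e_rev|`.
#'
#' Event peaks are estimated as the mean of a 100 microsecond window around
#' the aligned peak sample, which keeps the peak-scaling step from
#' propagating single-sample baseline noise into the variance parabola.
#'
#' @param waveforms Matrix of aligned events (rows = events; consistent sign,
#'   negative- or positive-going).
#' @param peak_index Column index of the aligned peak.
#' @param rate Sampling rate in kHz.
#' @param v_hold Holding potential in mV.
#' @param e_rev Reversal potential in mV (default 0).
#' @param bins Number of mean-amplitude bins (default 10).
#' @param decay_floor Decay samples are used while the mean amplitude
#'   exceeds this fraction of the peak (default 0.03).
#' @param decay_ceiling Decay samples with mean amplitude above this
#'   fraction of the peak are excluded (default 0.97): right at the peak the
#'   peak-scaling step suppresses the channel-gating variance to zero while
#'   recording noise does not shrink, so near-peak points carry almost pure
#'   noise and bias the unitary current upward.
#'
#' @return An object of class `nsfa_result`: `i_unitary` (pA), `n_channels`,
#'   `g_unitary` (pS), `baseline_var` (pA^2), `n_events_used`, `fit_r2`,
#'   `binned` (data.frame `mean_amp`, `variance`, `n`), `flags`. Refuses
#'   (error) with 50 events or fewer; a non-positive fitted i or a
#'   degenerate zero-variance input yields a flagged failure (fields NA).
#' @export
peak_scaled_nsfa <- function(waveforms, peak_index, rate, v_hold,
                             e_rev = 0, bins = 10, decay_floor = 0.03,
                             decay_ceiling = 0.97) {
  n_ev <- nrow(waveforms)
  if (n_ev <= 50)
    stop("peak-scaled NSFA requires more than 50 events (got ", n_ev, ")")
  if (v_hold == e_rev) stop("zero driving force")
  # flip to positive-going magnitudes for internal math
  mw0 <- colMeans(waveforms)
  sgn <- if (mw0[peak_index] < 0) -1 else 1
  W <- waveforms * sgn
  mw <- mw0 * sgn
  hw <- max(1L, round(0.05 * rate))         # 100 us half-window
  pk_cols <- max(1, peak_index - hw):min(ncol(W), peak_index + hw)
  ev_peak <- rowMeans(W[, pk_cols, drop = FALSE])
  m_peak <- mean(mw[pk_cols])
  if (m_peak <= 0) stop("mean waveform has no peak at peak_index")
  scale <- ev_peak / m_peak
  decay_cols <- which(seq_len(ncol(W)) >= peak_index &
                        mw >= decay_floor * m_peak &
                        mw <= decay_ceiling * m_peak)
  res <- W[, decay_cols, drop = FALSE] -
    outer(scale, mw[decay_cols])
  v <- apply(res, 2, stats::var)
  a <- mw[decay_cols]
  flags <- character(0)
  if (max(v) < 1e-12) {
    return(structure(list(i_unitary = NA_real_, n_channels = NA_real_,
                          g_unitary = NA_real_, baseline_var = NA_real_,
                          n_events_used = n_ev, fit_r2 = NA_real_,
                          binned = NULL, flags = "degenerate_zero_variance"),
                     class = "nsfa_result"))
  }
  br <- range(a)
  cuts <- seq(br[1], br[2], length.out = bins + 1)
  bin <- pmin(pmax(findInterval(a, cuts, rightmost.closed = TRUE), 1), bins)
  bd <- data.frame(
    mean_amp = tapply(a, bin, mean),
    variance = tapply(v, bin, mean),
    n = as.vector(table(factor(bin, levels = seq_len(bins)))))
  bd <- bd[bd$n > 0, ]
  fit <- stats::lm(variance ~ mean_amp + I(mean_amp^2), data = bd,
                   weights = bd$n)
  cf <- stats::coef(fit)
  b <- unname(cf[1]); i_u <- unname(cf[2]); c2 <- unname(cf[3])
  r2 <- summary(fit)$r.squared
  if (!(i_u > 0)) {
    return(structure(list(i_unitary = NA_real_, n_channels = NA_real_,
                          g_unitary = NA_real_, baseline_var = b,
                          n_events_used = n_ev, fit_r2 = r2, binned = bd,
                          flags = "negative_unitary_current"),
                     class = "nsfa_result"))
  }
  n_ch <- if (c2 < 0) -1 / c2 else NA_real_
  if (is.na(n_ch)) flags <- c(flags, "nonconcave_parabola")
  g <- i_u / abs(v_hold - e_rev) * 1000     # pA/mV = nS -> pS
  structure(list(i_unitary = i_u, n_channels = n_ch, g_unitary = g,
                 baseline_var = b, n_events_used = n_ev, fit_r2 = r2,
                 binned = bd, flags = flags),
            class = "nsfa_result")
}

#' @export
print.nsfa_result <- function(x, ...) {
  if (length(x$flags) && is.na(x$i_unitary)) {
    cat("<nsfa_result> failed:", paste(x$flags, collapse = ", "), "\n")
  } else {
    cat(sprintf(
      "<nsfa_result> i = %.3g pA, N = %.3g, g = %.3g pS (r2 = %.3f, %d events)\n",
      x$i_unitary, x$n_channels, x$g_unitary, x$fit_r2, x$n_events_used))
  }
  invisible(x)
}
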