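#' Binomial smoothing
#'
#' Convolution with normalized Pascal-triangle coefficients of order `n`
#' (the near-Gaussian smoothing kernel of common acquisition software),
#' edge-padded by reflection so the output length equals the input length.
#'
#' @param x Numeric vector.
#' @param n Kernel order (default 50, i.e. 51 coefficients).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
binomial_smooth <- function(x, n = 50) {
  if (n < 1) return(x)
  k <- stats::dbinom(0:n, n, 0.5)
  h <- (length(k) - 1) / 2
  hl <- floor(h); hr <- ceiling(h)
  xp <- c(rev(x[2:(hl + 1)]), x, rev(x[(length(x) - hr):(length(x) - 1)]))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(hl + 1):(hl + length(x))])
}

window_mean <- function(x, rate, t0, t1) {
  i0 <- max(1L, floor(t0 * rate) + 1L)
  i1 <- min(length(x), ceiling(t1 * rate))
  if (i1 < i0) stop("window error: empty analysis window [", t0, ", ", t1, "] ms")
  mean(x[i0:i1])
}

#' Measure a single evoked EPSC
#'
#' Amplitude is peak-to-baseline after binomial smoothing: the baseline is
#' the mean of a 2 ms window before the stimulus (or, for in-train EPSCs, of
#' a 400 microsecond window immediately after the stimulation artifact), and
#' the peak is the mean of a 100 microsecond window centred on the
#' post-stimulus current minimum (ties: first minimum wins). Charge is the
#' integral of (baseline - current) from the stimulus to the point where the
#' smoothed trace re-crosses the baseline after the peak (or the end of the
#' charge window), in pC.
#'
#' @param rec A [recording].
#' @param stim_time Stimulus onset in ms.
#' @param in_train Use the post-artifact local baseline instead of the 2 ms
#'   pre-stimulus baseline, for EPSCs riding on previous decays.
#' @param search_ms Peak-search window length after the stimulus in ms.
#'   Default: the gap to the next stimulus in `rec$stim_times` if there is
#'   one, else 30 ms.
#' @param art_delay Dead time after stimulus onset covering the stimulation
#'   artifact, in ms (default 0.2).
#' @param charge_max_ms Upper bound of the charge-integration window in ms
#'   (default 60).
#' @param smooth_n Binomial smoothing order (default 50, matched to 200 kHz
#'   sampling; reduce for lower rates).
#'
#' @return List with `amplitude` (pA, positive magnitude), `charge` (pC),
#'   `baseline` (pA) and `t_peak` (ms).
#' @export
measure_epsc <- function(rec, stim_time, in_train = FALSE, search_ms = NULL,
                         art_delay = 0.2, charge_max_ms = 60, smooth_n = 50) {
  stopifnot(inherits(rec, "recording"))
  if (stim_time < 0 || stim_time >= rec$duration)
    stop("stimulus outside the recording")
  if (!in_train && stim_time < 2)
    stop("window error: need >= 2 ms of pre-stimulus baseline")
  if (is.null(search_ms)) {
    nxt <- rec$stim_times[rec$stim_times > stim_time + 1e-9]
    search_ms <- if (length(nxt)) min(nxt) - stim_time else
      min(30, rec$duration - stim_time)
  }
  search_ms <- min(search_ms, rec$duration - stim_time)
  xs <- binomial_smooth(rec$samples, smooth_n)
  rate <- rec$rate
  baseline <- if (in_train)
    window_mean(xs, rate, stim_time + art_delay,
                stim_time + art_delay + 0.4)
  else
    window_mean(xs, rate, stim_time - 2, stim_time)
  i0 <- floor((stim_time + art_delay) * rate) + 1L
  i1 <- min(length(xs), ceiling((stim_time + search_ms) * rate))
  seg <- xs[i0:i1]
  ipk <- which.min(seg)                       # first minimum wins
  pos_dev <- max(seg) - baseline
  neg_dev <- baseline - seg[ipk]
  if (pos_dev > 1.5 * neg_dev && pos_dev > 1e-9)
    stop("sign error: post-stimulus deflection is positive-going")
  t_peak <- (i0 + ipk - 2) / rate
  v_peak <- window_mean(xs, rate, t_peak - 0.05, t_peak + 0.05)
  amplitude <- abs(min(v_peak - baseline, 0))
  # charge: stimulus to baseline re-cross after the peak, or window end
  iend <- min(length(xs), ceiling((stim_time + charge_max_ms) * rate))
  cseg <- xs[i0:iend]
  post <- seq_along(cseg) > ipk
  recross <- which(post & cseg >= baseline)
  stop_i <- if (length(recross)) recross[1] else length(cseg)
  charge <- sum(baseline - cseg[1:stop_i]) / rate / 1000
  list(amplitude = amplitude, charge = charge, baseline = baseline,
       t_peak = t_peak)
}

#' Biexponential decay fit and 10-90% rise time of an averaged EPSC
#'
#' Fits `A * (f * exp(-t/tau_fast) + (1-f) * exp(-t/tau_slow))` by nonlinear
#' least squares to the decay (peak to end) of a baseline-subtracted averaged
#' EPSC, and measures the 10-90% rise time by linear interpolation between
#' samples on the rising phase.
#'
#' @param wave Averaged EPSC waveform (negative-going, single peak, decay
#'   covering several slow time constants), starting at the EPSC onset.
#' @param rate Sampling rate in kHz.
#' @param baseline Baseline current in pA; default is the mean of the first
#'   two samples (appropriate for onset-aligned averages). Pass the
#'   pre-stimulus baseline explicitly for waveforms cut elsewhere.
#'
#' @return List with `tau_fast`, `tau_slow` (ms, ordered), `frac_fast`,
#'   `rise_10_90` (ms), `peak` (pA magnitude) and `mono_fallback` (TRUE when
#'   the biexponential fit failed to converge and a monoexponential was
#'   used, in which case `tau_fast == tau_slow`).
#' @export
fit_epsc_decay <- function(wave, rate, baseline = NULL) {
  stopifnot(length(wave) > 10, rate > 0)
  if (is.null(baseline)) baseline <- mean(wave[1:2])
  y <- baseline - wave                      # positive magnitude
  ipk <- which.max(y)
  peak <- y[ipk]
  if (peak <= 0) stop("no negative-going peak found")
  # rise time
  ris <- y[1:ipk]
  t_ris <- (seq_len(ipk) - 1) / rate
  t10 <- {
    th <- 0.1 * peak; i <- which(ris >= th)[1]
    if (i == 1) 0 else stats::approx(ris[(i - 1):i], t_ris[(i - 1):i], th)$y
  }
  t90 <- {
    th <- 0.9 * peak; i <- which(ris >= th)[1]
    if (i == 1) 0 else stats::approx(ris[(i - 1):i], t_ris[(i - 1):i], th)$y
  }
  rise_10_90 <- t90 - t10
  # decay fit from peak
  yd <- y[ipk:length(y)]
  td <- (seq_along(yd) - 1) / rate
  # crude starts: tail fit for slow, early fit for fast
  tail_i <- td > max(td) / 3 & yd > 0
  tau_s0 <- if (sum(tail_i) > 5) {
    c0 <- unname(stats::coef(stats::lm(log(yd[tail_i]) ~ td[tail_i]))[2])
    if (is.finite(c0) && c0 < 0) -1 / c0 else max(td) / 3
  } else max(td) / 3
  tau_f0 <- unname(max(td[which(yd <= peak * exp(-1))[1]], 2 / rate,
                       na.rm = TRUE))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yd ~ A * (f * exp(-td / tf) + (1 - f) * exp(-td / ts)),
      start = list(A = peak, f = 0.7, tf = tau_f0, ts = tau_s0),
      lower = c(A = 0, f = 0, tf = 1e-3, ts = 1e-3),
      upper = c(A = Inf, f = 1, tf = Inf, ts = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  mono_fallback <- FALSE
  if (is.null(fit)) {
    mono <- tryCatch(
      minpack.lm::nlsLM(yd ~ A * exp(-td / tf),
                        start = list(A = peak, tf = tau_f0),
                        lower = c(0, 1e-3)),
      error = function(e) NULL)
    if (is.null(mono)) stop("decay fit failed")
    cf <- stats::coef(mono)
    return(list(tau_fast = unname(cf["tf"]), tau_slow = unname(cf["tf"]),
                frac_fast = 1, rise_10_90 = rise_10_90, peak = peak,
                mono_fallback = TRUE))
  }
  cf <- stats::coef(fit)
  tf <- unname(cf["tf"]); ts <- unname(cf["ts"]); f <- unname(cf["f"])
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; f <- 1 - f }
  list(tau_fast = tf, tau_slow = ts, frac_fast = f,
       rise_10_90 = rise_10_90, peak = peak, mono_fallback = mono_fallback)
}

#' Paired-pulse ratio
#'
#' @param amp1,amp2 First and second EPSC amplitudes (pA, magnitudes).
#' @return `amp2 / amp1`.
#' @export
analyze_ppr <- function(amp1, amp2) {
  if (!(amp1 > 0)) stop("PPR undefined: first amplitude must be > 0")
  amp2 / amp1
}

#' Biexponential fit of paired-pulse ratio versus inter-stimulus interval
#'
#' Fits `PPR(ISI) = 1 - a_f * exp(-ISI/tau_f) - a_s * exp(-ISI/tau_s)`,
#' approaching 1 at large intervals. The fast time constant tracks the
#' recovery of the fast depression component (receptor desensitization and
#' vesicle depletion at short intervals).
#'
#' @param isi Inter-stimulus intervals in ms.
#' @param ppr Paired-pulse ratios at those intervals.
#' @return List with `tau_fast`, `tau_slow` (ms, ordered), `a_fast`,
#'   `a_slow`, and `fitted` values.
#' @export
fit_ppr_curve <- function(isi, ppr) {
  stopifnot(length(isi) == length(ppr), length(isi) >= 4)
  depth <- max(1 - min(ppr), 0.05)
  fit <- minpack.lm::nlsLM(
    ppr ~ 1 - af * exp(-isi / tf) - as_ * exp(-isi / ts),
    start = list(af = 0.6 * depth, as_ = 0.4 * depth,
                 tf = max(min(isi), 5), ts = max(isi) / 3),
    lower = c(0, 0, 1e-2, 1e-2),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  tf <- unname(cf["tf"]); ts <- unname(cf["ts"])
  af <- unname(cf["af"]); as_ <- unname(cf["as_"])
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp
                 tmp <- af; af <- as_; as_ <- tmp }
  list(tau_fast = tf, tau_slow = ts, a_fast = af, a_slow = as_,
       fitted = unname(stats::fitted(fit)))
}

#' Coefficient of variation of evoked amplitudes
#'
#' Sample SD (n - 1 denominator) over mean; inversely related to release
#' probability across trials.
#'
#' @param amplitudes At least 3 amplitudes with positive mean.
#' @return CV (unitless).
#' @export
cv_of_amplitudes <- function(amplitudes) {
  if (length(amplitudes) < 3) stop("need >= 3 amplitudes")
  m <- mean(amplitudes)
  if (!(m > 0)) stop("CV undefined: mean must be > 0")
  stats::sd(amplitudes) / m
}

#' Quantal content with driving-force scaling
#'
#' The mean mEPSC amplitude is scaled from the mini holding potential to the
#' evoked holding potential assuming ohmic AMPAR conduction with reversal at
#' `e_rev` (scaling factor `(v_evoked - e_rev)/(v_mini - e_rev)`), giving the
#' quantal size q at the evoked potential; quantal content m is the mean
#' evoked EPSC divided by q.
#'
#' @param mean_epsc Mean evoked EPSC amplitude in pA (magnitude) at
#'   `v_evoked`.
#' @param mean_mepsc Mean mEPSC amplitude in pA (magnitude) at `v_mini`.
#' @param v_evoked,v_mini Holding potentials in mV (defaults -80 and -100,
#'   junction-corrected).
#' @param e_rev AMPAR current reversal potential in mV (default 0).
#' @return List with `m` (quantal content), `q` (quantal size in pA at
#'   `v_evoked`) and `scaling_factor`.
#' @export
quantal_content <- function(mean_epsc, mean_mepsc, v_evoked = -80,
                            v_mini = -100, e_rev = 0) {
  if (v_mini == e_rev || v_evoked == e_rev)
    stop("zero driving force: holding potential equals reversal potential")
  scaling_factor <- (v_evoked - e_rev) / (v_mini - e_rev)
  q <- mean_mepsc * scaling_factor
  if (!(q > 0)) stop("quantal size must be > 0")
  list(m = mean_epsc / q, q = q, scaling_factor = scaling_factor)
}

#' Train depression, cumulative-EPSC pool and release-probability analysis
#'
#' From per-pulse EPSC amplitudes of a high-frequency train: normalized
#' amplitudes; the depression time constant from a monoexponential-to-plateau
#' fit of normalized amplitude versus time; the steady state as the mean of
#' the last `last_k` normalized amplitudes; the cumulative amplitude profile
#' with a straight-line fit to its last `n_fit` points versus time, whose
#' slope is the steady-state recruitment rate (pA/ms) and whose
#' back-extrapolated intercept at t = 0 estimates the readily releasable
#' pool in pA; dividing by the quantal size gives the pool in quanta, and
#' the first amplitude divided by the intercept gives the apparent release
#' probability.
#'
#' @param amplitudes Per-pulse amplitudes in pA (magnitudes), >= `n_fit`.
#' @param isi Inter-stimulus interval in ms.
#' @param quantal_size Quantal size q in pA at the evoked potential.
#' @param last_k Pulses averaged for the steady state (default 5).
#' @param n_fit Cumulative points in the linear fit (default 10).
#'
#' @return An object of class `train_analysis`: `norm_amplitudes`,
#'   `depression_tau` (ms, NA when no depression is fittable),
#'   `steady_state`, `cumulative` (pA), `recruitment_slope` (pA/ms),
#'   `rrp_pa`, `rrp_quanta`, `apparent_pr`, `flags`.
#' @export
analyze_train <- function(amplitudes, isi, quantal_size, last_k = 5,
                          n_fit = 10) {
  n <- length(amplitudes)
  if (n < n_fit) stop("need at least ", n_fit, " amplitudes for the linear fit")
  stopifnot(quantal_size > 0, isi > 0, amplitudes[1] > 0)
  norm <- amplitudes / amplitudes[1]
  t <- (seq_len(n) - 1) * isi
  steady_state <- mean(norm[(n - last_k + 1):n])
  flags <- character(0)
  dep_fit <- tryCatch(
    minpack.lm::nlsLM(norm ~ ss + (1 - ss) * exp(-t / tau),
                      start = list(ss = steady_state, tau = 2 * isi),
                      lower = c(0, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  depression_tau <- if (!is.null(dep_fit) && stats::sd(norm) > 1e-12)
    unname(stats::coef(dep_fit)["tau"]) else NA_real_
  if (is.na(depression_tau)) flags <- c(flags, "no_depression_fit")
  cumulative <- cumsum(amplitudes)
  # cumulative-fit abscissa: stimulus k at k*isi, so that a train without
  # depletion (constant amplitudes) back-extrapolates to a zero intercept
  tc <- seq_len(n) * isi
  idx <- (n - n_fit + 1):n
  lf <- stats::lm(cumulative[idx] ~ tc[idx])
  intercept <- unname(stats::coef(lf)[1])
  slope <- unname(stats::coef(lf)[2])
  if (intercept > 1e-8 * cumulative[n]) {
    rrp_quanta <- intercept / quantal_size
    apparent_pr <- amplitudes[1] / intercept
  } else {
    rrp_quanta <- NA_real_
    apparent_pr <- NA_real_
    flags <- c(flags, "nonpositive_intercept")
  }
  structure(list(norm_amplitudes = norm, depression_tau = depression_tau,
                 steady_state = steady_state, cumulative = cumulative,
                 recruitment_slope = slope, rrp_pa = intercept,
                 rrp_quanta = rrp_quanta, apparent_pr = apparent_pr,
                 flags = flags),
            class = "train_analysis")
}

#' Phasic charge transfer during a train
#'
#' Cumulative area between each EPSC and its own local baseline current,
#' measured immediately after the stimulation artifact of that pulse; the
#' per-pulse integration runs to the next stimulus (the last pulse uses the
#' preceding inter-stimulus interval). Referencing each pulse to its local
#' baseline isolates the phasic EPSC component from slow baseline build-up.
#'
#' @param rec A [recording] of the train.
#' @param stim_times Stimulus onsets in ms (default `rec$stim_times`).
#' @param art_delay Dead time after each stimulus in ms (default 0.2).
#' @param baseline_win Local-baseline window length in ms (default 0.4).
#' @param smooth_n Binomial smoothing order (default 50).
#' @return Total phasic charge in pC.
#' @export
phasic_train_charge <- function(rec, stim_times = rec$stim_times,
                                art_delay = 0.2, baseline_win = 0.4,
                                smooth_n = 50) {
  stopifnot(inherits(rec, "recording"), length(stim_times) >= 1)
  xs <- binomial_smooth(rec$samples, smooth_n)
  rate <- rec$rate
  n <- length(stim_times)
  ends <- c(stim_times[-1], stim_times[n] +
              if (n > 1) diff(stim_times)[n - 1] else 20)
  total <- 0
  for (k in seq_len(n)) {
    b0 <- stim_times[k] + art_delay
    if ((b0 + baseline_win) * rate > length(xs))
      stop("missing baseline window for pulse ", k)
    bl <- window_mean(xs, rate, b0, b0 + baseline_win)
    i0 <- floor(b0 * rate) + 1L
    i1 <- min(length(xs), ceiling(min(ends[k], rec$duration) * rate))
    total <- total + sum(bl - xs[i0:i1]) / rate
  }
  total / 1000
}

#' Recovery from short-term depression
#'
#' Fits the biexponential recovery
#' `R(t) = 1 - a_f * exp(-t/tau_f) - a_s * exp(-t/tau_s)` to normalized EPSC
#' amplitudes measured at the recovery stimulus times after a depressing
#' train (normalized to the first EPSC of the train). A recording is flagged
#' as included only if recovery reached at least 85% of the initial EPSC
#' amplitude within the probed interval.
#'
#' @param times Recovery stimulus times in ms after the last train pulse
#'   (cumulative).
#' @param norm_recovery Normalized amplitudes at those times.
#' @return An object of class `recovery_fit`: `tau_fast`, `tau_slow` (ms,
#'   `tau_fast <= tau_slow`), `frac_fast` = a_f/(a_f + a_s), `included`,
#'   `fit_ok`. On fit failure or a degenerate (already fully recovered)
#'   input, `fit_ok` is FALSE and the parameters are NA.
#' @export
analyze_recovery <- function(times, norm_recovery) {
  stopifnot(length(times) == length(norm_recovery), length(times) >= 4)
  included <- max(norm_recovery) >= 0.85
  depth <- 1 - min(norm_recovery)
  fit <- if (depth > 1e-6) tryCatch(
    minpack.lm::nlsLM(
      norm_recovery ~ 1 - af * exp(-times / tf) - as_ * exp(-times / ts),
      start = list(af = 0.5 * depth, as_ = 0.5 * depth,
                   tf = max(min(times), 20), ts = max(times) / 2),
      lower = c(0, 0, 1, 1),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL) else NULL
  if (is.null(fit)) {
    return(structure(list(tau_fast = NA_real_, tau_slow = NA_real_,
                          frac_fast = NA_real_, included = included,
                          fit_ok = FALSE), class = "recovery_fit"))
  }
  cf <- stats::coef(fit)
  tf <- unname(cf["tf"]); ts <- unname(cf["ts"])
  af <- unname(cf["af"]); as_ <- unname(cf["as_"])
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp
                 tmp <- af; af <- as_; as_ <- tmp }
  frac_fast <- if (af + as_ > 0) af / (af + as_) else NA_real_
  structure(list(tau_fast = tf, tau_slow = ts, frac_fast = frac_fast,
                 included = included, fit_ok = TRUE),
            class = "recovery_fit")
}

#' Input-output slope by linear regression
#'
#' Ordinary least-squares slope of mean EPSC amplitude against stimulation
#' voltage.
#'
#' @param voltage Stimulation intensities (V or mV), >= 3 distinct values.
#' @param amplitude Mean EPSC amplitudes (pA).
#' @return Slope in pA per voltage unit.
#' @export
io_slope <- function(voltage, amplitude) {
  stopifnot(length(voltage) == length(amplitude))
  if (length(voltage) < 3) stop("need >= 3 intensity steps")
  if (stats::sd(voltage) == 0) stop("constant stimulation intensity")
  unname(stats::coef(stats::lm(amplitude ~ voltage))[2])
}

#' Percent change between two group means
#'
#' @param a Reference mean.
#' @param b Comparison mean.
#' @return `100 * (b - a) / a`.
#' @export
percent_change <- function(a, b) 100 * (b - a) / a
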