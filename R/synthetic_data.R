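#' EPSC kinetic template parameters
#'
#' Kinetics of a stereotypical AMPAR-mediated EPSC: exponential rise and
#' biexponential decay. Defaults emulate fast cerebellar mossy-fibre to
#' granule-cell EPSCs (fast decay ~1.25 ms, slow decay ~12.87 ms, 10-90%
#' rise time ~0.33 ms).
#'
#' @param rise_tau Rise time constant in ms (< `decay_tau_fast`).
#' @param decay_tau_fast Fast decay time constant in ms.
#' @param decay_tau_slow Slow decay time constant in ms.
#' @param frac_fast Fraction of the fast decay component, in `[0, 1]`.
#' @param peak Peak amplitude magnitude in pA.
#'
#' @return An object of class `epsc_kinetics`.
#' @export
epsc_kinetics <- function(rise_tau = 0.37, decay_tau_fast = 1.25,
                          decay_tau_slow = 12.87, frac_fast = 0.85,
                          peak = 91.1) {
  stopifnot(rise_tau > 0, decay_tau_fast > 0, decay_tau_slow > 0,
            frac_fast >= 0, frac_fast <= 1, peak > 0)
  if (!(rise_tau < decay_tau_fast))
    stop("rise_tau must be smaller than decay_tau_fast")
  structure(list(rise_tau = rise_tau, decay_tau_fast = decay_tau_fast,
                 decay_tau_slow = decay_tau_slow, frac_fast = frac_fast,
                 peak = peak),
            class = "epsc_kinetics")
}

# unscaled template shape at times t (ms)
epsc_shape <- function(kin, t) {
  (1 - exp(-t / kin$rise_tau)) *
    (kin$frac_fast * exp(-t / kin$decay_tau_fast) +
       (1 - kin$frac_fast) * exp(-t / kin$decay_tau_slow))
}

#' EPSC waveform template
#'
#' Samples the product-of-exponentials EPSC shape
#' \deqn{(1 - e^{-t/\tau_{rise}})(f e^{-t/\tau_{fast}} + (1-f) e^{-t/\tau_{slow}})}
#' on the given time base and rescales it so that the single negative-going
#' peak has magnitude `kin$peak`.
#'
#' @param kin An [epsc_kinetics] object.
#' @param rate Sampling rate in kHz. The rise must be resolved:
#'   `rise_tau * rate >= 3` or a resolution error is raised.
#' @param length_ms Template duration in ms; must cover at least
#'   `5 * decay_tau_slow`.
#'
#' @return Numeric vector of current samples in pA (negative-going; the first
#'   sample is at t = 0, value 0).
#' @export
epsc_template <- function(kin, rate, length_ms) {
  stopifnot(inherits(kin, "epsc_kinetics"), rate > 0, length_ms > 0)
  if (kin$rise_tau * rate < 3)
    stop("resolution error: sampling rate too low to resolve the EPSC rise (",
         "rise_tau * rate = ", kin$rise_tau * rate, " < 3)")
  if (length_ms < 5 * kin$decay_tau_slow)
    stop("template length must cover >= 5 * decay_tau_slow")
  t <- seq(0, length_ms, by = 1 / rate)
  w <- epsc_shape(kin, t)
  -w / max(w) * kin$peak
}

#' Multiplicative amplitude / additive baseline noise model
#'
#' @param amplitude_cv Coefficient of variation of the multiplicative
#'   Gaussian noise on evoked amplitudes (truncated at 0 by redrawing;
#'   biological trial-to-trial variability of evoked EPSCs has CV ~0.2).
#' @param baseline_sd Additive Gaussian baseline noise SD in pA.
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(amplitude_cv = 0.1, baseline_sd = 2, seed = 1L) {
  stopifnot(amplitude_cv >= 0, baseline_sd >= 0)
  structure(list(amplitude_cv = amplitude_cv, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# positive multiplicative noise factors: Gaussian(1, cv) with redraw at <= 0
mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  x <- stats::rnorm(n, 1, cv)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), 1, cv)
  x
}

#' Simulate evoked train-plus-recovery recordings
#'
#' Generates one sweep per protocol repetition. Per-pulse true amplitudes are
#' the Tsodyks-Markram model predictions scaled by `amp_scale` and by
#' independent multiplicative Gaussian noise; EPSC templates superimpose
#' linearly on the decaying tails of preceding responses; additive Gaussian
#' baseline noise is applied on top. The ground-truth per-pulse amplitudes
#' are returned alongside the recordings so measurement routines can be
#' validated against them.
#'
#' @param params [tm_params] generating ground truth.
#' @param protocol [stim_protocol].
#' @param kin [epsc_kinetics] (its `peak` field is ignored; see `amp_scale`).
#' @param noise [noise_model].
#' @param rate Sampling rate in kHz (default 200).
#' @param amp_scale Scale converting model amplitude to pA for the first
#'   pulse (default 100 pA per unit model amplitude).
#' @param pre_ms Baseline time before the first stimulus in ms (default 10).
#' @param post_ms Time after the last stimulus in ms (default 30).
#' @param v_hold Holding potential in mV (default -80, junction-corrected).
#' @param onset_latency Synaptic delay between stimulus onset and EPSC onset
#'   in ms (default 0.8, emulating the mono-synaptic latency that leaves the
#'   post-artifact local-baseline window free of the rising EPSC).
#' @param artifact_amp Amplitude in pA of an optional rectangular stimulation
#'   artifact of 0.15 ms at each stimulus (default 0 = disabled; the
#'   measurement routines blank artifacts anyway).
#'
#' @return List with `recordings` (list of [recording], one per repetition)
#'   and `truth` (data.frame `repetition`, `pulse`, `stim_time`,
#'   `true_amplitude` in pA).
#' @export
simulate_evoked_recording <- function(params, protocol, kin = epsc_kinetics(),
                                      noise = noise_model(), rate = 200,
                                      amp_scale = 100, pre_ms = 10,
                                      post_ms = 30, v_hold = -80,
                                      onset_latency = 0.8,
                                      artifact_amp = 0) {
  stopifnot(inherits(params, "tm_params"), inherits(protocol, "stim_protocol"))
  set.seed(noise$seed)
  st <- protocol_stim_times(protocol, t0 = pre_ms)
  base_amp <- tm_amplitudes(params, st)
  base_amp <- base_amp / base_amp[1] * amp_scale
  isi_min <- min(diff(st))
  tpl_len <- 10 * kin$decay_tau_slow
  if (isi_min < 3 * kin$rise_tau)
    warning("pulse interval close to template resolution; EPSCs overlap strongly")
  kin1 <- kin; kin1$peak <- 1
  tpl <- epsc_template(kin1, rate, tpl_len)   # unit-peak, negative
  dur <- max(st) + post_ms
  n <- round(dur * rate)
  recs <- vector("list", protocol$n_repetitions)
  truth <- vector("list", protocol$n_repetitions)
  # all amplitude noise is drawn before any baseline noise, so the ground
  # truth is invariant to the baseline_sd setting at a given seed
  amp_draws <- lapply(seq_len(protocol$n_repetitions), function(r)
    base_amp * mult_noise(length(st), noise$amplitude_cv))
  for (r in seq_len(protocol$n_repetitions)) {
    amps <- amp_draws[[r]]
    x <- numeric(n)
    for (k in seq_along(st)) {
      i0 <- round((st[k] + onset_latency) * rate) + 1
      idx <- i0:min(n, i0 + length(tpl) - 1)
      x[idx] <- x[idx] + tpl[seq_along(idx)] * amps[k]
      if (artifact_amp != 0) {
        ia <- round(st[k] * rate) + 1
        ja <- ia:min(n, ia + round(0.15 * rate))
        x[ja] <- x[ja] + artifact_amp
      }
    }
    if (noise$baseline_sd > 0) x <- x + stats::rnorm(n, 0, noise$baseline_sd)
    recs[[r]] <- recording(x, rate = rate, v_hold = v_hold, stim_times = st,
                           filter_khz = 10,
                           label = sprintf("sim train rep %d", r))
    truth[[r]] <- data.frame(repetition = r, pulse = seq_along(st),
                             stim_time = st, true_amplitude = amps)
  }
  list(recordings = recs, truth = do.call(rbind, truth))
}

#' Simulate a cohort of measured train-amplitude series
#'
#' Amplitude-level counterpart of [simulate_evoked_recording]: for each
#' synthetic cell it evaluates the Tsodyks-Markram prediction for the 100 Hz
#' and 300 Hz train-plus-recovery protocols, applies independent
#' multiplicative amplitude noise per repetition, averages across the
#' repetitions (stimulus-locked averaging, as for real sweeps) and
#' normalizes to the first pulse. This is the input representation the
#' plasticity-model fit consumes; the waveform-rendering and measurement
#' path is validated separately.
#'
#' @param params [tm_params] shared ground truth of the cohort.
#' @param n_cells Number of synthetic cells.
#' @param amplitude_cv Multiplicative noise CV per pulse and repetition.
#' @param n_repetitions Repetitions averaged per cell (default 5).
#' @param freqs Train frequencies in Hz (default c(100, 300)).
#' @param protocol_template [stim_protocol] whose frequency is swapped.
#' @param seed Integer seed.
#'
#' @return List of length `n_cells`; each element is a list of per-frequency
#'   series, each with `stim_times` (ms) and `norm_amplitudes`
#'   (first pulse = 1).
#' @export
simulate_train_cohort <- function(params, n_cells = 20, amplitude_cv = 0.1,
                                  n_repetitions = 5, freqs = c(100, 300),
                                  protocol_template = stim_protocol(),
                                  seed = 1L) {
  set.seed(seed)
  protos <- lapply(freqs, function(f) {
    p <- protocol_template; p$train_freq <- f; p
  })
  sts <- lapply(protos, protocol_stim_times)
  base <- lapply(sts, function(st) {
    a <- tm_amplitudes(params, st); a / a[1]
  })
  lapply(seq_len(n_cells), function(cell) {
    series <- lapply(seq_along(freqs), function(j) {
      a <- base[[j]]
      reps <- vapply(seq_len(n_repetitions),
                     function(r) a * mult_noise(length(a), amplitude_cv),
                     numeric(length(a)))
      m <- rowMeans(reps)
      list(freq = freqs[j], stim_times = sts[[j]],
           norm_amplitudes = m / m[1])
    })
    names(series) <- paste0("f", freqs)
    series
  })
}

#' Postsynaptic channel model for miniature events
#'
#' @param n_channels Number of channels open at the event peak.
#' @param i_unitary Single-channel current magnitude in pA.
#' @param baseline_sd Additive baseline noise SD in pA.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(n_channels = 10, i_unitary = 1.41,
                          baseline_sd = 2) {
  stopifnot(n_channels >= 1, i_unitary > 0, baseline_sd >= 0)
  structure(list(n_channels = as.integer(n_channels), i_unitary = i_unitary,
                 baseline_sd = baseline_sd),
            class = "channel_model")
}

#' Simulate aligned miniature-EPSC event waveforms
#'
#' Each event starts with all `n_channels` channels open at the peak; each
#' channel then closes stochastically and independently, with survival
#' probability at decay time t equal to the normalized template decay d(t),
#' so the ensemble-mean decay follows the kinetics while the across-event
#' variance has the binomial structure
#' \eqn{\sigma^2 = i\,\bar I - \bar I^2/N} that peak-scaled fluctuation
#' analysis assumes. A deterministic template rise precedes the peak.
#'
#' @param ch [channel_model].
#' @param kin [epsc_kinetics]; only the kinetic fields are used, the peak is
#'   `n_channels * i_unitary`.
#' @param n_events Number of events.
#' @param rate Sampling rate in kHz (default 50).
#' @param decay_ms Length of simulated decay in ms (default
#'   `6 * decay_tau_slow`).
#' @param seed Integer seed.
#'
#' @return List with `waveforms` (matrix, events x samples, negative-going),
#'   `peak_index` (column of the peak), `t` (time base, ms relative to event
#'   onset).
#' @export
simulate_mini_events <- function(ch, kin, n_events, rate = 50,
                                 decay_ms = 6 * kin$decay_tau_slow,
                                 seed = 1L) {
  stopifnot(inherits(ch, "channel_model"), inherits(kin, "epsc_kinetics"))
  set.seed(seed)
  # deterministic rise portion up to the argmax of the shape
  t_dense <- seq(0, 5 * kin$rise_tau + 2, by = 1 / rate)
  shp <- epsc_shape(kin, t_dense)
  ipk <- which.max(shp)
  rise <- shp[1:ipk] / shp[ipk]                   # 0..1, ends at 1
  td <- seq(0, decay_ms, by = 1 / rate)           # decay time from peak
  d <- kin$frac_fast * exp(-td / kin$decay_tau_fast) +
    (1 - kin$frac_fast) * exp(-td / kin$decay_tau_slow)
  d <- d / d[1]                                   # survival prob per sample
  ns <- ipk + length(td) - 1
  W <- matrix(0, n_events, ns)
  for (e in seq_len(n_events)) {
    u <- stats::runif(ch$n_channels)
    # channel j open at decay sample k iff u_j <= d_k (monotone trajectories)
    open_count <- vapply(d, function(dk) sum(u <= dk), numeric(1))
    ev <- c(rise[-ipk] * ch$n_channels, open_count) * ch$i_unitary
    W[e, ] <- -ev
  }
  if (ch$baseline_sd > 0)
    W <- W + matrix(stats::rnorm(length(W), 0, ch$baseline_sd), nrow(W))
  list(waveforms = W, peak_index = ipk,
       t = (seq_len(ns) - 1) / rate)
}

#' Simulate a continuous miniature-EPSC recording
#'
#' Poisson event times at `rate_hz` over `duration_ms`; each event waveform
#' is drawn from the binomial channel model of [simulate_mini_events] and
#' added to a Gaussian baseline-noise trace.
#'
#' @param ch [channel_model].
#' @param kin [epsc_kinetics].
#' @param rate_hz Mean event frequency in Hz.
#' @param duration_ms Recording duration in ms.
#' @param rate Sampling rate in kHz (default 50).
#' @param v_hold Holding potential in mV (default -100).
#' @param seed Integer seed.
#'
#' @return List with `recording` (a [recording]) and `event_times` (ms, the
#'   ground-truth event onsets).
#' @export
simulate_mini_recording <- function(ch, kin, rate_hz, duration_ms,
                                    rate = 50, v_hold = -100, seed = 1L) {
  stopifnot(duration_ms > 0, rate_hz >= 0)
  set.seed(seed)
  n_ev <- stats::rpois(1, rate_hz * duration_ms / 1000)
  times <- sort(stats::runif(n_ev, 0, duration_ms * 0.98))
  n <- round(duration_ms * rate)
  x <- stats::rnorm(n, 0, ch$baseline_sd)
  if (n_ev > 0) {
    ev <- simulate_mini_events(
      channel_model(ch$n_channels, ch$i_unitary, baseline_sd = 0),
      kin, n_ev, rate = rate, seed = seed + 1L)
    for (e in seq_len(n_ev)) {
      i0 <- round(times[e] * rate) + 1
      idx <- i0:min(n, i0 + ncol(ev$waveforms) - 1)
      x[idx] <- x[idx] + ev$waveforms[e, seq_along(idx)]
    }
  }
  rec <- recording(x, rate = rate, v_hold = v_hold, filter_khz = 2.7,
                   label = "sim minis")
  list(recording = rec, event_times = times)
}
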