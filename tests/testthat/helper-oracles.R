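# Independent oracles used across the suite. Each one recomputes a quantity
# by a different route than the implementation under test.

# Dense ODE integration of the plasticity dynamics between stimuli (lsoda),
# with the same event rule at each stimulus. Independent of the event-driven
# closed-form recursion in the package.
tm_ode_oracle <- function(params, stim_times, rtol = 1e-10) {
  u <- 0; R <- 1
  amps <- numeric(length(stim_times))
  deriv <- function(t, y, parms)
    list(c(-y[1] / params$tau_facil, (1 - y[2]) / params$tau_rec))
  for (k in seq_along(stim_times)) {
    if (k > 1) {
      dt <- stim_times[k] - stim_times[k - 1]
      out <- deSolve::ode(c(u, R), c(0, dt), deriv, NULL,
                          method = "lsoda", rtol = rtol, atol = 1e-12)
      u <- out[2, 2]; R <- out[2, 3]
    }
    u <- u + params$U_SE * (1 - u)
    amps[k] <- params$A_SE * u * R
    R <- R * (1 - u)
  }
  amps
}

# Analytic steady state of the event recursion at fixed inter-stimulus
# interval, from the closed-form fixed point of the two linear maps.
tm_steady_state_oracle <- function(params, isi) {
  ef <- exp(-isi / params$tau_facil)
  er <- exp(-isi / params$tau_rec)
  U <- params$U_SE
  u_ss <- U / (1 - ef * (1 - U))              # u after the spike increment
  # R_pre fixed point: R = 1 - (1 - R*(1-u_ss)) * er
  R_ss <- (1 - er) / (1 - er * (1 - u_ss))
  params$A_SE * u_ss * R_ss
}

# Dense-grid trapezoid quadrature of the EPSC template shape.
template_charge_oracle <- function(kin, length_ms, dt = 1e-4) {
  t <- seq(0, length_ms, by = dt)
  w <- (1 - exp(-t / kin$rise_tau)) *
    (kin$frac_fast * exp(-t / kin$decay_tau_fast) +
       (1 - kin$frac_fast) * exp(-t / kin$decay_tau_slow))
  scale <- kin$peak / max(w)
  sum((w[-1] + w[-length(w)]) / 2) * dt * scale    # pA*ms
}

# 4-D grid search over the fit bounds (on the same log scaling the EA uses),
# as an independent check that the EA is not stuck far from the optimum.
tm_grid_oracle <- function(observed, bounds = default_tm_bounds(),
                           n_axis = 25) {
  gr <- list(seq(bounds[1, 1], bounds[1, 2], length.out = n_axis),
             10^seq(log10(bounds[2, 1]), log10(bounds[2, 2]),
                    length.out = n_axis),
             10^seq(log10(bounds[3, 1]), log10(bounds[3, 2]),
                    length.out = n_axis),
             10^seq(log10(bounds[4, 1]), log10(bounds[4, 2]),
                    length.out = n_axis))
  pop <- as.matrix(expand.grid(gr))
  loss <- synephys:::tm_loss_batch(pop, observed)
  i <- which.min(loss)
  list(par = pop[i, ], loss = loss[i])
}

# Event-level depletion-model oracle: Binomial release from a finite pool
# with constant replenishment, averaged over trials; the cumulative released
# quanta are back-extrapolated with the same linear rule the estimator
# defines, but computed directly on quantal counts.
depletion_oracle <- function(n0, p, repl_per_ms, isi, n_pulses = 20,
                             n_trials = 5000, seed = 1) {
  set.seed(seed)
  cum <- matrix(0, n_trials, n_pulses)
  for (tr in seq_len(n_trials)) {
    pool <- n0; rel <- numeric(n_pulses)
    for (k in seq_len(n_pulses)) {
      r <- stats::rbinom(1, round(pool), p)
      rel[k] <- r
      pool <- pool - r + repl_per_ms * isi
    }
    cum[tr, ] <- cumsum(rel)
  }
  cm <- colMeans(cum)
  t <- seq_len(n_pulses) * isi
  idx <- (n_pulses - 9):n_pulses
  cf <- stats::coef(stats::lm(cm[idx] ~ t[idx]))
  list(rrp = unname(cf[1]), slope = unname(cf[2]), cum_mean = cm)
}

# Closed-form phasic-charge oracle by template decomposition: the trace is a
# sum of unit-peak templates with known onsets and amplitudes, so each
# pulse's local baseline and windowed integral are computed analytically
# from exponential integrals (no sampling, no smoothing).
phasic_charge_oracle <- function(st_onset, amps, kin, windows, bl_windows) {
  # analytic integral of the unnormalized shape over [a, b], a >= 0
  shp_int <- function(a, b) {
    f <- kin$frac_fast
    ii <- function(tau) tau * (exp(-a / tau) - exp(-b / tau))
    tf <- kin$decay_tau_fast; ts <- kin$decay_tau_slow; tr <- kin$rise_tau
    f * ii(tf) + (1 - f) * ii(ts) -
      f * ii(1 / (1 / tf + 1 / tr)) - (1 - f) * ii(1 / (1 / ts + 1 / tr))
  }
  tg <- seq(0, 10 * kin$decay_tau_slow, by = 1e-3)
  smax <- max(epsc_shape(kin, tg))
  total <- 0
  for (k in seq_along(st_onset)) {
    a <- windows[k, 1]; b <- windows[k, 2]
    ba <- bl_windows[k, 1]; bb <- bl_windows[k, 2]
    # magnitude of the summed templates, integrated over the window and
    # averaged over the baseline window
    int_k <- 0; bl_k <- 0
    for (j in seq_along(st_onset)) {
      if (st_onset[j] <= b) {
        aj <- max(a - st_onset[j], 0); bj <- b - st_onset[j]
        if (bj > 0) int_k <- int_k + amps[j] * shp_int(aj, bj) / smax
      }
      if (st_onset[j] <= bb) {
        aj <- max(ba - st_onset[j], 0); bj <- bb - st_onset[j]
        if (bj > 0) bl_k <- bl_k + amps[j] * shp_int(aj, bj) / smax / (bb - ba)
      }
    }
    total <- total + int_k - bl_k * (b - a)
  }
  unname(total) / 1000    # pA*ms -> pC
}

# Expected-value depletion recursion (deterministic mean amplitudes in pA)
depletion_mean_amps <- function(n0, p, repl_per_ms, isi, q, n_pulses = 20) {
  pool <- n0; amps <- numeric(n_pulses)
  for (k in seq_len(n_pulses)) {
    amps[k] <- p * pool * q
    pool <- pool * (1 - p) + repl_per_ms * isi
  }
  amps
}
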