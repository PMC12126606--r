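test_that("template integral matches closed form and quadrature oracle", {
  # near-zero rise, single decay: charge -> peak * tau_fast (pA*ms)
  kin <- epsc_kinetics(rise_tau = 0.002, decay_tau_fast = 5,
                       decay_tau_slow = 5.001, frac_fast = 1, peak = 100)
  tpl <- epsc_template(kin, rate = 2000, length_ms = 60)
  q_num <- -sum(tpl) / 2000
  expect_equal(q_num, 100 * 5, tolerance = 0.005)
  # dense-grid quadrature oracle on the control kinetics to 0.1%
  kin2 <- epsc_kinetics()
  tpl2 <- epsc_template(kin2, rate = 200, length_ms = 80)
  q2 <- -sum(tpl2) / 200
  expect_equal(q2, template_charge_oracle(kin2, 80), tolerance = 1e-3)
})

test_that("control kinetics give the expected 10-90% rise time", {
  tpl <- epsc_template(epsc_kinetics(), rate = 200, length_ms = 80)
  fd <- fit_epsc_decay(tpl, rate = 200)
  expect_equal(fd$rise_10_90, 0.333, tolerance = 0.15)
})

test_that("template peak, sign and resolution guard are enforced", {
  kin <- epsc_kinetics(peak = 91.1)
  tpl <- epsc_template(kin, rate = 200, length_ms = 80)
  expect_equal(min(tpl), -91.1)
  expect_error(epsc_template(kin, rate = 5, length_ms = 80), "resolution")
  expect_error(epsc_template(kin, rate = 200, length_ms = 10), "5 \\* decay")
})

test_that("noiseless evoked simulation is measured back within windowing tolerance", {
  # fast mono-exponential kinetics so inter-pulse overlap is negligible and
  # the check isolates the windowing conventions
  kinf <- epsc_kinetics(rise_tau = 0.37, decay_tau_fast = 1.25,
                        decay_tau_slow = 1.2501, frac_fast = 1, peak = 1)
  sim <- simulate_evoked_recording(
    control_tm(), stim_protocol(train_freq = 100, n_repetitions = 1),
    kin = kinf, noise = noise_model(0, 0, seed = 1), rate = 100)
  rec <- sim$recordings[[1]]
  amps <- vapply(seq_along(rec$stim_times), function(k)
    measure_epsc(rec, rec$stim_times[k], in_train = (k > 1),
                 smooth_n = 20)$amplitude, numeric(1))
  err <- abs(amps - sim$truth$true_amplitude) / sim$truth$true_amplitude
  expect_lt(max(err), 0.02)
})

test_that("recovery pulses fall at the cumulative recovery intervals", {
  st <- protocol_stim_times(stim_protocol(train_freq = 300))
  last_train <- st[20]
  expect_equal(st[21:26] - last_train, cumsum(c(25, 50, 100, 300, 1000, 3000)))
})

test_that("configured amplitude CV is realized across repetitions", {
  p <- control_tm()
  pr <- stim_protocol(train_freq = 100, n_repetitions = 200)
  sim <- simulate_evoked_recording(p, pr, kin = epsc_kinetics(peak = 1),
                                   noise = noise_model(0.1, 0, seed = 4),
                                   rate = 20)
  a1 <- sim$truth$true_amplitude[sim$truth$pulse == 1]
  expect_lt(abs(sd(a1) / mean(a1) - 0.10), 0.02)
})

test_that("simulation is seed-reproducible and truth ignores baseline noise", {
  p <- control_tm(); pr <- stim_protocol(train_freq = 300, n_repetitions = 2)
  s1 <- simulate_evoked_recording(p, pr, noise = noise_model(0.1, 2, seed = 8),
                                  rate = 20)
  s2 <- simulate_evoked_recording(p, pr, noise = noise_model(0.1, 2, seed = 8),
                                  rate = 20)
  expect_identical(s1$recordings[[2]]$samples, s2$recordings[[2]]$samples)
  s3 <- simulate_evoked_recording(p, pr, noise = noise_model(0.1, 0, seed = 8),
                                  rate = 20)
  expect_identical(s1$truth$true_amplitude, s3$truth$true_amplitude)
})

test_that("mini event counts follow the Poisson law and rate 0 is silent", {
  s0 <- simulate_mini_recording(channel_model(), mini_kin(), rate_hz = 0,
                                duration_ms = 5000, rate = 5, seed = 1)
  expect_length(s0$event_times, 0)
  counts <- vapply(1:100, function(s)
    length(simulate_mini_recording(channel_model(), mini_kin(),
                                   rate_hz = 0.25, duration_ms = 120000,
                                   rate = 1, seed = s)$event_times),
    numeric(1))
  expect_equal(mean(counts), 30, tolerance = 1 / 30)
})

test_that("ensemble mini statistics match the channel model", {
  ch <- channel_model(n_channels = 10, i_unitary = 1.41, baseline_sd = 2)
  ev <- simulate_mini_events(ch, mini_kin(), n_events = 500, rate = 50,
                             seed = 13)
  peaks <- -ev$waveforms[, ev$peak_index]
  expect_equal(mean(peaks), 10 * 1.41, tolerance = 0.02)
  # binomial variance law along the decay: sigma^2 = i*I - I^2/N (noise-free
  # channels so the law is exact up to Monte-Carlo error)
  ch0 <- channel_model(10, 1.41, baseline_sd = 0)
  ev0 <- simulate_mini_events(ch0, mini_kin(), n_events = 2000, rate = 50,
                              seed = 14)
  W <- -ev0$waveforms
  dec <- ev0$peak_index:ncol(W)
  mI <- colMeans(W)[dec]
  vI <- apply(W[, dec], 2, var)
  pred <- 1.41 * mI - mI^2 / 10
  use <- mI > 0.05 * max(mI)
  # z-scores against the binomial sampling error of a variance estimate
  z <- (vI[use] - pred[use]) /
    (pred[use] * sqrt(2 / (nrow(W) - 1)) + 1e-12)
  expect_lt(mean(abs(z) > 3), 0.02)
  expect_lt(abs(mean(z)), 0.5)
})
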