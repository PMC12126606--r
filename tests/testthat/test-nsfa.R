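test_that("mini summary statistics: empty, frequency arithmetic, generator truth", {
  empty <- data.frame(event_time = numeric(0), amplitude = numeric(0),
                      charge = numeric(0), rise_10_90 = numeric(0),
                      decay_tau = numeric(0))
  ms <- mini_stats(empty, duration_ms = 1000)
  expect_equal(ms$frequency, 0)
  expect_identical(ms$n_events, 0L)
  ev <- data.frame(event_time = seq(1, 30) * 1000, amplitude = 14,
                   charge = 0.014, rise_10_90 = 0.25, decay_tau = 0.86)
  expect_equal(mini_stats(ev, 120000)$frequency, 0.25)
  # synthetic events: mean detected amplitude near N * i
  ch <- channel_model(10, 1.41, baseline_sd = 2)
  sim <- simulate_mini_events(ch, mini_kin(), 300, rate = 50, seed = 6)
  peaks <- -sim$waveforms[, sim$peak_index]
  expect_equal(mean(peaks), 14.1, tolerance = 0.05)
})

test_that("NSFA refuses 50 events and flags degenerate identical events", {
  ch <- channel_model(10, 1.41, baseline_sd = 0)
  ev <- simulate_mini_events(ch, mini_kin(), 50, rate = 50, seed = 1)
  expect_error(peak_scaled_nsfa(ev$waveforms, ev$peak_index, 50, -100),
               "more than 50")
  # identical noiseless deterministic events: zero residual variance
  tpl <- epsc_template(epsc_kinetics(rise_tau = 0.15, decay_tau_fast = 0.86,
                                     decay_tau_slow = 3, frac_fast = 0.95,
                                     peak = 14), 50, 30)
  W <- matrix(rep(tpl, 60), nrow = 60, byrow = TRUE)
  r <- peak_scaled_nsfa(W, which.min(tpl), 50, -100)
  expect_true("degenerate_zero_variance" %in% r$flags)
  expect_true(is.na(r$i_unitary))
})

test_that("binomial-channel simulation recovers i, g and N", {
  ch <- channel_model(n_channels = 10, i_unitary = 1.41, baseline_sd = 2)
  ev <- simulate_mini_events(ch, mini_kin(), 500, rate = 50, seed = 3)
  r <- peak_scaled_nsfa(ev$waveforms, ev$peak_index, rate = 50,
                        v_hold = -100, e_rev = 0, bins = 10)
  expect_equal(r$i_unitary, 1.41, tolerance = 0.10)
  expect_equal(r$g_unitary, 14.1, tolerance = 0.10)
  expect_equal(r$n_channels, 10, tolerance = 0.20)
  expect_gt(r$fit_r2, 0.8)
  expect_identical(r$n_events_used, 500L)
})

test_that("NSFA is invariant to a global sign flip", {
  ch <- channel_model(10, 1.41, baseline_sd = 1)
  ev <- simulate_mini_events(ch, mini_kin(), 200, rate = 50, seed = 4)
  r1 <- peak_scaled_nsfa(ev$waveforms, ev$peak_index, 50, -100)
  r2 <- peak_scaled_nsfa(-ev$waveforms, ev$peak_index, 50, -100)
  expect_equal(r1$i_unitary, r2$i_unitary)
  expect_equal(r1$n_channels, r2$n_channels)
})

test_that("fitted parabola vertex matches its closed form", {
  ch <- channel_model(12, 1.2, baseline_sd = 1)
  ev <- simulate_mini_events(ch, mini_kin(), 400, rate = 50, seed = 5)
  r <- peak_scaled_nsfa(ev$waveforms, ev$peak_index, 50, -100)
  # vertex of sigma^2 = i*I - I^2/N + b is at I = i*N/2, height i^2*N/4 + b
  i <- r$i_unitary; N <- r$n_channels; b <- r$baseline_var
  vx <- i * N / 2
  vy <- i * vx - vx^2 / N + b
  expect_equal(vy, i^2 * N / 4 + b, tolerance = 1e-10)
})

test_that("threshold detector finds simulated events at plausible rates", {
  sim <- simulate_mini_recording(channel_model(10, 1.41, baseline_sd = 1.5),
                                 mini_kin(), rate_hz = 1,
                                 duration_ms = 30000, rate = 10, seed = 7)
  det <- detect_mini_events(sim$recording, smooth_n = 8,
                            window_ms = c(1, 6))
  n_true <- length(sim$event_times)
  expect_gt(length(det$times), 0.6 * n_true)
  expect_lt(length(det$times), 1.6 * n_true)
})
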