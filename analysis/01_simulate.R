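#!/usr/bin/env Rscript
# Step 1: generate the synthetic study data.
#
# Two cohorts of train-plus-recovery EPSC amplitude series (a control-like
# and a high-release-probability "sponge-like" condition, 20 cells each,
# paired 100 + 300 Hz protocols, amplitude noise CV 0.1) plus one rendered
# example sweep. The mEPSC event sets for fluctuation analysis are
# regenerated from the same seeds in 03_nsfa.R rather than stored, since the
# raw waveform matrices are large. Steps 02-04 consume these outputs.

suppressPackageStartupMessages(library(synephys))

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

conditions <- list(
  control = tm_params(U_SE = 0.34, A_SE = 1 / 0.34,
                      tau_facil = 10, tau_rec = 97.1),
  sponge  = tm_params(U_SE = 0.45, A_SE = 1 / 0.45,
                      tau_facil = 10, tau_rec = 60.8))

# -- train cohorts (normalized amplitude series per cell) ---------------------
for (cn in names(conditions)) {
  cohort <- simulate_train_cohort(conditions[[cn]], n_cells = 20,
                                  amplitude_cv = 0.1,
                                  seed = seed + match(cn, names(conditions)))
  rows <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    do.call(rbind, lapply(cohort[[i]], function(s)
      data.frame(cell = i, freq = s$freq, pulse = seq_along(s$stim_times),
                 stim_time = round(s$stim_times, 4),
                 norm_amplitude = round(s$norm_amplitudes, 6))))
  }))
  utils::write.csv(rows, file.path(out, paste0("cohort_", cn, ".csv")),
                   row.names = FALSE)
  message(sprintf("%s cohort: 20 cells x {100, 300} Hz written", cn))
}

# -- one rendered example sweep (text recording format, short recovery) -------
proto <- stim_protocol(train_freq = 300, n_repetitions = 1,
                       recovery_intervals = c(25, 50, 100))
sim <- simulate_evoked_recording(
  conditions$control, proto, kin = epsc_kinetics(peak = 1),
  noise = noise_model(0.1, 2, seed = seed), rate = 10, amp_scale = 91.1)
write_recording(sim$recordings[[1]], file.path(out, "example_sweep.csv"))
utils::write.csv(sim$truth, file.path(out, "example_sweep_truth.csv"),
                 row.names = FALSE)
message("example 300 Hz sweep rendered at 10 kHz with ground truth")
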