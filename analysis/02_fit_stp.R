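#!/usr/bin/env Rscript
# Step 2: fit the Tsodyks-Markram short-term plasticity model to every cell
# of both simulated cohorts with the evolutionary optimizer and summarize
# the recovered parameters against the generating ground truth.
#
# Reads results/cohort_{control,sponge}.csv (from 01_simulate.R); writes
# results/tm_fits.csv and results/tm_fit_summary.json.

suppressPackageStartupMessages(library(synephys))

out <- "results"
truth <- list(control = c(U_SE = 0.34, tau_rec = 97.1),
              sponge = c(U_SE = 0.45, tau_rec = 60.8))

all_fits <- list()
summary <- list()
for (cn in names(truth)) {
  tab <- utils::read.csv(file.path(out, paste0("cohort_", cn, ".csv")))
  cohort <- lapply(split(tab, tab$cell), function(ct)
    lapply(split(ct, ct$freq), function(s) {
      s <- s[order(s$pulse), ]
      list(stim_times = s$stim_time,
           norm_amplitudes = s$norm_amplitude / s$norm_amplitude[1])
    }))
  fits <- fit_tm_cohort(cohort, fit_config(offspring_size = 100,
                                           max_generations = 30,
                                           seed = 1000L))
  fits$condition <- cn
  all_fits[[cn]] <- fits
  summary[[cn]] <- list(
    mean_U_SE = mean(fits$U_SE), sd_U_SE = sd(fits$U_SE),
    mean_tau_rec = mean(fits$tau_rec), sd_tau_rec = sd(fits$tau_rec),
    mean_tau_facil = mean(fits$tau_facil),
    true_U_SE = truth[[cn]][["U_SE"]],
    true_tau_rec = truth[[cn]][["tau_rec"]])
  message(sprintf(
    "%s: mean fitted U_SE %.3f (truth %.2f), tau_rec %.1f ms (truth %.1f)",
    cn, mean(fits$U_SE), truth[[cn]][["U_SE"]],
    mean(fits$tau_rec), truth[[cn]][["tau_rec"]]))
}

save_results(list(tm_fits = do.call(rbind, all_fits),
                  tm_fit_summary = summary), out)
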