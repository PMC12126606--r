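#!/usr/bin/env Rscript
# Step 4: estimation-statistics comparison of the two fitted cohorts.
#
# Reads results/tm_fits.csv (from 02_fit_stp.R); reports Cohen's d with a
# BCa bootstrap 95% CI (5000 resamples) and a permutation t test (5000
# reshuffles) for the fitted release probability U_SE and recovery time
# constant; writes results/group_stats.json.

suppressPackageStartupMessages(library(synephys))

out <- "results"
fits <- utils::read.csv(file.path(out, "tm_fits.csv"))
ctrl <- fits[fits$condition == "control", ]
spng <- fits[fits$condition == "sponge", ]

stats <- list()
for (par in c("U_SE", "tau_rec")) {
  cmp <- compare_groups(ctrl[[par]], spng[[par]],
                        n_boot = 5000, n_perm = 5000, seed = 17L)
  stats[[par]] <- list(
    mean_control = mean(ctrl[[par]]), mean_sponge = mean(spng[[par]]),
    percent_change = percent_change(mean(ctrl[[par]]), mean(spng[[par]])),
    cohens_d = cmp$d, ci_low = cmp$ci_low, ci_high = cmp$ci_high,
    p_perm = cmp$p_perm)
  message(sprintf(
    "%s: control %.3f vs sponge %.3f (%+.1f%%), d = %.2f [%.2f, %.2f], p = %.4g",
    par, mean(ctrl[[par]]), mean(spng[[par]]),
    percent_change(mean(ctrl[[par]]), mean(spng[[par]])),
    cmp$d, cmp$ci_low, cmp$ci_high, cmp$p_perm))
}

save_results(list(group_stats = stats), out)
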