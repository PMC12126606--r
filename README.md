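# synephys

Analysis of evoked and miniature excitatory postsynaptic currents (EPSCs)
from voltage-clamp recordings, built around the measurements used to dissect
synaptic strength at high-fidelity central synapses such as the cerebellar
mossy-fibre → granule-cell connection. The package is aimed at cellular
electrophysiologists who want a scriptable, testable version of the usual
IgorPro-style analysis chain, together with a synthetic-data generator that
makes every stage verifiable by parameter recovery.

## What it does

* **EPSC quantification** — peak-to-baseline amplitudes after binomial
  smoothing (2 ms pre-stimulus baseline, or a 400 µs post-artifact local
  baseline inside trains; 100 µs peak window), charge integrals,
  biexponential decay fits, 10–90% rise times.
* **Release-probability proxies** — paired-pulse ratios and their
  biexponential dependence on the inter-stimulus interval, coefficient of
  variation of evoked amplitudes, quantal content m = EPSC/q with
  driving-force scaling of mEPSC amplitudes (q).
* **Train analysis** — depression time constant, steady state, phasic
  charge transfer, and cumulative-EPSC back-extrapolation giving the
  readily releasable pool (RRP) and the apparent release probability
  (first EPSC / back-extrapolated cumulative EPSC).
* **Recovery from depression** — biexponential recovery fits over the
  25–3000 ms recovery-pulse intervals with an 85% recovery inclusion rule.
* **Short-term plasticity modelling** — the Tsodyks–Markram model with
  parameters U_SE (utilization of synaptic efficacy ≙ release probability),
  A_SE, τ_facil and τ_rec. Between stimuli,
  du/dt = −u/τ_facil and dR/dt = (1 − R)/τ_rec; at each stimulus
  u ← u + U_SE·(1 − u), the response is A_SE·u·R, and R ← R·(1 − u).
  Parameters are fitted to normalized 100 + 300 Hz train + recovery
  amplitudes with an evolutionary algorithm (SBX crossover and polynomial
  mutation, η = 20, p_c = 0.7, p_m = 0.4, offspring 500, ≤ 50 generations).
* **Peak-scaled non-stationary fluctuation analysis (NSFA)** — variance of
  peak-scaled mEPSC decays versus mean amplitude, fitted with
  σ²(Ī) = i·Ī − Ī²/N + b to yield the unitary current i, the number of
  channels open at the peak N, and the single-channel conductance
  g = i/|V_hold − E_rev| (recordings with > 50 events only).
* **Estimation statistics** — Cohen's d with BCa bootstrap 95% CIs
  (5000 resamples) and permutation t tests (5000 reshuffles).
* **Synthetic data** — deterministic-plasticity train cohorts with
  multiplicative amplitude noise, fully rendered sweeps, and a binomial
  channel model for mEPSCs whose ensemble variance obeys
  σ² = i·Ī − Ī²/N by construction.

## Worked example

Fit the plasticity model to a noiseless 100 + 300 Hz train and recover its
parameters:

```r
library(synephys)

truth <- tm_params(U_SE = 0.34, A_SE = 1 / 0.34, tau_facil = 10, tau_rec = 97.1)
obs <- lapply(c(100, 300), function(f) {
  pr <- stim_protocol(train_freq = f)
  list(stim_times = protocol_stim_times(pr),
       norm_amplitudes = tm_normalized(truth, pr))
})
fit_tm(obs, fit_config(seed = 1))
#> <tm_fit> loss 1.23e-16 after 50 generations
#> Tsodyks-Markram parameters: U_SE = 0.34, A_SE = 2.94, tau_facil = 10 ms, tau_rec = 97.1 ms
```

The numbers mean: the optimizer reduced the summed squared residual over
all 52 pulses to numerical zero and returned the generating parameters —
release probability 0.34, facilitation decay 10 ms, recovery from
depression 97.1 ms (A_SE·U_SE ≈ 1 on the normalized scale).

The numbered scripts under `analysis/` run the full synthetic study:
`01_simulate.R` builds two 20-cell cohorts (control-like, U_SE = 0.34,
τ_rec = 97.1 ms; and a high-release-probability condition, U_SE = 0.45,
τ_rec = 60.8 ms) with 10% amplitude noise; `02_fit_stp.R` fits every cell;
`03_nsfa.R` runs peak-scaled NSFA on simulated mEPSCs; `04_group_stats.R`
compares the fitted parameters between conditions. A representative run
prints:

```
control: mean fitted U_SE 0.340 (truth 0.34), tau_rec 96.6 ms (truth 97.1)
sponge:  mean fitted U_SE 0.445 (truth 0.45), tau_rec 61.9 ms (truth 60.8)
control: g = 14.88 pS (truth 14.1), N = 9.6 (truth 10)
U_SE: control 0.340 vs sponge 0.445 (+31.1%), d = 11.31 [6.14, 19.20], p = 0.0002
```

i.e. both cohort means are recovered within a few percent, and the
between-condition difference in fitted release probability is detected
with a large standardized effect size.

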