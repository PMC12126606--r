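---
title: "Models, measurement conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, measurement conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synephys)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the measurement conventions, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the underlying conventions are genuinely open.

## The short-term plasticity model

`tm_amplitudes()` implements the deterministic Tsodyks–Markram synapse.
Two latent variables evolve between stimuli: the running utilization $u$
(facilitation) decays to zero with $\tau_{facil}$, and the available
resource fraction $R$ (vesicle pool) recovers to one with $\tau_{rec}$:

$$\frac{du}{dt} = -\frac{u}{\tau_{facil}}, \qquad
  \frac{dR}{dt} = \frac{1-R}{\tau_{rec}}.$$

At each stimulus the utilization is incremented *before* release,
$u \leftarrow u + U_{SE}(1-u)$, the response is $A_{SE}\,u\,R$, and the
released fraction is then removed, $R \leftarrow R(1-u)$. At the first
stimulus $u = U_{SE}$ and $R = 1$. Update order matters — conventions
differ across the literature — so this choice is fixed here, stated in the
function documentation, and pinned by a property test that compares the
event-driven recursion against dense ODE integration (`deSolve::lsoda`)
to a relative tolerance of $10^{-5}$ on random parameter draws.

Because between-stimulus dynamics are linear, the recursion uses the exact
interval solutions ($u \cdot e^{-\Delta t/\tau}$ and
$1-(1-R')e^{-\Delta t/\tau}$); there is no integration error.
$\tau_{facil}$ is bounded below at 0.1 ms to keep the exponentials finite.

**Why four parameters.** With normalized amplitudes $A_{SE}$ is redundant
up to the constraint $A_{SE} U_{SE} \approx 1$. It is nevertheless kept as
a free, bounded parameter to mirror the four-parameter fit convention;
the objective compares *raw* model amplitudes $A_{SE} u_n R_n$ against the
normalized data, so the first-pulse residual $(A_{SE}U_{SE}-1)^2$ anchors
the scale and all four parameters are identifiable.

## The evolutionary fit

`fit_tm()` minimizes the summed squared residual over every pulse (train
*and* the six recovery pulses — the recovery pulses are what identify
$\tau_{rec}$) of all supplied frequencies jointly, weighting the 100 Hz
and 300 Hz series equally. The optimizer is a single-objective
evolutionary algorithm with the standard operator suite consistent with
the stated hyperparameters: simulated-binary crossover and polynomial
mutation, both with distribution index $\eta = 20$, crossover probability
0.7, mutation probability 0.4 (a mutated individual perturbs each gene
with probability 0.5), tournament selection of size 3 from the best fifth
of the population, and elitist $(\mu+\lambda)$ truncation survival, which
makes the best loss non-increasing by construction. Defaults are
offspring 500 and at most 50 generations, with early stopping after 10
generations of < $10^{-8}$ improvement.

Two numerical choices matter in practice:

* **Log-scaled genes.** $A_{SE}$, $\tau_{facil}$ and $\tau_{rec}$ span
  3–4 decades within their bounds ($U_{SE} \in [0.01, 1]$,
  $A_{SE} \in [0.1, 100]$, $\tau_{facil} \in [0.1, 500]$ ms,
  $\tau_{rec} \in [1, 2000]$ ms — chosen to cover all plausible values
  with margin). The variation operators act on $\log_{10}$ transforms of
  the three scale-like parameters so that mutation steps are
  proportionate everywhere in the range; on the linear scale the same
  operators spend most of their steps in the wrong decade.
* **Derivative-free polish.** After the EA a short Nelder–Mead descent
  (bound-clamped, on the same gene scale) refines the best individual and
  is kept only if it lowers the loss. On noiseless data this drives the
  residual to numerical zero; without it the EA stops within a small
  neighbourhood of the optimum, which is fine for cohort means but
  noticeably looser per fit.

Each cell of a cohort is fitted with its own derived seed
(`config$seed + cell index`), so cohort fits are independent and exactly
reproducible.

## Measurement conventions

`measure_epsc()` follows fixed windows throughout: amplitudes are
peak-to-baseline after smoothing with normalized Pascal-triangle
(binomial) coefficients of order 50 — matched to 200 kHz acquisition;
reduce `smooth_n` proportionally at lower rates — with the baseline taken
from a 2 ms pre-stimulus window, or, inside trains, from a 400 µs window
immediately after the stimulation artifact (0.2 ms dead time by default),
and the peak as the mean of a 100 µs window centred on the post-stimulus
current minimum (ties: first minimum wins). Positive-going deflections
larger than 1.5× the negative deflection raise a sign error. Charge
integrates (baseline − current) from the stimulus to the first
baseline re-crossing after the peak or a configurable cap, whichever
comes first, since "the entire duration of the EPSC" needs an explicit
endpoint.

Two consequences of these conventions are documented rather than hidden:

* **Local-baseline overlap bias.** Inside high-frequency trains each
  amplitude is referenced to its own post-artifact baseline, i.e. overlap
  is corrected only locally — there is no template subtraction. When the
  decay is slow relative to the inter-stimulus interval, the stacked
  tails keep decaying between the baseline window and the peak window, so
  in-train amplitudes are systematically under-read relative to the
  generative amplitudes (up to tens of percent at 300 Hz with a
  12.9 ms slow decay component). The windowing itself is accurate: with
  negligible overlap the noiseless round trip from simulated amplitude to
  measured amplitude agrees within 2%. Model fitting consumes normalized
  measured amplitudes, which is exactly what the measurement produces on
  real data too.
* **Cumulative-fit abscissa.** The cumulative-EPSC line fit (last 10
  points) uses stimulus times $t_k = k \cdot \mathrm{ISI}$, so a train
  with constant amplitudes (no depletion) back-extrapolates to a zero
  intercept and a degenerate pool estimate is flagged instead of
  invented. The slope is reported in pA/ms. The intercept divided by the
  quantal size gives the RRP in quanta; the first amplitude divided by
  the intercept gives the apparent release probability, the definition
  consistent with quantal content ≈ Pr × RRP. On a depletion-model
  ground truth with constant replenishment the estimator reproduces an
  event-level oracle within 2% but under-reads the true pool by roughly
  15% — the well-known bias of back-extrapolation with ongoing
  recruitment — which the test suite pins as a reproducible property.

`analyze_recovery()` fits $R(t) = 1 - a_f e^{-t/\tau_f} - a_s e^{-t/\tau_s}$
at the cumulative recovery-pulse times (the configured intervals are
*consecutive* inter-stimulus intervals, so the default
25/50/100/300/1000/3000 ms probes recovery out to ~4.5 s) and applies the
85%-recovery inclusion criterion. Fully recovered (flat) input flags the
fit as degenerate rather than fabricating time constants. The depression
fit is a monoexponential-to-plateau in time (not pulse number), and the
steady state is the mean of the last 5 normalized amplitudes; both window
choices are package conventions where no single standard exists.

## Peak-scaled fluctuation analysis

`peak_scaled_nsfa()` scales the mean waveform to each event's peak,
computes the across-event residual variance at every decay sample, pools
the (mean amplitude, variance) points into 10 equal-width amplitude bins,
and fits $\sigma^2(\bar I) = i\bar I - \bar I^2/N + b$ by least squares
weighted with per-bin point counts. The baseline variance $b$ is fitted,
not pre-subtracted, which keeps the method usable when the noise floor is
unknown. Analyses with 50 events or fewer are refused outright.

Event peaks are estimated from a 100 µs window around the aligned peak
(not a single sample), and decay samples with mean amplitude above 97% of
the peak are excluded: at the peak itself the peak-scaling step removes
the channel-gating variance entirely while the recording noise does not
shrink, so near-peak points contain almost pure noise and, if included,
bias the unitary current upward by a few percent on synthetic ground
truth. With these two guards the estimator is unbiased on the binomial
channel model within Monte-Carlo error at 500 events. Bin count,
weighting and the treatment of $b$ are package decisions, stated here
because the underlying method leaves them open.

The simple threshold detector (`detect_mini_events()`, 5 SD criterion) is
deliberately plumbing-grade; serious event detection on real data should
use a dedicated detector, and the NSFA entry point accepts any aligned
waveform matrix.

## Estimation statistics

`compare_groups()` reports Cohen's d (pooled SD, $n_a+n_b-2$
denominator) with a bias-corrected and accelerated bootstrap interval:
resampling is within each group independently (two-independent-groups
design), the bias term comes from the bootstrap proportion below the
point estimate (with a half-tie correction), and the acceleration from
delete-one jackknife skewness over all observations. With fewer than 6
total observations the jackknife is unusable and the function falls back
to a percentile interval, flagged in the result. The permutation test
permutes group labels and uses Welch's t as the statistic — the variant
is unspecified in common usage, and Welch's is the safer default under
unequal variances — with an add-one correction so p is never exactly
zero. Calibration is pinned by a 1000-replicate null simulation in the
test suite (rejection rate 0.05 ± 0.015 at α = 0.05).

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, at
the stated study conditions: 20-pulse trains at 100 or 300 Hz plus six
recovery pulses, five repetitions averaged stimulus-locked, single-pulse
EPSCs, and mEPSC streams at −100 mV. Evoked per-pulse amplitudes are
model predictions times multiplicative Gaussian noise (truncated at zero
by redrawing; default CV 0.1, the order of trial-to-trial variability of
evoked EPSCs), rendered as linearly superimposed templates
$(1-e^{-t/\tau_{rise}})(f e^{-t/\tau_{fast}}+(1-f)e^{-t/\tau_{slow}})$
with a 0.8 ms synaptic onset latency after each stimulus and additive
Gaussian baseline noise (default 2 pA — a typical whole-cell noise floor;
the underlying noise SD is not a quantity the package asserts about any
particular dataset). Default control kinetics use a 0.37 ms rise time
constant, which yields a 10–90% rise of ~0.33 ms with the 1.25/12.87 ms
biexponential decay, and `frac_fast = 0.85`, consistent with a ~3 ms
weighted decay per unit peak. Ground-truth amplitude draws are made
before any baseline-noise draws, so the truth table is invariant to the
noise floor at a fixed seed; fixing the seed reproduces recordings
bit-exactly.

mEPSCs use a binomial channel model: all $N$ channels are open at the
event peak, and each closes independently with survival probability equal
to the normalized mean decay, so the ensemble mean follows the kinetics
while the across-event variance is exactly $i\bar I - \bar I^2/N$ — the
law NSFA assumes. The rise is deterministic; event times are Poisson.

The default cohort ground truths (a control-like condition with
$U_{SE} = 0.34$, $\tau_{rec} = 97.1$ ms, 14.1 pS / ~10 channels, and a
high-release-probability condition with $U_{SE} = 0.45$,
$\tau_{rec} = 60.8$ ms, 14.0 pS / ~15 channels) are group-mean parameter
sets representative of control and miRNA-sponge cerebellar granule-cell
synapses. $\tau_{facil}$ is not separately constrained by published group
means; 10 ms is adopted once as a plausible mossy-fibre value and used as
generating truth throughout. $A_{SE}$ defaults to $1/U_{SE}$ so the
first-pulse model amplitude is 1 on the normalized scale.

What the generator does **not** emulate: stimulation artifacts (optional
rectangular transients exist but are off by default, since analysis
blanks artifacts anyway), electrode/seal drift, receptor desensitization
and saturation, NMDA/GABA components, stochastic vesicle-pool dynamics in
the evoked pathway (the plasticity model is deterministic with
multiplicative noise), and correlated or non-Gaussian recording noise.
Passing parameter-recovery tests therefore demonstrates the correctness
and calibration of the estimators under the stated statistical
assumptions — not robustness to every pathology of real recordings.

## Problem sizes

The test suite and the acceptance script are scaled for a single CPU:
parameter-recovery cohorts use 20 cells with offspring 100 × 30
generations (the full default of 500 × 50 is exercised on noiseless
single fits, where it reaches numerical zero loss); NSFA recovery uses
500 events; the null-calibration simulation uses 1000 replicates with 199
reshuffles each; waveform-level checks render sweeps at 10–100 kHz rather
than the full 200 kHz where the check does not concern the sampling rate
itself. These sizes are the package's validation choices and are stated
in the tests alongside their tolerances.

## Known limitations

* In-train amplitude measurement inherits the local-baseline overlap bias
  discussed above; it is the intended convention, not an estimator of the
  generative amplitude.
* The RRP back-extrapolation under-reads a replenishing pool (~15% on the
  depletion ground truth); comparisons between conditions remain valid
  because the bias is shared.
* The EA's per-fit spread at the reduced 100 × 30 budget is a few percent
  on $U_{SE}$ and $\tau_{rec}$; cohort means are accurate well within
  that.
* BCa intervals with small groups (n < ~10) lean on a noisy jackknife
  acceleration; the percentile fallback below 6 observations is a guard,
  not a recommendation.
* The threshold event detector will merge overlapping minis and miss
  small events near the noise floor; it exists to make the pipeline
  runnable end-to-end, not as a detection benchmark.
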