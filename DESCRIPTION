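Package: synephys
Title: Synaptic Electrophysiology Analysis with Short-Term Plasticity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of evoked and miniature excitatory postsynaptic
    currents (EPSCs) from voltage-clamp recordings, with the analyses used to
    characterise transmission at high-fidelity central synapses such as the
    cerebellar mossy-fibre to granule-cell connection: peak/charge/kinetics
    measurement, paired-pulse ratios, quantal content, high-frequency train
    depression, cumulative-EPSC readily-releasable-pool estimation, recovery
    from depression, peak-scaled non-stationary fluctuation analysis of mEPSC
    decays, Tsodyks-Markram short-term plasticity model fitting via an
    evolutionary algorithm, and estimation statistics (Cohen's d with BCa
    bootstrap intervals and permutation t tests). A synthetic-data generator
    produces ground-truth recordings so every analysis stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    boot,
    withr
Config/testthat/edition: 3
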