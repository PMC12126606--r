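# Shared fixture builders (all generated in code at test time).

control_tm <- function() tm_params(U_SE = 0.34, A_SE = 1 / 0.34,
                                   tau_facil = 10, tau_rec = 97.1)
sponge_tm <- function() tm_params(U_SE = 0.45, A_SE = 1 / 0.45,
                                  tau_facil = 10, tau_rec = 60.8)

# noiseless normalized observation set at 100 + 300 Hz for a parameter set
make_obs <- function(truth) {
  lapply(c(100, 300), function(f) {
    pr <- stim_protocol(train_freq = f)
    list(stim_times = protocol_stim_times(pr),
         norm_amplitudes = tm_normalized(truth, pr))
  })
}

# quick fit configuration used where full convergence is not the point
quick_fit <- function(seed = 1)
  fit_config(offspring_size = 60, max_generations = 15, seed = seed)

# mini-EPSC kinetics used by the channel-model simulations
mini_kin <- function() epsc_kinetics(rise_tau = 0.15, decay_tau_fast = 0.86,
                                     decay_tau_slow = 3, frac_fast = 0.95,
                                     peak = 1)
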