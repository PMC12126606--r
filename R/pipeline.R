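#' Demo pipeline configuration
#'
#' Bundles the protocol, fit configuration, cohort sizes and ground-truth
#' parameters of the end-to-end synthetic demonstration. The two conditions
#' emulate a control-like synapse (release probability U_SE = 0.34, recovery
#' time constant 97.1 ms, single-channel conductance 14.1 pS, ~10 AMPARs
#' open at peak) and a high-release-probability condition (U_SE = 0.45,
#' recovery 60.8 ms, conductance 14.0 pS, ~15 channels).
#'
#' @param n_cells Cells per condition (default 10).
#' @param amplitude_cv Multiplicative amplitude noise CV (default 0.1).
#' @param n_events NSFA events per condition (default 300).
#' @param fit A [fit_config]; default is scaled to a quick demo
#'   (offspring 100, 30 generations).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cells = 10, amplitude_cv = 0.1,
                            n_events = 300,
                            fit = fit_config(offspring_size = 100,
                                             max_generations = 30),
                            seed = 1L, out_dir = "demo_results") {
  stopifnot(n_cells >= 2, n_events > 50)
  structure(list(
    n_cells = n_cells, amplitude_cv = amplitude_cv, n_events = n_events,
    fit = fit, seed = as.integer(seed), out_dir = out_dir,
    conditions = list(
      control = list(params = tm_params(U_SE = 0.34, A_SE = 1 / 0.34,
                                        tau_facil = 10, tau_rec = 97.1),
                     g_pS = 14.1, n_channels = 10),
      sponge = list(params = tm_params(U_SE = 0.45, A_SE = 1 / 0.45,
                                       tau_facil = 10, tau_rec = 60.8),
                    g_pS = 14.0, n_channels = 15))),
    class = "pipeline_config")
}

#' Run the full synthetic pipeline end-to-end
#'
#' Generates two synthetic cohorts (train-plus-recovery amplitude series and
#' binomial-channel mEPSC events) from known ground-truth parameters, fits
#' the Tsodyks-Markram model to every cell with the evolutionary algorithm,
#' runs peak-scaled NSFA per condition, compares the fitted release
#' probabilities between conditions with estimation statistics, and writes
#' the result tables (CSV) and scalar summaries (JSON) to the configured
#' output directory.
#'
#' @param config A [pipeline_config].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `fits` (per-cell data.frame), `nsfa`
#'   (per-condition results), `comparison` (the [compare_groups] result for
#'   U_SE) and `files` (paths written).
#' @export
run_demo <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  fits <- list(); nsfa_res <- list()
  cond_names <- names(config$conditions)
  for (j in seq_along(cond_names)) {
    cn <- cond_names[j]
    cond <- config$conditions[[cn]]
    say("condition %s: simulating %d cells and fitting the plasticity model",
        cn, config$n_cells)
    cohort <- simulate_train_cohort(
      cond$params, n_cells = config$n_cells,
      amplitude_cv = config$amplitude_cv,
      seed = config$seed + 100L * j)
    cfg <- config$fit; cfg$seed <- config$seed + 1000L * j
    f <- fit_tm_cohort(cohort, cfg)
    f$condition <- cn
    fits[[cn]] <- f
    say("condition %s: NSFA on %d simulated mEPSC events", cn, config$n_events)
    i_u <- cond$g_pS / 1000 * 100          # pS * |V| -> pA at -100 mV
    ev <- simulate_mini_events(
      channel_model(cond$n_channels, i_u, baseline_sd = 2),
      epsc_kinetics(rise_tau = 0.15, decay_tau_fast = 0.86,
                    decay_tau_slow = 3, frac_fast = 0.95, peak = 1),
      n_events = config$n_events, rate = 50,
      seed = config$seed + 2000L * j)
    nsfa_res[[cn]] <- peak_scaled_nsfa(ev$waveforms, ev$peak_index,
                                       rate = 50, v_hold = -100)
  }
  fit_tab <- do.call(rbind, fits)
  cmp <- compare_groups(fits[[1]]$U_SE, fits[[2]]$U_SE,
                        seed = config$seed)
  summary_json <- list(
    mean_U_SE = lapply(fits, function(f) mean(f$U_SE)),
    mean_tau_rec = lapply(fits, function(f) mean(f$tau_rec)),
    nsfa_g_pS = lapply(nsfa_res, function(x) x$g_unitary),
    nsfa_n_channels = lapply(nsfa_res, function(x) x$n_channels),
    U_SE_comparison = list(d = cmp$d, ci_low = cmp$ci_low,
                           ci_high = cmp$ci_high, p_perm = cmp$p_perm),
    seed = config$seed)
  files <- save_results(list(tm_fits = fit_tab, summary = summary_json),
                        config$out_dir)
  say("U_SE %s: %.3f, %s: %.3f (d = %.2f [%.2f, %.2f], p = %.4g)",
      cond_names[1], mean(fits[[1]]$U_SE), cond_names[2],
      mean(fits[[2]]$U_SE), cmp$d, cmp$ci_low, cmp$ci_high, cmp$p_perm)
  invisible(list(fits = fit_tab, nsfa = nsfa_res, comparison = cmp,
                 files = files))
}
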