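#' Tsodyks-Markram short-term plasticity parameters
#'
#' Container for the four parameters of the phenomenological
#' depression-facilitation synapse model: `U_SE`, the utilization of synaptic
#' efficacy (fraction of presynaptic resources consumed per action potential,
#' corresponding to release probability); `A_SE`, the absolute synaptic
#' efficacy (amplitude scale, in pA or normalized units); `tau_facil`, the
#' decay time constant of facilitation (ms); and `tau_rec`, the time constant
#' of recovery from depression (ms).
#'
#' @param U_SE Utilization of synaptic efficacy, in (0, 1].
#' @param A_SE Amplitude scale, > 0.
#' @param tau_facil Facilitation time constant in ms, > 0. Values below
#'   0.1 ms are rejected to avoid numerical overflow in the interval decays.
#' @param tau_rec Recovery time constant in ms, > 0.
#'
#' @return An object of class `tm_params`.
#' @export
#' @examples
#' tm_params(U_SE = 0.34, A_SE = 1, tau_facil = 10, tau_rec = 97.1)
tm_params <- function(U_SE, A_SE = 1, tau_facil = 10, tau_rec = 100) {
  stopifnot(is.numeric(U_SE), is.numeric(A_SE),
            is.numeric(tau_facil), is.numeric(tau_rec))
  if (!(U_SE > 0 && U_SE <= 1)) stop("U_SE must be in (0, 1]")
  if (!(A_SE > 0)) stop("A_SE must be > 0")
  if (!(tau_facil >= 0.1)) stop("tau_facil must be >= 0.1 ms")
  if (!(tau_rec > 0)) stop("tau_rec must be > 0")
  structure(list(U_SE = U_SE, A_SE = A_SE,
                 tau_facil = tau_facil, tau_rec = tau_rec),
            class = "tm_params")
}

#' @export
print.tm_params <- function(x, ...) {
  cat(sprintf(
    "Tsodyks-Markram parameters: U_SE = %.3g, A_SE = %.3g, tau_facil = %.3g ms, tau_rec = %.3g ms\n",
    x$U_SE, x$A_SE, x$tau_facil, x$tau_rec))
  invisible(x)
}

#' Per-stimulus EPSC amplitudes of the Tsodyks-Markram model
#'
#' Event-driven exact recursion for the deterministic depression-facilitation
#' model. Between stimuli the running utilization u relaxes to 0 with
#' `tau_facil` and the available resource fraction R recovers to 1 with
#' `tau_rec`. At each stimulus the facilitation increment is applied first,
#' `u <- u + U_SE * (1 - u)`, the response is `A_SE * u * R`, and the released
#' fraction is then subtracted, `R <- R * (1 - u)`. At the first stimulus
#' u = U_SE and R = 1. This update-order convention (facilitate before
#' release, deplete after) follows the standard depressing-facilitating
#' formulation; conventions differ across the literature, so it is fixed
#' here and cross-checked against dense ODE integration in the test suite.
#'
#' @param params A [tm_params] object.
#' @param stim_times Strictly increasing stimulus times in ms.
#'
#' @return Numeric vector of per-stimulus amplitudes (same units as `A_SE`).
#' @export
#' @examples
#' p <- tm_params(U_SE = 0.5, A_SE = 1, tau_facil = 10, tau_rec = 100)
#' tm_amplitudes(p, c(0, 10, 20))
tm_amplitudes <- function(params, stim_times) {
  stopifnot(inherits(params, "tm_params"))
  stim_times <- as.numeric(stim_times)
  if (length(stim_times) == 0) return(numeric(0))
  if (any(diff(stim_times) <= 0))
    stop("stim_times must be strictly increasing")
  amps <- tm_amplitudes_batch(
    matrix(c(params$U_SE, params$A_SE, params$tau_facil, params$tau_rec),
           nrow = 1), stim_times)
  drop(amps)
}

# Vectorized recursion over a matrix of parameter rows
# (columns U_SE, A_SE, tau_facil, tau_rec). Used by the single-parameter
# front end and by the evolutionary optimizer, where evaluating a whole
# population per pulse-step makes the fit fast.
tm_amplitudes_batch <- function(par_mat, stim_times) {
  n <- length(stim_times)
  m <- nrow(par_mat)
  U <- par_mat[, 1]; A <- par_mat[, 2]
  tf <- par_mat[, 3]; tr <- par_mat[, 4]
  amps <- matrix(NA_real_, m, n)
  u <- U                      # first stimulus: u = U_SE, R = 1
  R <- rep(1, m)
  amps[, 1] <- A * u * R
  Rpost <- R * (1 - u)
  if (n > 1) {
    dts <- diff(stim_times)
    for (k in 2:n) {
      ef <- exp(-dts[k - 1] / tf)
      er <- exp(-dts[k - 1] / tr)
      u <- u * ef
      R <- 1 - (1 - Rpost) * er
      u <- u + U * (1 - u)
      amps[, k] <- A * u * R
      Rpost <- R * (1 - u)
    }
  }
  amps
}

#' Normalized Tsodyks-Markram amplitudes for a train + recovery protocol
#'
#' Runs [tm_amplitudes] on the stimulus times of a train-plus-recovery
#' protocol and normalizes to the first pulse, matching the convention of
#' fitting normalized EPSC amplitudes.
#'
#' @param params A [tm_params] object.
#' @param protocol A [stim_protocol] object.
#'
#' @return Numeric vector of length `n_train_pulses + length(recovery_intervals)`
#'   with the first element exactly 1.
#' @export
tm_normalized <- function(params, protocol) {
  st <- protocol_stim_times(protocol)
  a <- tm_amplitudes(params, st)
  a / a[1]
}
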