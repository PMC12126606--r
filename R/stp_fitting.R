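#' Evolutionary-algorithm fit configuration
#'
#' Hyperparameters of the single-objective evolutionary optimizer used to fit
#' the Tsodyks-Markram model: simulated-binary crossover and polynomial
#' mutation (both with distribution index `eta`), tournament selection and
#' one-elite survival. Defaults follow the standard configuration for this
#' problem: offspring size 500, eta = 20, mutation probability 0.4,
#' crossover probability 0.7, at most 50 generations.
#'
#' @param offspring_size Population/offspring size per generation (>= 2).
#' @param eta Distribution index of SBX crossover and polynomial mutation.
#' @param p_mutation Probability that an offspring undergoes mutation; within
#'   a mutated individual each gene is perturbed with probability 0.5.
#' @param p_crossover Probability that a parent pair is recombined.
#' @param max_generations Generation cap.
#' @param bounds 4 x 2 matrix of (low, high) per parameter, rows
#'   `U_SE`, `A_SE`, `tau_facil`, `tau_rec`. Defaults cover all plausible
#'   values with margin: U_SE in `[0.01, 1]`, A_SE in `[0.1, 100]`,
#'   tau_facil in `[0.1, 500]` ms, tau_rec in `[1, 2000]` ms.
#' @param seed Integer seed; identical seed + config + data reproduce the
#'   fit exactly.
#' @param tol_improve Early-stop tolerance: stop if the best loss improves by
#'   less than this over `patience` generations.
#' @param patience Generations without improvement before early stop.
#' @param refine Polish the best individual with a derivative-free
#'   Nelder-Mead local search after the EA (default TRUE); the refined
#'   solution is kept only if its loss is lower.
#'
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(offspring_size = 500, eta = 20, p_mutation = 0.4,
                       p_crossover = 0.7, max_generations = 50,
                       bounds = default_tm_bounds(), seed = 1L,
                       tol_improve = 1e-8, patience = 10, refine = TRUE) {
  stopifnot(offspring_size >= 2,
            p_mutation >= 0, p_mutation <= 1,
            p_crossover >= 0, p_crossover <= 1,
            max_generations >= 1)
  bounds <- as.matrix(bounds)
  if (!all(dim(bounds) == c(4, 2)) || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a 4 x 2 matrix with low < high")
  structure(list(offspring_size = as.integer(offspring_size), eta = eta,
                 p_mutation = p_mutation, p_crossover = p_crossover,
                 max_generations = as.integer(max_generations),
                 bounds = bounds, seed = as.integer(seed),
                 tol_improve = tol_improve, patience = as.integer(patience),
                 refine = isTRUE(refine)),
            class = "fit_config")
}

#' @rdname fit_config
#' @export
default_tm_bounds <- function() {
  matrix(c(0.01, 1,
           0.1, 100,
           0.1, 500,
           1, 2000),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("U_SE", "A_SE", "tau_facil", "tau_rec"),
                         c("low", "high")))
}

# sum of squared residuals of raw model amplitudes against normalized
# observations, over all series (train + recovery pulses, all frequencies).
# With normalized data the first-pulse residual (A_SE * U_SE - 1)^2 anchors
# the otherwise-redundant A_SE.
tm_loss_batch <- function(pop, observed) {
  loss <- numeric(nrow(pop))
  for (s in observed) {
    pred <- tm_amplitudes_batch(pop, s$stim_times)
    res <- sweep(pred, 2, s$norm_amplitudes)
    loss <- loss + rowSums(res * res)
  }
  loss
}

# simulated binary crossover (SBX), vectorized over pairs x genes
sbx_crossover <- function(P1, P2, eta, lo, hi) {
  u <- matrix(stats::runif(length(P1)), nrow(P1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  C1 <- 0.5 * ((1 + beta) * P1 + (1 - beta) * P2)
  C2 <- 0.5 * ((1 - beta) * P1 + (1 + beta) * P2)
  list(clamp_rows(C1, lo, hi), clamp_rows(C2, lo, hi))
}

# polynomial mutation on selected genes
poly_mutate <- function(X, mask, eta, lo, hi) {
  if (!any(mask)) return(X)
  lo_m <- matrix(lo, nrow(X), ncol(X), byrow = TRUE)
  hi_m <- matrix(hi, nrow(X), ncol(X), byrow = TRUE)
  span <- hi_m - lo_m
  u <- matrix(stats::runif(length(X)), nrow(X))
  d1 <- (X - lo_m) / span
  d2 <- (hi_m - X) / span
  mpow <- 1 / (eta + 1)
  dq <- ifelse(u < 0.5,
               (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^mpow - 1,
               1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^mpow)
  Xm <- X + dq * span
  X[mask] <- Xm[mask]
  clamp_rows(X, lo, hi)
}

clamp_rows <- function(X, lo, hi) {
  for (j in seq_along(lo)) X[, j] <- pmin(pmax(X[, j], lo[j]), hi[j])
  X
}

#' Fit the Tsodyks-Markram model to normalized train amplitudes
#'
#' Optimizes `U_SE`, `A_SE`, `tau_facil` and `tau_rec` against normalized
#' EPSC amplitude series (train plus recovery pulses) recorded at one or
#' several train frequencies, jointly, by minimizing the summed squared
#' residuals with an evolutionary algorithm: tournament selection (size 3)
#' from the better half of the population, simulated-binary crossover and
#' polynomial mutation (both with distribution index `eta`), and elitist
#' (mu + lambda) truncation survival, so the best loss is non-increasing
#' across generations by construction. Internally `A_SE`, `tau_facil` and
#' `tau_rec` are searched on a log10 scale (they span 3-4 decades within
#' their bounds; `U_SE` stays linear), which conditions the variation
#' operators evenly across the range. An optional Nelder-Mead polish of the
#' best individual (derivative-free, bound-clamped) tightens the final
#' solution and is kept only when it lowers the loss.
#'
#' @param observed A single series or a list of series; each series is a list
#'   with `stim_times` (ms, strictly increasing) and `norm_amplitudes`
#'   (first element 1, length >= 2, same length as `stim_times`).
#' @param config A [fit_config].
#'
#' @return An object of class `tm_fit` with fields `params` ([tm_params]),
#'   `loss` (sum of squared residuals), `n_generations_run`, `converged`
#'   (TRUE if the early-stopping rule fired before the generation cap),
#'   `at_boundary` (TRUE if any fitted parameter sits on its bound, e.g. for
#'   degenerate all-equal input), and `loss_history` (best loss per
#'   generation).
#' @export
fit_tm <- function(observed, config = fit_config()) {
  if (!is.null(observed$stim_times)) observed <- list(observed)
  for (s in observed) {
    if (length(s$norm_amplitudes) < 2)
      stop("each observed series needs at least 2 amplitudes")
    if (length(s$norm_amplitudes) != length(s$stim_times))
      stop("norm_amplitudes and stim_times must have equal length")
    if (abs(s$norm_amplitudes[1] - 1) > 1e-8)
      stop("normalized series must start at 1")
    if (any(diff(s$stim_times) <= 0))
      stop("stim_times must be strictly increasing")
  }
  set.seed(config$seed)
  # gene space: U_SE linear, A_SE/tau_facil/tau_rec log10
  lo_n <- config$bounds[, 1]; hi_n <- config$bounds[, 2]
  lo <- c(lo_n[1], log10(lo_n[2:4])); hi <- c(hi_n[1], log10(hi_n[2:4]))
  to_nat <- function(P) { P[, 2:4] <- 10^P[, 2:4]; P }
  eval_loss <- function(P) tm_loss_batch(to_nat(P), observed)
  lam <- config$offspring_size
  pop <- sapply(seq_along(lo), function(j) stats::runif(lam, lo[j], hi[j]))
  loss <- eval_loss(pop)
  history <- min(loss)
  stall_ref <- min(loss); stall <- 0L; converged <- FALSE
  gens <- 1L
  for (g in seq_len(config$max_generations - 1L)) {
    gens <- g + 1L
    mu <- max(2L, lam %/% 5L)             # parent pool: best fifth
    ord <- order(loss)
    parents <- pop[ord[1:mu], , drop = FALSE]
    ploss <- loss[ord[1:mu]]
    pick <- function(k) {
      cand <- matrix(sample.int(mu, 3 * k, replace = TRUE), ncol = 3)
      cand[cbind(seq_len(k), max.col(-matrix(ploss[cand], k)))]
    }
    half <- ceiling(lam / 2)
    p1 <- parents[pick(half), , drop = FALSE]
    p2 <- parents[pick(half), , drop = FALSE]
    do_cx <- stats::runif(half) < config$p_crossover
    if (any(do_cx)) {
      cx <- sbx_crossover(p1[do_cx, , drop = FALSE],
                          p2[do_cx, , drop = FALSE], config$eta, lo, hi)
      p1[do_cx, ] <- cx[[1]]; p2[do_cx, ] <- cx[[2]]
    }
    off <- rbind(p1, p2)[seq_len(lam), , drop = FALSE]
    mut_ind <- stats::runif(lam) < config$p_mutation
    mask <- mut_ind & matrix(stats::runif(lam * 4) < 0.5, lam)
    off <- poly_mutate(off, mask, config$eta, lo, hi)
    off_loss <- eval_loss(off)
    comb <- rbind(pop, off); comb_loss <- c(loss, off_loss)
    keep <- order(comb_loss)[seq_len(lam)]   # (mu + lambda) truncation
    pop <- comb[keep, , drop = FALSE]; loss <- comb_loss[keep]
    history <- c(history, loss[1])
    if (stall_ref - loss[1] < config$tol_improve) {
      stall <- stall + 1L
      if (stall >= config$patience) { converged <- TRUE; break }
    } else {
      stall_ref <- loss[1]; stall <- 0L
    }
  }
  best <- pop[1, ]; best_loss <- loss[1]
  if (config$refine) {
    obj <- function(x) {
      x <- pmin(pmax(x, lo), hi)
      eval_loss(matrix(x, nrow = 1))
    }
    pol <- stats::optim(best, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (pol$value < best_loss) {
      best <- pmin(pmax(pol$par, lo), hi)
      best_loss <- pol$value
    }
  }
  best_nat <- drop(to_nat(matrix(best, nrow = 1)))
  at_boundary <- any(abs(best - lo) < 1e-9 * (hi - lo)) ||
    any(abs(best - hi) < 1e-9 * (hi - lo))
  structure(list(
    params = tm_params(U_SE = best_nat[1], A_SE = best_nat[2],
                       tau_facil = best_nat[3], tau_rec = best_nat[4]),
    loss = best_loss, n_generations_run = gens,
    converged = converged, at_boundary = at_boundary,
    loss_history = history), class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("<tm_fit> loss %.3g after %d generations%s%s\n",
              x$loss, x$n_generations_run,
              if (x$converged) " (converged)" else "",
              if (x$at_boundary) " [boundary]" else ""))
  print(x$params)
  invisible(x)
}

#' Fit every cell of a simulated or measured cohort
#'
#' @param cohort List of cells as produced by [simulate_train_cohort]; each
#'   cell is a list of normalized series.
#' @param config [fit_config]; each cell's fit is seeded with
#'   `config$seed + cell index` for independence and reproducibility.
#' @return A data.frame with one row per cell: the fitted parameters, the
#'   loss and convergence info.
#' @export
fit_tm_cohort <- function(cohort, config = fit_config()) {
  rows <- lapply(seq_along(cohort), function(i) {
    cfg <- config; cfg$seed <- config$seed + i
    f <- fit_tm(cohort[[i]], cfg)
    data.frame(cell = i, U_SE = f$params$U_SE, A_SE = f$params$A_SE,
               tau_facil = f$params$tau_facil, tau_rec = f$params$tau_rec,
               loss = f$loss, generations = f$n_generations_run,
               converged = f$converged, at_boundary = f$at_boundary)
  })
  do.call(rbind, rows)
}
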