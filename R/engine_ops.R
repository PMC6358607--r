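#' Engine configuration
#'
#' Tunables of the adaptive differential-evolution loop. Defaults are the
#' schedule used for the media-optimization campaigns: mutation factor
#' F = 1 reduced to 0.5 once the candidate-set score converges; crossover
#' rate CR = 0.5 reduced to 0.25 after the F reduction once, on average,
#' at least half of each target's elements are unchanged between two
#' consecutive generations.
#'
#' @param F_init,F_reduced mutation factor before/after convergence.
#' @param CR_init,CR_reduced crossover rate before/after the late-stage
#'   reduction.
#' @param extra_population extra formulations added to the 3 x D
#'   population (e.g. to fill liquid-handler capacity).
#' @param replicates replicate measurements per formulation per
#'   generation (>= 2; with 3 vs 3 replicates the smallest one-sided exact
#'   rank-sum p is 0.05).
#' @param alpha one-sided rank-sum significance level for a trial to
#'   displace its target.
#' @param clearing_fraction candidate-set members scoring below
#'   `(1 - clearing_fraction) x best` are cleared (the 10% score range).
#' @param margin multiplier on the inter-experimental score SD in
#'   competition against the best encountered.
#' @param convergence_tol,convergence_window relative best-score change
#'   and number of consecutive generations defining convergence (triggers
#'   the F reduction).
#' @param max_generations hard generation cap.
#' @param carried_termination stop early when, after the F reduction, at
#'   least 90% of the population is carried over unchanged for
#'   `convergence_window` consecutive generations. Disable to run the
#'   full horizon (as in benchmark performance-curve comparisons).
#' @param seed engine RNG seed.
#' @return a list of class `hdde_config`.
#' @export
engine_config <- function(F_init = 1.0, F_reduced = 0.5,
                          CR_init = 0.5, CR_reduced = 0.25,
                          extra_population = 0L, replicates = 3L,
                          alpha = 0.10, clearing_fraction = 0.10,
                          margin = 1.0,
                          convergence_tol = 0.05, convergence_window = 2L,
                          max_generations = 25L, carried_termination = TRUE,
                          seed = 1L) {
  cfg <- list(F_init = F_init, F_reduced = F_reduced,
              CR_init = CR_init, CR_reduced = CR_reduced,
              extra_population = as.integer(extra_population),
              replicates = as.integer(replicates),
              alpha = alpha, clearing_fraction = clearing_fraction,
              margin = margin,
              convergence_tol = convergence_tol,
              convergence_window = as.integer(convergence_window),
              max_generations = as.integer(max_generations),
              carried_termination = isTRUE(carried_termination),
              seed = as.integer(seed))
  if (!(cfg$F_reduced > 0 && cfg$F_reduced <= cfg$F_init)) {
    stop("require 0 < F_reduced <= F_init", call. = FALSE)
  }
  if (!(cfg$CR_reduced > 0 && cfg$CR_reduced <= cfg$CR_init && cfg$CR_init <= 1)) {
    stop("require 0 < CR_reduced <= CR_init <= 1", call. = FALSE)
  }
  if (!(cfg$clearing_fraction > 0 && cfg$clearing_fraction < 1)) {
    stop("require 0 < clearing_fraction < 1", call. = FALSE)
  }
  if (cfg$replicates < 2) stop("require replicates >= 2", call. = FALSE)
  if (cfg$extra_population < 0) stop("require extra_population >= 0", call. = FALSE)
  class(cfg) <- "hdde_config"
  cfg
}

#' Population size rule
#'
#' NP = 3 x D + extra: three targets per factor, plus any extra
#' formulations used to fill plate capacity.
#'
#' @param D number of factors.
#' @param extra extra formulations (default 0).
#' @return integer population size.
#' @examples
#' population_size(15)      # 45
#' population_size(14, 17)  # 59
#' @export
population_size <- function(D, extra = 0L) {
  stopifnot(D >= 1, extra >= 0)
  as.integer(3L * D + extra)
}

# rand/1 donor: x_r1 + F (x_r2 - x_r3) on level indices treated as reals.
# population: NP x D integer matrix; i: target row.
de_mutate <- function(i, population, F, rng) {
  NP <- nrow(population)
  if (NP < 4) stop("rand/1 mutation needs a population of at least 4", call. = FALSE)
  r <- with_rng(rng, sample(setdiff(seq_len(NP), i), 3L))
  population[r[1], ] + F * (population[r[2], ] - population[r[3], ])
}

# Binomial crossover with one forced donor position (trial always differs
# from the target pre-quantization).
de_crossover <- function(target, donor, CR, rng) {
  D <- length(target)
  stopifnot(length(donor) == D)
  with_rng(rng, {
    take <- stats::runif(D) < CR
    take[sample.int(D, 1L)] <- TRUE
    ifelse(take, donor, as.numeric(target))
  })
}

#' Quantize a real-valued trial vector onto the dose grid
#'
#' Coordinates are rounded to the nearest level index (halves away from
#' zero) and clipped to each factor's valid range.
#'
#' @param space an `hdde_space`.
#' @param x numeric vector of length D.
#' @return integer formulation (0-based level indices).
#' @export
quantize <- function(space, x) {
  if (length(x) != space$D) stop("vector length != D", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite coordinate in trial vector", call. = FALSE)
  k <- as.integer(sign(x) * floor(abs(x) + 0.5))
  pmin(pmax(k, 0L), space$n_levels - 1L)
}

#' Normalized performance score
#'
#' Mean response of a formulation's replicates divided by the mean
#' positive-control (PC) response, so the PC scores 1.0 (100%).
#'
#' @param values replicate responses of the formulation.
#' @param pc_values replicate responses of the positive control.
#' @return scalar score.
#' @export
normalized_score <- function(values, pc_values) {
  if (length(values) == 0 || length(pc_values) == 0) {
    stop("empty replicate set", call. = FALSE)
  }
  pc <- mean(pc_values)
  if (pc <= 0) stop("positive-control mean response must be > 0", call. = FALSE)
  mean(values) / pc
}

#' Noise-aware selection between target and trial
#'
#' The trial displaces the target only when its replicate median is higher
#' and a one-sided Wilcoxon rank-sum test rejects at level `alpha`
#' (exact when tie-free). Ties and non-significant differences retain the
#' incumbent, which stabilizes the population under measurement noise.
#'
#' @param target_values,trial_values replicate responses (>= 2 each).
#' @param alpha one-sided significance level.
#' @return `"target"` or `"trial"`.
#' @examples
#' select_winner(c(10, 11, 12), c(30, 31, 32), alpha = 0.10)  # "trial"
#' @export
select_winner <- function(target_values, trial_values, alpha = 0.10) {
  if (length(target_values) < 2 || length(trial_values) < 2) {
    stop("selection requires at least 2 replicates per formulation", call. = FALSE)
  }
  if (!(stats::median(trial_values) > stats::median(target_values))) {
    return("target")
  }
  p <- suppressWarnings(
    stats::wilcox.test(trial_values, target_values,
                       alternative = "greater", exact = TRUE)$p.value
  )
  if (is.finite(p) && p < alpha) "trial" else "target"
}

#' Convergence detection on the best-score history
#'
#' TRUE when the relative change of the best candidate score is below
#' `tol` over each of the last `window` generation steps.
#'
#' @param history numeric vector of per-generation best scores.
#' @param tol relative tolerance.
#' @param window number of consecutive steps required.
#' @return logical.
#' @export
detect_convergence <- function(history, tol = 0.05, window = 2L) {
  n <- length(history)
  if (n < window + 1L) return(FALSE)
  recent <- history[(n - window):n]
  rel <- abs(diff(recent)) / pmax(abs(recent[-length(recent)]), .Machine$double.eps)
  all(rel < tol)
}
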