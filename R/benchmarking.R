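#' Classic DE comparator (no library, no clearing, no adaptation)
#'
#' Baseline rand/1/bin differential evolution on the discrete grid:
#' each formulation is scored by a single noisy measurement, a trial
#' greedily replaces its target when its (stored, noisy) score is higher,
#' previously seen formulations are re-measured, and F/CR stay fixed.
#' Used to reproduce the qualitative ordering of the in silico
#' benchmark comparison.
#'
#' @param space an `hdde_space`.
#' @param evaluator an evaluator answering [evaluate_batch()].
#' @param budget total number of response measurements allowed.
#' @param NP population size.
#' @param F,CR fixed mutation factor and crossover rate.
#' @param seed search RNG seed.
#' @return list with `best` (formulation with the highest measured
#'   score), `best_measured` (that score), `n_evaluations`.
#' @export
classic_de_run <- function(space, evaluator, budget, NP = 3L * space$D,
                           F = 1.0, CR = 0.5, seed = 1L) {
  rng <- rng_new(seed)
  pop <- t(vapply(seq_len(NP), function(i) random_formulation(space, rng),
                  integer(space$D)))
  measure <- function(forms, gen) {
    res <- evaluate_batch(evaluator, forms, n_replicates = 1L, generation = gen)
    vapply(res$responses, `[[`, numeric(1), 1L)
  }
  fit <- measure(lapply(seq_len(NP), function(i) pop[i, ]), 1L)
  used <- NP
  best_i <- which.max(fit)
  best <- pop[best_i, ]
  best_measured <- fit[best_i]
  gen <- 1L
  while (used + NP <= budget) {
    gen <- gen + 1L
    trials <- pop
    for (i in seq_len(NP)) {
      donor <- de_mutate(i, pop, F, rng)
      trials[i, ] <- quantize(space, de_crossover(pop[i, ], donor, CR, rng))
    }
    tfit <- measure(lapply(seq_len(NP), function(i) trials[i, ]), gen)
    used <- used + NP
    win <- tfit > fit
    pop[win, ] <- trials[win, ]
    fit[win] <- tfit[win]
    if (max(fit) > best_measured) {
      best_i <- which.max(fit)
      best <- pop[best_i, ]
      best_measured <- fit[best_i]
    }
  }
  list(best = as.integer(best), best_measured = best_measured,
       n_evaluations = used)
}

#' Uniform random-search comparator
#'
#' Draws formulations uniformly at random, one noisy measurement each,
#' and keeps the best by measured score.
#'
#' @inheritParams classic_de_run
#' @return list with `best`, `best_measured`, `n_evaluations`.
#' @export
random_search <- function(space, evaluator, budget, seed = 1L) {
  rng <- rng_new(seed)
  best <- NULL
  best_measured <- -Inf
  for (b in seq_len(budget)) {
    f <- random_formulation(space, rng)
    res <- evaluate_batch(evaluator, list(f), n_replicates = 1L,
                          generation = 1L)
    v <- res$responses[[1]][1]
    if (v > best_measured) {
      best_measured <- v
      best <- f
    }
  }
  list(best = as.integer(best), best_measured = best_measured,
       n_evaluations = budget)
}
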