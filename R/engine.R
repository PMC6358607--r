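#' Initialize a closed-loop optimization state
#'
#' Creates the engine state with a uniformly random initial population of
#' `NP = 3 * D + extra_population` formulations, all pending evaluation as
#' generation 1. The state then alternates between [engine_pending()]
#' (formulations awaiting measurement) and [engine_ingest()] (feed
#' responses back); [hdde_run()] drives this loop against an in silico
#' evaluator.
#'
#' @param space an `hdde_space`.
#' @param config an [engine_config()].
#' @return an object of class `hdde_state`.
#' @export
engine_init <- function(space, config = engine_config()) {
  NP <- population_size(space$D, config$extra_population)
  if (NP < 4) stop("population must have at least 4 members for rand/1 mutation",
                   call. = FALSE)
  rng <- rng_new(config$seed)
  population <- t(vapply(seq_len(NP), function(i) random_formulation(space, rng),
                         integer(space$D)))
  state <- list(
    space = space, config = config, NP = NP,
    gen = 0L, population = population, prev_population = NULL,
    F = config$F_init, CR = config$CR_init,
    F_reduced = FALSE, F_reduced_gen = NA_integer_,
    CR_reduced_flag = FALSE, clearing_active = FALSE,
    best_history = numeric(0), carried_history = integer(0),
    cset = candidate_set(cap = NP), lib = eval_library(), rng = rng,
    pending = NULL, trace = NULL,
    terminated = FALSE, reason = NA_character_
  )
  class(state) <- "hdde_state"
  state$pending <- list(generation = 1L, trials = population)
  state
}

#' @export
print.hdde_state <- function(x, ...) {
  cat("HD-DE state: generation", x$gen, "| NP =", x$NP,
      "| F =", x$F, "CR =", x$CR,
      "| unique formulations =", unique_count(x$lib), "\n")
  if (x$terminated) cat("terminated:", x$reason, "\n")
  else if (!is.null(x$pending)) {
    cat("awaiting responses for generation", x$pending$generation, "\n")
  }
  invisible(x)
}

#' Formulations awaiting measurement
#'
#' Returns the deduplicated list of formulations that must be measured to
#' close the pending generation: new trial formulations (library hits are
#' reused, trials identical to their target need no measurement) plus any
#' population member not yet in the library (clearing replacements).
#' Positive-control wells are always required each generation.
#'
#' @param state an `hdde_state`.
#' @return list with `generation` and `formulations` (list of integer
#'   level vectors, possibly empty).
#' @export
engine_pending <- function(state) {
  if (state$terminated) stop("run already terminated (", state$reason, ")",
                             call. = FALSE)
  if (is.null(state$pending)) stop("no pending generation; ingest already closed it",
                                   call. = FALSE)
  trials <- state$pending$trials
  need <- list()
  seen <- character(0)
  add <- function(f) {
    k <- form_key(f)
    if (!(k %in% seen) && !lib_has(state$lib, f)) {
      seen <<- c(seen, k)
      need[[length(need) + 1L]] <<- as.integer(f)
    }
  }
  if (state$pending$generation == 1L) {
    for (i in seq_len(nrow(trials))) add(trials[i, ])
  } else {
    for (i in seq_len(nrow(trials))) {
      if (!identical(as.integer(trials[i, ]), as.integer(state$population[i, ]))) {
        add(trials[i, ])
      }
    }
    for (i in seq_len(state$NP)) add(state$population[i, ])  # cleared-slot targets
  }
  list(generation = state$pending$generation, formulations = need)
}

#' Ingest replicate responses and close the pending generation
#'
#' Records the measurements in the evaluation library, runs rank-sum
#' selection (target vs trial), updates the candidate solution set by
#' competition against the best encountered, applies clearing and the
#' adaptive F/CR schedule, appends a trace row, and checks termination.
#'
#' @param state an `hdde_state` with a pending generation.
#' @param responses named list (by formulation key, see the `key` column
#'   of [library_frame()]) of numeric replicate vectors, one entry per
#'   formulation returned by [engine_pending()].
#' @param pc_values numeric replicate responses of the positive control
#'   for this generation.
#' @param censored optional named list of logical vectors parallel to
#'   `responses` (left-censoring flags).
#' @return the updated `hdde_state`.
#' @export
engine_ingest <- function(state, responses, pc_values, censored = NULL) {
  pending <- engine_pending(state)
  g <- pending$generation
  need_keys <- vapply(pending$formulations, form_key, character(1))
  missing <- setdiff(need_keys, names(responses))
  if (length(missing)) {
    stop("responses missing for formulation(s): ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  unknown <- setdiff(names(responses), need_keys)
  if (length(unknown)) {
    stop("responses supplied for unknown/not-pending formulation(s): ",
         paste(unknown, collapse = "; "), call. = FALSE)
  }
  lib_add_pc(state$lib, pc_values, g)
  for (k in need_keys) {
    lib_add(state$lib, key_to_form(k), responses[[k]], g,
            if (!is.null(censored)) censored[[k]] else NULL)
  }

  cfg <- state$config
  sd_hat <- lib_pooled_score_sd(state$lib)
  evaluated_now <- need_keys

  if (g == 1L) {
    n_improved <- NA_integer_
    n_carried <- NA_integer_
    state$prev_population <- state$population
  } else {
    trials <- state$pending$trials
    n_improved <- 0L
    n_carried <- 0L
    new_pop <- state$population
    for (i in seq_len(state$NP)) {
      target <- as.integer(state$population[i, ])
      trial <- as.integer(trials[i, ])
      if (identical(trial, target)) {
        n_carried <- n_carried + 1L
        next
      }
      w <- select_winner(lib_norm_values(state$lib, target),
                         lib_norm_values(state$lib, trial),
                         alpha = cfg$alpha)
      if (w == "trial") {
        new_pop[i, ] <- trial
        n_improved <- n_improved + 1L
      } else {
        n_carried <- n_carried + 1L
      }
    }
    state$prev_population <- state$population
    state$population <- new_pop
  }

  for (k in evaluated_now) {
    f <- key_to_form(k)
    state$cset <- compete_best(state$cset, f, lib_score(state$lib, f),
                               sd_hat = sd_hat, margin = cfg$margin)
  }

  state$best_history <- c(state$best_history, cset_best(state$cset))
  if (g > 1L) state$carried_history <- c(state$carried_history, n_carried)

  # Adaptive schedule: F drops once on convergence of the best score;
  # clearing activates with it; CR drops only after the F reduction, when
  # on average at least half of each target's elements were unchanged.
  if (!state$F_reduced &&
      detect_convergence(state$best_history, cfg$convergence_tol,
                         cfg$convergence_window)) {
    state$F <- cfg$F_reduced
    state$F_reduced <- TRUE
    state$F_reduced_gen <- g
    state$clearing_active <- TRUE
  }
  if (state$F_reduced && !state$CR_reduced_flag && g > 1L) {
    unchanged <- mean(rowSums(state$population == state$prev_population))
    if (unchanged >= state$space$D / 2) {
      state$CR <- cfg$CR_reduced
      state$CR_reduced_flag <- TRUE
    }
  }

  if (state$clearing_active && length(state$cset$keys) > 0) {
    res <- clearing(state$cset, state$space, state$rng, cfg$clearing_fraction)
    state$cset <- res$cset
    state$population <- .inject_replacements(state$population, res$cleared_keys,
                                             res$replacements, state$lib)
  }

  pop_scores <- vapply(seq_len(state$NP), function(i) {
    lib_score(state$lib, state$population[i, ])
  }, numeric(1))
  row <- data.frame(generation = g,
                    best_score = cset_best(state$cset),
                    mean_score = mean(pop_scores, na.rm = TRUE),
                    n_improved = n_improved, n_carried = n_carried,
                    F = state$F, CR = state$CR,
                    unique_count = unique_count(state$lib))
  state$trace <- rbind(state$trace, row)
  state$gen <- g
  state$pending <- NULL

  cfg_window <- cfg$convergence_window
  if (g >= cfg$max_generations) {
    state$terminated <- TRUE
    state$reason <- "max_generations"
  } else if (cfg$carried_termination && state$F_reduced &&
             (g - state$F_reduced_gen) >= cfg_window) {
    # only generations run *after* the F reduction count towards the streak
    recent <- utils::tail(state$carried_history, g - state$F_reduced_gen)
    recent <- utils::tail(recent, cfg_window)
    if (length(recent) >= cfg_window && all(recent >= ceiling(0.9 * state$NP))) {
      state$terminated <- TRUE
      state$reason <- "converged"
    }
  }
  state
}

# Cleared candidate-set members are replaced in the population by
# perturbed roots: overwrite the slots currently holding a cleared
# formulation, then (if a cleared member is absent from the population)
# the lowest-scoring slots, conserving NP.
.inject_replacements <- function(population, cleared_keys, replacements, lib) {
  if (length(replacements) == 0) return(population)
  pop_keys <- apply(population, 1, form_key)
  slots <- integer(0)
  for (k in cleared_keys) {
    hit <- setdiff(which(pop_keys == k), slots)
    if (length(hit)) slots <- c(slots, hit[1])
  }
  if (length(slots) < length(replacements)) {
    scores <- vapply(seq_len(nrow(population)), function(i) {
      s <- lib_score(lib, population[i, ])
      if (is.na(s)) Inf else s  # never displace a not-yet-measured slot
    }, numeric(1))
    extra <- setdiff(order(scores), slots)
    slots <- c(slots, extra[seq_len(length(replacements) - length(slots))])
  }
  for (i in seq_along(replacements)) {
    population[slots[i], ] <- replacements[[i]]
  }
  population
}

#' Propose the next generation of trial formulations
#'
#' For each target, applies rand/1 mutation on level indices, binomial
#' crossover with one forced donor position, and nearest-level
#' quantization. The proposals are stored in the state (so re-reading a
#' saved state re-emits the identical batch) until [engine_ingest()]
#' closes the generation.
#'
#' @param state an `hdde_state` with no pending generation.
#' @return the updated state, with a new pending generation.
#' @export
engine_propose <- function(state) {
  if (state$terminated) stop("run already terminated (", state$reason, ")",
                             call. = FALSE)
  if (!is.null(state$pending)) return(state)
  g <- state$gen + 1L
  trials <- state$population
  for (i in seq_len(state$NP)) {
    donor <- de_mutate(i, state$population, state$F, state$rng)
    x <- de_crossover(state$population[i, ], donor, state$CR, state$rng)
    trials[i, ] <- quantize(state$space, x)
  }
  state$pending <- list(generation = g, trials = trials)
  state
}

#' Run the closed loop against an in silico evaluator
#'
#' Alternates [engine_propose()], batch evaluation and [engine_ingest()]
#' until termination: either the generation cap is reached, or -- after
#' the F reduction -- at least 90% of the population is carried over
#' unchanged for `convergence_window` consecutive generations.
#'
#' @param space an `hdde_space`.
#' @param evaluator an evaluator object (see [benchmark_landscape()] and
#'   [cell_landscape()]) answering [evaluate_batch()].
#' @param config an [engine_config()].
#' @return an object of class `hdde_run`: list with `state`, `library`
#'   (replicate-level data.frame), `candidates` (scored data.frame),
#'   `trace` (per-generation data.frame) and `reason`.
#' @export
hdde_run <- function(space, evaluator, config = engine_config()) {
  state <- engine_init(space, config)
  repeat {
    pending <- engine_pending(state)
    res <- evaluate_batch(evaluator, pending$formulations,
                          config$replicates, pending$generation)
    names(res$responses) <- vapply(pending$formulations, form_key, character(1))
    if (!is.null(res$censored)) names(res$censored) <- names(res$responses)
    state <- engine_ingest(state, res$responses, res$pc, res$censored)
    if (state$terminated) break
    state <- engine_propose(state)
  }
  structure(list(state = state,
                 library = library_frame(state$lib, space),
                 candidates = cset_frame(state$cset, space),
                 trace = state$trace,
                 reason = state$reason),
            class = "hdde_run")
}

#' @export
print.hdde_run <- function(x, ...) {
  tr <- x$trace
  cat("HD-DE run:", nrow(tr), "generations, terminated by", x$reason, "\n")
  cat("  unique formulations evaluated:", utils::tail(tr$unique_count, 1), "\n")
  cat("  best candidate score:", format(utils::tail(tr$best_score, 1), digits = 4),
      "| candidate set size:", nrow(x$candidates), "\n")
  invisible(x)
}
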