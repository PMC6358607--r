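#' Candidate solution set
#'
#' The maintained set of best-encountered formulations with normalized
#' scores, updated by competition against the best encountered and pruned
#' by clearing. Member formulations are distinct; the set size is bounded
#' (by the population size in the engine).
#'
#' @param cap maximum number of members.
#' @return an object of class `hdde_cset`.
#' @export
candidate_set <- function(cap = Inf) {
  structure(list(keys = character(0), forms = list(), scores = numeric(0),
                 cap = cap),
            class = "hdde_cset")
}

#' @export
print.hdde_cset <- function(x, ...) {
  cat("Candidate solution set:", length(x$keys), "members")
  if (length(x$scores)) cat(", best score", format(max(x$scores), digits = 4))
  cat("\n")
  invisible(x)
}

cset_best <- function(cset) if (length(cset$scores)) max(cset$scores) else NA_real_

cset_frame <- function(cset, space) {
  nms <- vapply(space$factors, `[[`, character(1), "name")
  lv <- do.call(rbind, cset$forms)
  if (is.null(lv)) lv <- matrix(integer(0), 0, space$D)
  colnames(lv) <- paste0("L_", nms)
  out <- data.frame(key = cset$keys, score = cset$scores, lv,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

#' Competition against the best encountered
#'
#' A newly selected formulation enters the candidate set outright while
#' the set is below capacity; once full, it replaces the lowest-scoring
#' member only if its score exceeds that member's by more than
#' `margin x sd_hat`, where `sd_hat` is the pooled SD of per-generation
#' scores of formulations measured in two or more generations (the
#' observable inter-experimental variability), falling back to 0.05 when
#' no repeat measurements exist. Re-encountered members just have their
#' score refreshed.
#'
#' @param cset an `hdde_cset`.
#' @param f candidate formulation (integer level vector).
#' @param score its normalized score.
#' @param sd_hat estimated score SD across generations (`NA` to use the
#'   fallback).
#' @param margin multiplier on `sd_hat`.
#' @return the updated `hdde_cset`.
#' @export
compete_best <- function(cset, f, score, sd_hat = NA_real_, margin = 1.0) {
  key <- form_key(f)
  hit <- match(key, cset$keys)
  if (!is.na(hit)) {
    cset$scores[hit] <- score
    return(cset)
  }
  if (length(cset$keys) < cset$cap) {
    cset$keys <- c(cset$keys, key)
    cset$forms <- c(cset$forms, list(as.integer(f)))
    cset$scores <- c(cset$scores, score)
    return(cset)
  }
  if (!is.finite(sd_hat)) sd_hat <- 0.05
  lo <- which.min(cset$scores)
  if (score > cset$scores[lo] + margin * sd_hat) {
    cset$keys[lo] <- key
    cset$forms[[lo]] <- as.integer(f)
    cset$scores[lo] <- score
  }
  cset
}

#' Clearing (niching) of the candidate set
#'
#' Members scoring below `(1 - fraction)` of the best member are removed;
#' for each cleared member a replacement formulation is generated by
#' perturbing a stochastically chosen (score-weighted) surviving root, so
#' the number of formulations under consideration is conserved.
#'
#' @param cset an `hdde_cset` (non-empty).
#' @param space the `hdde_space`.
#' @param rng engine RNG stream.
#' @param fraction the clearing score range (default 0.10).
#' @return list with elements `cset` (pruned set), `cleared_keys`, and
#'   `replacements` (list of formulations, one per cleared member).
#' @export
clearing <- function(cset, space, rng, fraction = 0.10) {
  stopifnot(length(cset$keys) > 0)
  thr <- (1 - fraction) * cset_best(cset)
  drop <- which(cset$scores < thr)
  cleared_keys <- cset$keys[drop]
  if (length(drop)) {
    cset$keys <- cset$keys[-drop]
    cset$forms <- cset$forms[-drop]
    cset$scores <- cset$scores[-drop]
  }
  replacements <- lapply(seq_along(cleared_keys), function(i) {
    root <- cset_sample_root(cset, rng)
    perturb_root(root, space, rng)
  })
  list(cset = cset, cleared_keys = cleared_keys, replacements = replacements)
}

# Score-weighted stochastic root selection among surviving members.
cset_sample_root <- function(cset, rng) {
  stopifnot(length(cset$keys) > 0)
  w <- pmax(cset$scores, 0)
  if (sum(w) <= 0) w <- rep(1, length(w))
  i <- with_rng(rng, sample.int(length(w), 1L, prob = w))
  cset$forms[[i]]
}

#' Perturb a root formulation
#'
#' Deterministically enumerates the pool of all single-factor, one-level
#' neighbours of the root (each factor moved up or down one dose level,
#' clipped to the grid; the root itself excluded) and returns one pool
#' member uniformly at random. The result is always at dose-step distance
#' exactly 1 from the root.
#'
#' @param root integer formulation.
#' @param space the `hdde_space`.
#' @param rng engine RNG stream.
#' @return an integer formulation.
#' @export
perturb_root <- function(root, space, rng) {
  pool <- perturb_pool(root, space)
  if (length(pool) == 0) stop("empty perturbation pool", call. = FALSE)
  pool[[with_rng(rng, sample.int(length(pool), 1L))]]
}

# The deterministic neighbour pool of a root formulation.
perturb_pool <- function(root, space) {
  root <- validate_formulation(space, root)
  pool <- list()
  for (j in seq_len(space$D)) {
    for (step in c(-1L, 1L)) {
      v <- root[j] + step
      if (v >= 0L && v < space$n_levels[j]) {
        nb <- root
        nb[j] <- v
        pool[[length(pool) + 1L]] <- nb
      }
    }
  }
  pool
}
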