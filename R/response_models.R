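#' Batch evaluation interface
#'
#' Evaluators stand in for the wet lab: given a batch of formulations they
#' return replicate responses plus positive-control (PC) replicates for
#' the generation. Each evaluator owns its own seeded RNG stream, so
#' measurement noise is reproducible independently of the search.
#'
#' @param evaluator an evaluator object.
#' @param formulations list of integer formulations (possibly empty).
#' @param n_replicates replicates per formulation.
#' @param generation generation index (>= 1).
#' @return list with `responses` (list of numeric vectors), `censored`
#'   (list of logical vectors or `NULL`) and `pc` (numeric PC replicates).
#' @export
evaluate_batch <- function(evaluator, formulations, n_replicates, generation) {
  UseMethod("evaluate_batch")
}

#' The Rosenbrock function
#'
#' `sum_{i=1}^{D-1} 100 (x_{i+1} - x_i^2)^2 + (1 - x_i)^2`; global minimum
#' 0 at (1, ..., 1). Used (minimized) as the in silico benchmark
#' objective.
#'
#' @param x numeric vector, length >= 2.
#' @return scalar value.
#' @examples
#' rosenbrock(rep(1, 15))  # 0
#' rosenbrock(c(-1, 1))    # 4
#' @export
rosenbrock <- function(x) {
  if (length(x) < 2) stop("Rosenbrock needs at least 2 coordinates", call. = FALSE)
  i <- seq_len(length(x) - 1)
  sum(100 * (x[i + 1] - x[i]^2)^2 + (1 - x[i])^2)
}

#' Noisy Rosenbrock benchmark landscape
#'
#' Maps each factor's level indices onto an equally spaced coordinate grid
#' (default \[-2, 2\], so 5-level grids contain the continuous optimum at
#' 1), scores a formulation by the affinely rescaled Rosenbrock value
#' `s(f) = (f_max - rosen) / (f_max - f_min)` -- the exact grid extrema
#' come from [grid_extrema_chain_dp()], so the best grid point scores 1.0,
#' playing the role of the known maximum / positive control -- and adds
#' independent Normal(0, `noise_sd`) noise to every replicate.
#'
#' @param space an `hdde_space` with >= 2 factors.
#' @param lower,upper coordinate range each factor's levels are spread over.
#' @param noise_sd replicate noise SD on the normalized score scale.
#' @param seed evaluator RNG seed.
#' @return an evaluator of class `benchmark_landscape`.
#' @export
benchmark_landscape <- function(space, lower = -2, upper = 2,
                                noise_sd = 0.05, seed = 1L) {
  stopifnot(space$D >= 2, noise_sd >= 0)
  grids <- lapply(space$n_levels, function(L) seq(lower, upper, length.out = L))
  obj <- list(space = space, grids = grids, noise_sd = noise_sd,
              rng = rng_new(seed))
  ext <- grid_extrema_chain_dp(obj)
  if (ext$f_max <= ext$f_min) stop("degenerate benchmark grid", call. = FALSE)
  obj$extrema <- ext
  class(obj) <- "benchmark_landscape"
  obj
}

bench_coords <- function(landscape, f) {
  f <- validate_formulation(landscape$space, f)
  vapply(seq_along(f), function(j) landscape$grids[[j]][f[j] + 1L], numeric(1))
}

#' Deterministic normalized benchmark score of a formulation
#'
#' @param landscape a [benchmark_landscape()].
#' @param f integer formulation.
#' @return score in \[0, 1\]; 1 at the grid optimum.
#' @export
benchmark_true_score <- function(landscape, f) {
  ext <- landscape$extrema
  (ext$f_max - rosenbrock(bench_coords(landscape, f))) / (ext$f_max - ext$f_min)
}

#' Noisy replicate scores from the benchmark
#'
#' @param f integer formulation.
#' @param landscape a [benchmark_landscape()].
#' @param n_replicates number of replicates.
#' @param rng optional stream (defaults to the landscape's own).
#' @return numeric replicate scores.
#' @export
benchmark_response <- function(f, landscape, n_replicates = 3L, rng = NULL) {
  if (is.null(rng)) rng <- landscape$rng
  s <- benchmark_true_score(landscape, f)
  s + with_rng(rng, stats::rnorm(n_replicates, 0, landscape$noise_sd))
}

#' @export
evaluate_batch.benchmark_landscape <- function(evaluator, formulations,
                                               n_replicates, generation) {
  responses <- lapply(formulations, function(f) {
    # responses must be nonnegative (count analogue): clip at 0
    pmax(benchmark_response(f, evaluator, n_replicates), 0)
  })
  pc <- pmax(1 + with_rng(evaluator$rng,
                          stats::rnorm(n_replicates, 0, evaluator$noise_sd)), 0)
  list(responses = responses, censored = NULL, pc = pc)
}

#' Exact grid extrema of the Rosenbrock benchmark by chain dynamic programming
#'
#' The Rosenbrock sum couples only adjacent coordinates, so the discrete
#' extrema over the full grid are found exactly by a forward pass whose
#' state is the level of the current factor: O(D * L^2) instead of
#' enumerating `prod(L_j)` points.
#'
#' @param landscape a [benchmark_landscape()] (or a list with `space` and
#'   per-factor coordinate `grids`).
#' @return list with `f_min`, `f_max`, `argmin`, `argmax` (0-based level
#'   vectors).
#' @export
grid_extrema_chain_dp <- function(landscape) {
  grids <- landscape$grids
  D <- length(grids)
  stopifnot(D >= 2)
  term <- function(xi, xj) 100 * (xj - xi^2)^2 + (1 - xi)^2
  # value[k] = best partial sum of terms 1..i-1 with x_i at level k
  run_dp <- function(better) {
    value <- rep(0, length(grids[[1]]))
    back <- vector("list", D)
    for (i in 2:D) {
      gi <- grids[[i - 1]]
      gj <- grids[[i]]
      newv <- numeric(length(gj))
      bk <- integer(length(gj))
      for (b in seq_along(gj)) {
        cand <- value + term(gi, gj[b])
        a <- if (better == "min") which.min(cand) else which.max(cand)
        newv[b] <- cand[a]
        bk[b] <- a
      }
      value <- newv
      back[[i]] <- bk
    }
    b <- if (better == "min") which.min(value) else which.max(value)
    path <- integer(D)
    path[D] <- b
    for (i in D:2) path[i - 1] <- back[[i]][path[i]]
    list(value = value[b], arg = path - 1L)
  }
  lo <- run_dp("min")
  hi <- run_dp("max")
  list(f_min = lo$value, f_max = hi$value, argmin = lo$arg, argmax = hi$arg)
}

#' Synthetic cell-response landscape
#'
#' Generative log-linear response surface on coded doses: each replicate
#' viable-cell count is
#' `exp(K + G_p + sum_j beta_j x_j + sum_{i<j} beta_ij x_i x_j +
#' sum_j beta_jj x_j^2 + Normal(0, sigma))`,
#' i.e. exactly the quadratic model family the post hoc regression
#' assumes, with lognormal replicate noise and per-generation block
#' offsets. Counts below `detection_threshold` are reported at the
#' threshold with a left-censoring flag (counting sensitivity limit).
#'
#' @param space an `hdde_space`.
#' @param K log-scale intercept (log count of the centre formulation).
#' @param mains numeric length-D main-effect coefficients.
#' @param quads numeric length-D quadratic (square-term) coefficients.
#' @param inters D x D matrix of two-factor interaction coefficients
#'   (upper triangle used), or `NULL` for none.
#' @param blocks numeric vector of generation offsets `G_p` (recycled;
#'   default 0).
#' @param sigma replicate noise SD on the log scale.
#' @param detection_threshold count below which responses are censored.
#' @param pc_log_mean log-scale mean of the positive-control count.
#' @param seed evaluator RNG seed.
#' @return an evaluator of class `cell_landscape`.
#' @export
cell_landscape <- function(space, K = log(1e5),
                           mains = rep(0, space$D), quads = rep(0, space$D),
                           inters = NULL, blocks = 0,
                           sigma = 0.2, detection_threshold = exp(K - 4),
                           pc_log_mean = K + 0.8, seed = 1L) {
  stopifnot(length(mains) == space$D, length(quads) == space$D,
            sigma >= 0, detection_threshold >= 0)
  if (is.null(inters)) inters <- matrix(0, space$D, space$D)
  stopifnot(all(dim(inters) == space$D), all(is.finite(inters)),
            all(is.finite(mains)), all(is.finite(quads)), is.finite(K))
  structure(list(space = space, K = K, mains = as.numeric(mains),
                 quads = as.numeric(quads), inters = inters,
                 blocks = as.numeric(blocks), sigma = sigma,
                 detection_threshold = detection_threshold,
                 pc_log_mean = pc_log_mean, rng = rng_new(seed)),
            class = "cell_landscape")
}

# Noise-free log-scale response (without block offset).
cell_log_mu <- function(landscape, f) {
  x <- coded_dose(landscape$space, f)
  xx <- tcrossprod(x)
  landscape$K + sum(landscape$mains * x) + sum(landscape$quads * x^2) +
    sum(landscape$inters[upper.tri(landscape$inters)] *
          xx[upper.tri(xx)])
}

cell_block <- function(landscape, generation) {
  b <- landscape$blocks
  b[((generation - 1) %% length(b)) + 1]
}

#' Replicate counts from the synthetic cell landscape
#'
#' @param f integer formulation.
#' @param landscape a [cell_landscape()].
#' @param generation generation index `p` (selects the block offset).
#' @param n_replicates replicates to draw.
#' @param rng optional stream (defaults to the landscape's own).
#' @return list with `values` (counts, censored ones reported at the
#'   detection threshold) and `censored` (logical flags).
#' @export
synth_response <- function(f, landscape, generation = 1L, n_replicates = 3L,
                           rng = NULL) {
  stopifnot(generation >= 1)
  if (is.null(rng)) rng <- landscape$rng
  mu <- cell_log_mu(landscape, f) + cell_block(landscape, generation)
  counts <- exp(mu + with_rng(rng, stats::rnorm(n_replicates, 0, landscape$sigma)))
  cens <- counts < landscape$detection_threshold
  counts[cens] <- landscape$detection_threshold
  list(values = counts, censored = cens)
}

#' @export
evaluate_batch.cell_landscape <- function(evaluator, formulations,
                                          n_replicates, generation) {
  out <- lapply(formulations, synth_response, landscape = evaluator,
                generation = generation, n_replicates = n_replicates)
  pc <- exp(evaluator$pc_log_mean +
              with_rng(evaluator$rng, stats::rnorm(n_replicates, 0, evaluator$sigma)))
  list(responses = lapply(out, `[[`, "values"),
       censored = lapply(out, `[[`, "censored"),
       pc = pc)
}

#' A randomized study-shaped cell landscape
#'
#' Draws a coefficient set emulating the effect structure reported for
#' media screens: a few dominant main effects (one clearly strongest),
#' saturation (negative quadratic) terms on some high-dose factors, and
#' many weak two-factor interactions, with lognormal replicate noise.
#'
#' @param space an `hdde_space`.
#' @param n_strong_mains number of strong main effects (|beta| in
#'   0.35-0.55, the first positive).
#' @param n_quads number of negative quadratic (saturation) terms.
#' @param n_inters number of weak two-factor interactions (|beta| ~ 0.1).
#' @param sigma log-scale replicate noise SD.
#' @param seed seed for both the coefficient draw and the evaluator noise.
#' @return a [cell_landscape()].
#' @export
random_cell_landscape <- function(space, n_strong_mains = 3L, n_quads = 2L,
                                  n_inters = 6L, sigma = 0.2, seed = 1L) {
  D <- space$D
  stopifnot(n_strong_mains <= D, n_quads <= D)
  r <- rng_new(seed)
  mains <- with_rng(r, stats::rnorm(D, 0, 0.05))
  strong <- with_rng(r, sample.int(D, n_strong_mains))
  mag <- with_rng(r, stats::runif(n_strong_mains, 0.35, 0.55))
  sgn <- c(1, with_rng(r, sample(c(-1, 1), n_strong_mains - 1, replace = TRUE)))
  mains[strong] <- mag * sgn[seq_len(n_strong_mains)]
  quads <- rep(0, D)
  quads[with_rng(r, sample.int(D, n_quads))] <-
    -with_rng(r, stats::runif(n_quads, 0.15, 0.25))
  inters <- matrix(0, D, D)
  pairs <- which(upper.tri(inters))
  pick <- with_rng(r, sample(pairs, min(n_inters, length(pairs))))
  inters[pick] <- with_rng(r, stats::runif(length(pick), -0.12, 0.12))
  K <- log(1e5)
  cell_landscape(space, K = K, mains = mains, quads = quads, inters = inters,
                 sigma = sigma, seed = seed + 1L)
}

#' Serialize / load a synthetic landscape's coefficients as CSV
#'
#' Long format with columns `term,value`; terms are `K`, `sigma`,
#' `detection_threshold`, `pc_log_mean`, `G<p>`, factor names (mains),
#' `name^2` (quadratics) and `a*b` (interactions). Round-trips exactly.
#'
#' @param landscape a [cell_landscape()].
#' @param path CSV file path.
#' @param space (for reading) the `hdde_space` the coefficients refer to.
#' @param seed evaluator seed for the reloaded landscape.
#' @return `read_landscape_csv()` returns a [cell_landscape()].
#' @export
write_landscape_csv <- function(landscape, path) {
  nms <- vapply(landscape$space$factors, `[[`, character(1), "name")
  rows <- data.frame(term = c("K", "sigma", "detection_threshold", "pc_log_mean"),
                     value = c(landscape$K, landscape$sigma,
                               landscape$detection_threshold,
                               landscape$pc_log_mean))
  rows <- rbind(rows, data.frame(
    term = paste0("G", seq_along(landscape$blocks)), value = landscape$blocks))
  rows <- rbind(rows, data.frame(term = nms, value = landscape$mains))
  rows <- rbind(rows, data.frame(term = paste0(nms, "^2"), value = landscape$quads))
  ut <- which(upper.tri(landscape$inters), arr.ind = TRUE)
  if (nrow(ut)) {
    rows <- rbind(rows, data.frame(
      term = paste0(nms[ut[, 1]], "*", nms[ut[, 2]]),
      value = landscape$inters[ut]))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path, space, seed = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  val <- function(term, default = 0) {
    i <- match(term, df$term)
    if (is.na(i)) default else df$value[i]
  }
  nms <- vapply(space$factors, `[[`, character(1), "name")
  gterms <- grep("^G[0-9]+$", df$term, value = TRUE)
  blocks <- if (length(gterms)) {
    df$value[match(gterms[order(as.integer(sub("^G", "", gterms)))], df$term)]
  } else 0
  inters <- matrix(0, space$D, space$D)
  for (i in grep("\\*", df$term)) {
    ab <- strsplit(df$term[i], "*", fixed = TRUE)[[1]]
    a <- match(ab[1], nms); b <- match(ab[2], nms)
    inters[min(a, b), max(a, b)] <- df$value[i]
  }
  K <- val("K", log(1e5))
  cell_landscape(space, K = K,
                 mains = vapply(nms, val, numeric(1)),
                 quads = vapply(paste0(nms, "^2"), val, numeric(1)),
                 inters = inters, blocks = blocks,
                 sigma = val("sigma", 0.2),
                 detection_threshold = val("detection_threshold", exp(K - 4)),
                 pc_log_mean = val("pc_log_mean", K + 0.8),
                 seed = seed)
}
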