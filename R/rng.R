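#' Independent seeded random-number streams
#'
#' The search engine and each in silico evaluator own separate streams so
#' that measurement noise and search stochasticity can be controlled
#' independently (e.g. re-running the search against a frozen noise
#' realisation). A stream stores a Mersenne-Twister state and swaps it into
#' the session RNG only for the duration of [with_rng()].
#'
#' @param seed integer seed.
#' @return an object of class `hdde_rng`.
#' @export
rng_new <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- .save_session_rng()
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  .restore_session_rng(old)
  e$seed <- as.integer(seed)
  class(e) <- "hdde_rng"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param rng an `hdde_rng` stream.
#' @param expr expression using R's random-number functions.
#' @return the value of `expr`; the stream's state is advanced.
#' @export
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "hdde_rng"))
  old <- .save_session_rng()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit(.restore_session_rng(old), add = TRUE)
  res <- force(expr)
  rng$state <- get(".Random.seed", envir = globalenv())
  res
}

.save_session_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_session_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Serializable snapshot (checkpoint support).
rng_state <- function(rng) as.integer(rng$state)

rng_restore <- function(state) {
  e <- new.env(parent = emptyenv())
  e$state <- as.integer(state)
  e$seed <- NA_integer_
  class(e) <- "hdde_rng"
  e
}
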