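#' The self-assembled evaluation library
#'
#' Deduplicated archive of every formulation ever sent for measurement,
#' with replicate responses, generation tags and censoring flags. Positive
#' control (PC) wells are stored per generation and excluded from the
#' unique-formulation count. Re-submitting an already-seen formulation
#' appends replicates without raising the unique count.
#'
#' @return `eval_library()` returns an empty library (class `hdde_library`,
#'   environment-backed).
#' @export
eval_library <- function() {
  lib <- new.env(parent = emptyenv())
  lib$forms <- new.env(parent = emptyenv())  # key -> integer level vector
  lib$records <- new.env(parent = emptyenv()) # key -> list(gen, values, censored)
  lib$pc <- list()                            # generation -> list(values, censored)
  lib$order <- character(0)                   # insertion order of keys
  class(lib) <- "hdde_library"
  lib
}

lib_has <- function(lib, f) {
  exists(form_key(f), envir = lib$forms, inherits = FALSE)
}

lib_add <- function(lib, f, values, generation, censored = NULL) {
  stopifnot(length(values) >= 1)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("replicate responses must be finite and >= 0", call. = FALSE)
  }
  if (is.null(censored)) censored <- rep(FALSE, length(values))
  key <- form_key(f)
  if (!exists(key, envir = lib$forms, inherits = FALSE)) {
    assign(key, as.integer(f), envir = lib$forms)
    lib$order <- c(lib$order, key)
    assign(key, list(), envir = lib$records)
  }
  recs <- get(key, envir = lib$records)
  recs[[length(recs) + 1L]] <- list(gen = as.integer(generation),
                                    values = values,
                                    censored = as.logical(censored))
  assign(key, recs, envir = lib$records)
  invisible(lib)
}

lib_add_pc <- function(lib, values, generation, censored = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(values))
  lib$pc[[as.character(generation)]] <- list(values = as.numeric(values),
                                             censored = as.logical(censored))
  invisible(lib)
}

lib_pc_mean <- function(lib, generation) {
  pc <- lib$pc[[as.character(generation)]]
  if (is.null(pc)) stop("no PC responses recorded for generation ", generation,
                        call. = FALSE)
  m <- mean(pc$values)
  if (m <= 0) stop("positive-control mean response is not positive", call. = FALSE)
  m
}

lib_records <- function(lib, f) {
  key <- form_key(f)
  if (!exists(key, envir = lib$records, inherits = FALSE)) return(NULL)
  get(key, envir = lib$records)
}

# Raw replicate values pooled over all generations for a formulation.
lib_values <- function(lib, f) {
  recs <- lib_records(lib, f)
  if (is.null(recs)) return(numeric(0))
  unlist(lapply(recs, `[[`, "values"))
}

# Replicates normalized by their own generation's PC mean (score scale);
# keeps reused library replicates comparable across generations.
lib_norm_values <- function(lib, f) {
  recs <- lib_records(lib, f)
  if (is.null(recs)) return(numeric(0))
  unlist(lapply(recs, function(r) r$values / lib_pc_mean(lib, r$gen)))
}

# Mean normalized score of a formulation (per-generation normalization,
# generations weighted by replicate count).
lib_score <- function(lib, f) {
  v <- lib_norm_values(lib, f)
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' @rdname eval_library
#' @param lib an `hdde_library`.
#' @export
unique_count <- function(lib) length(lib$order)

# Pooled SD of per-generation scores across formulations measured in >= 2
# generations: the engine's estimate of inter-experimental variability.
# NA when no formulation has repeats.
lib_pooled_score_sd <- function(lib) {
  devs <- numeric(0)
  for (key in lib$order) {
    recs <- get(key, envir = lib$records)
    gens <- vapply(recs, `[[`, integer(1), "gen")
    if (length(unique(gens)) < 2) next
    s <- vapply(recs, function(r) mean(r$values) / lib_pc_mean(lib, r$gen),
                numeric(1))
    devs <- c(devs, s - mean(s))
  }
  if (length(devs) < 2) return(NA_real_)
  sqrt(sum(devs^2) / (length(devs) - 1))
}

#' Flatten an evaluation library to a replicate-level data frame
#'
#' One row per replicate measurement: formulation id/key, 0-based level
#' columns (`L_<factor>`), generation, replicate index, response,
#' censoring flag, and a control flag (PC rows have `NA` levels).
#'
#' @param lib an `hdde_library`.
#' @param space the `hdde_space` the formulations live in.
#' @return a data.frame.
#' @export
library_frame <- function(lib, space) {
  nms <- vapply(space$factors, `[[`, character(1), "name")
  rows <- list()
  for (key in lib$order) {
    f <- get(key, envir = lib$forms)
    recs <- get(key, envir = lib$records)
    lv <- as.data.frame(stats::setNames(as.list(f), paste0("L_", nms)))
    for (r in recs) {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(key = key, generation = r$gen,
                   replicate = seq_along(r$values),
                   response = r$values, censored = r$censored,
                   is_control = FALSE, stringsAsFactors = FALSE),
        lv)
    }
  }
  na_lv <- as.data.frame(stats::setNames(as.list(rep(NA_integer_, space$D)),
                                         paste0("L_", nms)))
  for (g in names(lib$pc)) {
    pc <- lib$pc[[g]]
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(key = "PC", generation = as.integer(g),
                 replicate = seq_along(pc$values),
                 response = pc$values, censored = pc$censored,
                 is_control = TRUE, stringsAsFactors = FALSE),
      na_lv)
  }
  if (length(rows) == 0) {
    out <- data.frame(key = character(0), generation = integer(0),
                      replicate = integer(0), response = numeric(0),
                      censored = logical(0), is_control = logical(0))
    for (nm in paste0("L_", nms)) out[[nm]] <- integer(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Rebuild a library from a library_frame()-shaped data frame.
library_from_frame <- function(df, space) {
  nms <- paste0("L_", vapply(space$factors, `[[`, character(1), "name"))
  lib <- eval_library()
  if (is.null(df) || NROW(df) == 0) return(lib)
  ctl <- df[df$is_control, , drop = FALSE]
  for (g in unique(ctl$generation)) {
    sub <- ctl[ctl$generation == g, , drop = FALSE]
    lib_add_pc(lib, sub$response, g, sub$censored)
  }
  tst <- df[!df$is_control, , drop = FALSE]
  if (nrow(tst)) {
    # group rows by (key, generation) preserving first-appearance order,
    # so a rebuilt library serializes back to the identical frame
    grp <- paste(tst$key, tst$generation, sep = "@")
    for (g in unique(grp)) {
      sub <- tst[grp == g, , drop = FALSE]
      f <- as.integer(sub[1, nms])
      lib_add(lib, f, sub$response, sub$generation[1], sub$censored)
    }
  }
  lib
}
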