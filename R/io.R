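#' @name run_config
#' @title Run configuration files
#'
#' @description
#' A single YAML file defines a run: `seed`, a `factors` list (as in
#' [write_factor_space()]), an `engine` block (any [engine_config()]
#' argument) and an `evaluator` block with `type` one of `"benchmark"`
#' (noisy Rosenbrock; optional `noise_sd`, `lower`, `upper`),
#' `"synthetic"` (cell landscape; optional `landscape_csv` with explicit
#' coefficients, otherwise a seeded [random_cell_landscape()] draw) or
#' `"external"` (responses arrive via the propose/ingest CSV loop).
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a list with `space`, `engine`
#'   (an `hdde_config`), `evaluator` (raw spec list) and `seed`.
NULL

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$factors)) stop("config lacks a 'factors' block", call. = FALSE)
  space <- factor_space(lapply(cfg$factors, function(fc) {
    culture_factor(fc$name, as.numeric(fc$doses),
                   if (is.null(fc$unit)) "" else fc$unit)
  }))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  eng <- cfg$engine
  if (is.null(eng)) eng <- list()
  eng$seed <- seed
  engine <- do.call(engine_config, eng)
  ev <- cfg$evaluator
  if (is.null(ev)) ev <- list(type = "external")
  list(space = space, engine = engine, evaluator = ev, seed = seed)
}

#' Build an evaluator from a config evaluator block
#'
#' @param spec evaluator block of a run config (list with `type`).
#' @param space the `hdde_space`.
#' @param seed default evaluator seed (the run seed + 1; overridden by
#'   `spec$seed`).
#' @return an evaluator object, or `NULL` for `type: external`.
#' @export
make_evaluator <- function(spec, space, seed = 2L) {
  type <- if (is.null(spec$type)) "external" else spec$type
  if (!is.null(spec$seed)) seed <- as.integer(spec$seed)
  pick <- function(name, default) if (is.null(spec[[name]])) default else spec[[name]]
  switch(type,
    external = NULL,
    benchmark = benchmark_landscape(
      space,
      lower = pick("lower", -2), upper = pick("upper", 2),
      noise_sd = pick("noise_sd", 0.05), seed = seed),
    synthetic = {
      if (!is.null(spec$landscape_csv)) {
        read_landscape_csv(spec$landscape_csv, space, seed = seed)
      } else {
        random_cell_landscape(
          space,
          n_strong_mains = pick("n_strong_mains", 3L),
          n_quads = pick("n_quads", 2L),
          n_inters = pick("n_inters", 6L),
          sigma = pick("sigma", 0.2), seed = seed)
      }
    },
    stop("unknown evaluator type: ", type, call. = FALSE)
  )
}

# --- provenance -------------------------------------------------------------

# FNV-1a 32-bit hash over raw bytes, hex string; used to stamp outputs
# with the config / library they derive from.
fnv1a <- function(raw_bytes) {
  h <- 2166136261
  for (b in as.integer(raw_bytes)) {
    # xor with a byte touches only the low 8 bits; keep h as a double < 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  # h is a double; render as 8 hex digits without 32-bit coercion
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

config_hash <- function(config) fnv1a(serialize(unclass(config), NULL))

file_hash <- function(path) fnv1a(readBin(path, "raw", file.size(path)))

meta_line <- function(seed, hash, extra = "") {
  paste0("# hdde schema=1 seed=", seed, " hash=", hash,
         if (nzchar(extra)) paste0(" ", extra) else "")
}

write_csv_meta <- function(df, path, seed, hash, extra = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_line(seed, hash, extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a package-written CSV (skipping the provenance header)
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# --- checkpointing ----------------------------------------------------------

#' Save / load an engine state checkpoint
#'
#' JSON snapshot of the complete engine state (space, configuration,
#' population, candidate set, evaluation library, RNG state, pending
#' proposals, trace), sufficient to stop and resume a lab-in-the-loop run
#' between generations.
#'
#' @param state an `hdde_state`.
#' @param path JSON file path.
#' @return `load_checkpoint()` returns the restored `hdde_state`.
#' @export
save_checkpoint <- function(state, path) {
  space <- state$space
  obj <- list(
    schema = 1L,
    space = lapply(space$factors, function(f) {
      list(name = f$name, unit = f$unit, doses = f$doses)
    }),
    config = unclass(state$config),
    NP = state$NP, gen = state$gen,
    population = state$population,
    prev_population = state$prev_population,
    F = state$F, CR = state$CR,
    F_reduced = state$F_reduced, F_reduced_gen = state$F_reduced_gen,
    CR_reduced_flag = state$CR_reduced_flag,
    clearing_active = state$clearing_active,
    best_history = state$best_history,
    carried_history = state$carried_history,
    cset = list(keys = state$cset$keys, forms = state$cset$forms,
                scores = state$cset$scores, cap = state$NP),
    library = library_frame(state$lib, space),
    rng_state = rng_state(state$rng),
    pending = if (is.null(state$pending)) NULL else
      list(generation = state$pending$generation, trials = state$pending$trials),
    trace = state$trace,
    terminated = state$terminated, reason = state$reason
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("corrupt or unreadable checkpoint '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(obj$schema) || obj$schema != 1L || is.null(obj$population)) {
    stop("corrupt checkpoint '", path, "': missing schema/population",
         call. = FALSE)
  }
  space <- factor_space(lapply(seq_len(nrow(obj$space)), function(i) {
    culture_factor(obj$space$name[i], obj$space$doses[[i]], obj$space$unit[i])
  }))
  cfgl <- obj$config
  config <- do.call(engine_config, cfgl[setdiff(names(cfgl), character(0))])
  as_pop <- function(m) {
    if (is.null(m)) return(NULL)
    matrix(as.integer(m), nrow = obj$NP, ncol = space$D)
  }
  cset <- candidate_set(cap = obj$NP)
  if (length(obj$cset$keys)) {
    cset$keys <- as.character(obj$cset$keys)
    forms <- obj$cset$forms
    if (is.matrix(forms)) {
      forms <- lapply(seq_len(nrow(forms)), function(i) as.integer(forms[i, ]))
    } else {
      forms <- lapply(forms, as.integer)
    }
    cset$forms <- forms
    cset$scores <- as.numeric(obj$cset$scores)
  }
  state <- list(
    space = space, config = config, NP = as.integer(obj$NP),
    gen = as.integer(obj$gen),
    population = as_pop(obj$population),
    prev_population = as_pop(obj$prev_population),
    F = obj$F, CR = obj$CR,
    F_reduced = isTRUE(obj$F_reduced),
    F_reduced_gen = if (is.null(obj$F_reduced_gen) ||
                        identical(obj$F_reduced_gen, "NA")) NA_integer_ else
      as.integer(obj$F_reduced_gen),
    CR_reduced_flag = isTRUE(obj$CR_reduced_flag),
    clearing_active = isTRUE(obj$clearing_active),
    best_history = as.numeric(obj$best_history),
    carried_history = as.integer(obj$carried_history),
    cset = cset,
    lib = library_from_frame(obj$library, space),
    rng = rng_restore(obj$rng_state),
    pending = if (is.null(obj$pending)) NULL else
      list(generation = as.integer(obj$pending$generation),
           trials = as_pop(obj$pending$trials)),
    trace = if (is.null(obj$trace)) NULL else within(obj$trace, {
      generation <- as.integer(generation)
      n_improved <- as.integer(n_improved)
      n_carried <- as.integer(n_carried)
      unique_count <- as.integer(unique_count)
    }),
    terminated = isTRUE(obj$terminated),
    reason = if (is.null(obj$reason)) NA_character_ else obj$reason
  )
  class(state) <- "hdde_state"
  state
}

# --- lab-in-the-loop commands ----------------------------------------------

#' Initialize a lab-in-the-loop run directory
#'
#' Creates `outdir`, saves the initial checkpoint (`checkpoint.json`) and
#' a copy of the factor space; [hdde_propose()] then emits the first
#' recipe CSV.
#'
#' @param config_path run-config YAML (see [read_run_config()]).
#' @param outdir run directory.
#' @param seed optional seed override.
#' @return the initial `hdde_state`, invisibly.
#' @export
hdde_init_run <- function(config_path, outdir, seed = NULL) {
  rc <- read_run_config(config_path)
  if (!is.null(seed)) {
    rc$seed <- as.integer(seed)
    eng <- unclass(rc$engine)
    eng$seed <- rc$seed
    rc$engine <- do.call(engine_config, eng)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- engine_init(rc$space, rc$engine)
  file.copy(config_path, file.path(outdir, "config.yaml"), overwrite = TRUE)
  save_checkpoint(state, file.path(outdir, "checkpoint.json"))
  invisible(state)
}

#' Emit the recipe CSV for the pending generation
#'
#' Writes `recipe_G<g>.csv` listing every formulation awaiting
#' measurement: one row per formulation (id = key, then per factor the
#' 1-based dose level and the real concentration) plus a `PC` control
#' row. Re-running without ingesting responses re-emits the identical
#' file (the proposal is frozen in the checkpoint).
#'
#' @param outdir run directory containing `checkpoint.json`.
#' @return path of the written CSV, invisibly.
#' @export
hdde_propose <- function(outdir) {
  ck <- file.path(outdir, "checkpoint.json")
  state <- load_checkpoint(ck)
  if (is.null(state$pending)) {
    state <- engine_propose(state)
    save_checkpoint(state, ck)
  }
  pending <- engine_pending(state)
  space <- state$space
  nms <- vapply(space$factors, `[[`, character(1), "name")
  rows <- lapply(pending$formulations, function(f) {
    r <- list(id = form_key(f))
    for (j in seq_len(space$D)) {
      r[[paste0(nms[j], "_level")]] <- f[j] + 1L  # 1-based for the bench
      r[[paste0(nms[j], "_conc")]] <- space$factors[[j]]$doses[f[j] + 1L]
    }
    as.data.frame(r, check.names = FALSE)
  })
  pc <- as.data.frame(c(list(id = "PC"),
                        stats::setNames(rep(list(NA), 2 * space$D),
                                        c(rbind(paste0(nms, "_level"),
                                                paste0(nms, "_conc"))))),
                      check.names = FALSE)
  df <- rbind(do.call(rbind, rows), pc)
  path <- file.path(outdir, sprintf("recipe_G%d.csv", pending$generation))
  write_csv_meta(df, path, state$config$seed, config_hash(state$config),
                 extra = paste0("generation=", pending$generation))
  invisible(path)
}

#' Ingest a responses CSV and advance the run
#'
#' The responses CSV needs columns `id` (formulation key from the recipe,
#' or `PC`), `response` (viable-cell count; one row per replicate) and
#' optionally `censored` (0/1). Replicate counts must be at least the
#' configured number per formulation. On success the checkpoint is
#' advanced, a trace CSV is rewritten and a JSON log line appended;
#' ingesting twice for the same generation is rejected.
#'
#' @param outdir run directory.
#' @param responses_csv path to the responses CSV.
#' @return the updated `hdde_state`, invisibly.
#' @export
hdde_ingest <- function(outdir, responses_csv) {
  ck <- file.path(outdir, "checkpoint.json")
  state <- load_checkpoint(ck)
  df <- read_csv_meta(responses_csv)
  if (!all(c("id", "response") %in% names(df))) {
    stop("responses CSV must have 'id' and 'response' columns", call. = FALSE)
  }
  bad <- !is.finite(df$response)
  if (any(bad)) {
    stop("malformed numeric response in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$censored)) df$censored <- FALSE
  pending <- engine_pending(state)   # errors if the generation is closed
  need <- vapply(pending$formulations, form_key, character(1))
  ids <- unique(df$id)
  unknown <- setdiff(ids, c(need, "PC"))
  if (length(unknown)) {
    stop("responses reference unknown formulation id(s): ",
         paste(unknown, collapse = "; "), call. = FALSE)
  }
  pc <- df[df$id == "PC", , drop = FALSE]
  if (nrow(pc) == 0) stop("responses CSV lacks PC control rows", call. = FALSE)
  responses <- lapply(split(df[df$id != "PC", ], df$id[df$id != "PC"]),
                      function(s) s$response)
  censored <- lapply(split(df[df$id != "PC", ], df$id[df$id != "PC"]),
                     function(s) as.logical(s$censored))
  nrep <- vapply(responses, length, integer(1))
  if (any(nrep < state$config$replicates)) {
    stop("fewer than ", state$config$replicates, " replicates for: ",
         paste(names(responses)[nrep < state$config$replicates], collapse = "; "),
         call. = FALSE)
  }
  state <- engine_ingest(state, responses, pc$response, censored)
  save_checkpoint(state, ck)
  write_csv_meta(state$trace, file.path(outdir, "trace.csv"),
                 state$config$seed, config_hash(state$config))
  logline <- jsonlite::toJSON(c(as.list(state$trace[nrow(state$trace), ]),
                                list(terminated = state$terminated,
                                     reason = state$reason)),
                              auto_unbox = TRUE, digits = NA)
  cat(logline, "\n", file = file.path(outdir, "log.jsonl"), append = TRUE,
      sep = "")
  invisible(state)
}

#' Run a full in silico optimization and write its artifacts
#'
#' Executes [hdde_run()] with the configured evaluator and writes
#' `library.csv`, `candidates.csv`, `trace.csv` and `summary.json`
#' (unique formulation count, fraction of the search space tested, best
#' score, termination reason, seed and config hash) into `outdir`.
#'
#' @param config_path run-config YAML with evaluator type `benchmark` or
#'   `synthetic`.
#' @param outdir output directory.
#' @param seed optional seed override (engine seed; the evaluator gets
#'   `seed + 1` unless the config pins one).
#' @return the `hdde_run` object, invisibly.
#' @export
hdde_simulate <- function(config_path, outdir, seed = NULL) {
  rc <- read_run_config(config_path)
  if (!is.null(seed)) {
    rc$seed <- as.integer(seed)
    eng <- unclass(rc$engine)
    eng$seed <- rc$seed
    rc$engine <- do.call(engine_config, eng)
  }
  evaluator <- make_evaluator(rc$evaluator, rc$space, seed = rc$seed + 1L)
  if (is.null(evaluator)) {
    stop("simulate requires a 'benchmark' or 'synthetic' evaluator; ",
         "use the propose/ingest loop for external responses", call. = FALSE)
  }
  run <- hdde_run(rc$space, evaluator, rc$engine)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(rc$engine)
  write_csv_meta(run$library, file.path(outdir, "library.csv"), rc$seed, h)
  write_csv_meta(run$candidates, file.path(outdir, "candidates.csv"), rc$seed, h)
  write_csv_meta(run$trace, file.path(outdir, "trace.csv"), rc$seed, h)
  total <- total_combinations(rc$space)
  uc <- unique_count(run$state$lib)
  summary <- list(seed = rc$seed, config_hash = h,
                  generations = nrow(run$trace),
                  unique_count = uc,
                  total_combinations = attr(total, "exact"),
                  fraction_tested_pct = uc / total * 100,
                  best_score = max(run$candidates$score),
                  reason = run$reason)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' Post hoc analysis of a library CSV
#'
#' Reads a `library.csv` (as written by [hdde_simulate()] or rebuilt from
#' lab data), fits the quadratic response-surface model on generations
#' >= 2, and writes `coefficients.csv` (all terms with estimates, FDR p
#' and logworth), `volcano.csv` (plot-ready factor effects), pairwise
#' Hamming and dose-step distance matrices over the distinct
#' formulations of the final generation, and `similarity_trace.csv`
#' (per-generation mean pairwise distances among that generation's
#' formulations, a diversity trace). Outputs are stamped with the input
#' file's checksum.
#'
#' @param library_csv path to the library CSV.
#' @param space the `hdde_space` (or a run-config YAML path to read it
#'   from).
#' @param outdir output directory.
#' @param seed seed for the stochastic censored imputation.
#' @param threshold detection threshold for censored rows (default: the
#'   recorded value of the censored responses).
#' @return the `hdde_regression`, invisibly.
#' @export
hdde_analyze <- function(library_csv, space, outdir, seed = 1L,
                         threshold = NULL) {
  if (is.character(space)) space <- read_run_config(space)$space
  df <- read_csv_meta(library_csv)
  gens <- sort(unique(df$generation[!df$is_control]))
  if (length(gens) < 2) {
    stop("library spans a single generation; excluding the initial ",
         "population leaves nothing to fit", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  h <- file_hash(library_csv)
  design <- build_design(df, space, threshold = threshold, rng = rng_new(seed))
  res <- fit_quadratic(design)
  coefs <- as.data.frame(res)
  write_csv_meta(coefs, file.path(outdir, "coefficients.csv"), seed, h,
                 extra = "log=natural")
  write_csv_meta(volcano_table(res), file.path(outdir, "volcano.csv"), seed, h)

  nms <- paste0("L_", vapply(space$factors, `[[`, character(1), "name"))
  sim_rows <- lapply(gens, function(g) {
    sub <- df[!df$is_control & df$generation == g, , drop = FALSE]
    keys <- unique(sub$key)
    forms <- lapply(keys, function(k) {
      as.integer(sub[match(k, sub$key), nms])
    })
    if (length(forms) < 2) {
      return(data.frame(generation = g, n = length(forms),
                        mean_hamming = NA_real_, mean_dose_steps = NA_real_))
    }
    data.frame(generation = g, n = length(forms),
               mean_hamming = pairwise_matrix(forms, "hamming")$summary[["mean"]],
               mean_dose_steps =
                 pairwise_matrix(forms, "levenshtein_eq")$summary[["mean"]])
  })
  write_csv_meta(do.call(rbind, sim_rows),
                 file.path(outdir, "similarity_trace.csv"), seed, h)

  last <- df[!df$is_control & df$generation == max(gens), , drop = FALSE]
  keys <- unique(last$key)
  if (length(keys) >= 2) {
    forms <- lapply(keys, function(k) as.integer(last[match(k, last$key), nms]))
    for (metric in c("hamming", "levenshtein_eq")) {
      write_distmat_csv(pairwise_matrix(forms, metric, labels = keys),
                        file.path(outdir, paste0("distmat_", metric, ".csv")))
    }
  }
  invisible(res)
}
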