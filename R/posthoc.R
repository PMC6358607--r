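#' Impute left-censored log responses
#'
#' Counts below the detection threshold are recorded at the threshold;
#' for regression they are replaced under a censored-normal model: a
#' normal distribution is fitted to the log responses by maximum
#' likelihood treating flagged values as left-censored at
#' `log(threshold)` (via [fitdistrplus::fitdistcens()]), and each
#' censored value is replaced by a draw from the fitted normal truncated
#' above at `log(threshold)` (or by its conditional mean with
#' `deterministic = TRUE`).
#'
#' @param log_values numeric log-scale responses.
#' @param censored logical flags, same length.
#' @param threshold detection threshold on the count scale (> 0).
#' @param rng an [rng_new()] stream (required unless deterministic).
#' @param deterministic replace by the truncated-normal conditional mean
#'   instead of a random draw.
#' @return completed numeric vector, with the fitted `mu` and `sd` in
#'   attribute `"fit"`.
#' @export
impute_censored <- function(log_values, censored, threshold, rng = NULL,
                            deterministic = FALSE) {
  stopifnot(length(log_values) == length(censored), threshold > 0)
  censored <- as.logical(censored)
  if (!any(censored)) return(log_values)
  if (all(censored)) stop("all responses censored; nothing to fit", call. = FALSE)
  if (sum(!censored) < 10) {
    stop("need at least 10 uncensored responses to fit the censored normal",
         call. = FALSE)
  }
  b <- log(threshold)
  cens <- data.frame(
    left = ifelse(censored, NA_real_, log_values),
    right = ifelse(censored, b, log_values)
  )
  fit <- fitdistrplus::fitdistcens(cens, "norm")
  mu <- unname(fit$estimate["mean"])
  sd <- unname(fit$estimate["sd"])
  z <- (b - mu) / sd
  nc <- sum(censored)
  if (deterministic) {
    draw <- rep(mu - sd * stats::dnorm(z) / stats::pnorm(z), nc)
  } else {
    if (is.null(rng)) stop("stochastic imputation requires an rng stream",
                           call. = FALSE)
    u <- with_rng(rng, stats::runif(nc)) * stats::pnorm(z)
    draw <- mu + sd * stats::qnorm(u)
  }
  out <- log_values
  out[censored] <- draw
  attr(out, "fit") <- c(mu = mu, sd = sd)
  out
}

#' Build the quadratic-model design table from an evaluation library
#'
#' One row per (formulation, replicate) measurement with generation >= 2
#' (the random initial population is excluded); columns are the coded
#' doses `x_j`, their squares, all two-factor crossproducts, and a
#' generation block factor; the response is the natural-log count with
#' left-censored values imputed by [impute_censored()].
#'
#' @param library_df replicate-level data.frame as produced by
#'   [library_frame()] (columns `key`, `L_<factor>`, `generation`,
#'   `response`, `censored`, `is_control`).
#' @param space the `hdde_space`.
#' @param threshold detection threshold on the count scale; defaults to
#'   the largest censored response (their recorded value). Required only
#'   when censored rows exist.
#' @param rng stream for stochastic imputation.
#' @param deterministic_imputation use the conditional-mean imputation.
#' @return a data.frame with response `y`, factor column `block`, and one
#'   column per model term; term metadata in attribute `"terms"`
#'   (data.frame with `column`, `label`, `type`).
#' @export
build_design <- function(library_df, space, threshold = NULL, rng = NULL,
                         deterministic_imputation = FALSE) {
  df <- library_df[!library_df$is_control & library_df$generation >= 2, ,
                   drop = FALSE]
  if (nrow(df) == 0) {
    stop("library spans no generation beyond the first; nothing to analyze",
         call. = FALSE)
  }
  nms <- vapply(space$factors, `[[`, character(1), "name")
  lv <- as.matrix(df[, paste0("L_", nms), drop = FALSE])
  X <- t(apply(lv, 1, function(f) coded_dose(space, f)))
  y <- log(df$response)
  if (any(df$censored)) {
    if (is.null(threshold)) threshold <- max(df$response[df$censored])
    y <- impute_censored(y, df$censored, threshold, rng = rng,
                         deterministic = deterministic_imputation)
  }
  D <- space$D
  safe <- make.names(nms)
  main_cols <- paste0("M_", safe)
  quad_cols <- paste0("Q_", safe)
  out <- data.frame(y = as.numeric(y),
                    block = factor(df$generation), check.names = FALSE)
  for (j in seq_len(D)) out[[main_cols[j]]] <- X[, j]
  for (j in seq_len(D)) out[[quad_cols[j]]] <- X[, j]^2
  terms <- data.frame(column = c(main_cols, quad_cols),
                      label = c(nms, paste0(nms, "^2")),
                      type = rep(c("main", "quadratic"), each = D),
                      stringsAsFactors = FALSE)
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      col <- paste0("I_", safe[i], "_", safe[j])
      out[[col]] <- X[, i] * X[, j]
      terms <- rbind(terms, data.frame(column = col,
                                       label = paste0(nms[i], "*", nms[j]),
                                       type = "interaction"))
    }
  }
  attr(out, "terms") <- terms
  out
}

#' Fit the quadratic response-surface model
#'
#' Ordinary least squares of the log response on the full term set (main,
#' quadratic and two-factor interaction effects on coded doses, plus
#' generation block contrasts with the earliest generation as reference).
#' Raw two-sided t-test p-values per coefficient are FDR-adjusted
#' (Benjamini-Hochberg) over the family of factor-effect terms (blocks
#' and intercept excluded); logworth is `-log10` of the adjusted p.
#' Terms dropped for collinearity are reported with a warning, not
#' silently removed.
#'
#' @param design a [build_design()] table.
#' @return an object of class `hdde_regression`: data.frame with one row
#'   per term (`term`, `type`, `estimate`, `se`, `p_raw`, `p_fdr`,
#'   `logworth`, `significant`, `aliased`), plus the `lm` fit in
#'   attribute `"fit"`.
#' @export
fit_quadratic <- function(design) {
  terms <- attr(design, "terms")
  if (is.null(terms)) stop("design lacks term metadata; use build_design()",
                           call. = FALSE)
  if (nrow(design) <= nrow(terms) + nlevels(design$block)) {
    warning("fewer rows than model terms; expect aliased (pruned) terms",
            call. = FALSE)
  }
  dat <- design
  if (nlevels(dat$block) < 2) dat$block <- NULL  # single generation: no contrasts
  fit <- stats::lm(y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  all_cf <- stats::coef(fit)
  aliased_cols <- names(all_cf)[is.na(all_cf)]
  if (length(aliased_cols)) {
    lab <- terms$label[match(aliased_cols, terms$column)]
    warning("terms aliased (collinear) and pruned from the fit: ",
            paste(ifelse(is.na(lab), aliased_cols, lab), collapse = ", "),
            call. = FALSE)
  }
  if (sum(!is.na(all_cf)) < 2) {
    stop("design singular after pruning; aliased terms: ",
         paste(aliased_cols, collapse = ", "), call. = FALSE)
  }
  get_stat <- function(col, k) if (col %in% rownames(cf)) cf[col, k] else NA_real_
  res <- data.frame(
    term = terms$label, type = terms$type,
    estimate = vapply(terms$column, get_stat, numeric(1), 1L),
    se = vapply(terms$column, get_stat, numeric(1), 2L),
    p_raw = vapply(terms$column, get_stat, numeric(1), 4L),
    stringsAsFactors = FALSE
  )
  res$aliased <- terms$column %in% aliased_cols
  blocks <- grep("^block", rownames(cf), value = TRUE)
  extra <- data.frame(
    term = c("(Intercept)", blocks),
    type = c("intercept", rep("block", length(blocks))),
    estimate = cf[c("(Intercept)", blocks), 1],
    se = cf[c("(Intercept)", blocks), 2],
    p_raw = cf[c("(Intercept)", blocks), 4],
    aliased = FALSE, stringsAsFactors = FALSE
  )
  res <- rbind(extra, res)
  # degenerate (zero-residual) fits give NaN p-values; keep them out of BH
  fam <- res$type %in% c("main", "quadratic", "interaction") &
    !res$aliased & is.finite(res$p_raw)
  res$p_fdr <- NA_real_
  res$p_fdr[fam] <- fdr_adjust(res$p_raw[fam])
  res$logworth <- -log10(res$p_fdr)
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < 0.05
  rownames(res) <- NULL
  attr(res, "fit") <- fit
  class(res) <- c("hdde_regression", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement (order-preserving),
#' as implemented by [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric raw p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Volcano table of factor effects
#'
#' One row per non-intercept, non-block term with estimate (effect
#' strength, horizontal axis), logworth (`-log10` FDR p, vertical axis)
#' and the significance flag at FDR 0.05 (strict), sorted by logworth
#' descending. Ready for plotting.
#'
#' @param result an `hdde_regression` from [fit_quadratic()].
#' @return data.frame with `term`, `type`, `estimate`, `logworth`,
#'   `significant`.
#' @export
volcano_table <- function(result) {
  stopifnot(inherits(result, "hdde_regression"))
  v <- result[result$type %in% c("main", "quadratic", "interaction"),
              c("term", "type", "estimate", "logworth", "significant")]
  v <- v[order(-replace(v$logworth, is.na(v$logworth), -Inf)), ]
  rownames(v) <- NULL
  class(v) <- "data.frame"
  v
}

#' @export
print.hdde_regression <- function(x, ...) {
  cat("Quadratic response-surface fit:", nrow(x), "terms,",
      sum(x$significant, na.rm = TRUE), "significant at FDR 0.05\n")
  print.data.frame(utils::head(volcano_table(x), 10), digits = 4)
  invisible(x)
}
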