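#' Formulation similarity metrics
#'
#' Two ordinal metrics on equal-length formulations, computed on dose
#' *level indices* (coded ordinal steps), not real concentrations:
#' `hamming()` counts the factors whose dose level differs;
#' `levenshtein_eq()` sums the absolute dose-level differences over all
#' factors -- the Levenshtein-equivalent adaptation for equal-length,
#' multi-level sequences, where insertions/deletions are meaningless and
#' each substitution is weighted by the dose-step discrepancy. Both are
#' true metrics (identity, symmetry, triangle inequality), and
#' `hamming(a, b) <= levenshtein_eq(a, b) <= hamming(a, b) * (max levels - 1)`.
#'
#' @param a,b integer formulations of equal length.
#' @return non-negative integer distance.
#' @examples
#' hamming(c(0, 1, 2), c(1, 1, 0))        # 2
#' levenshtein_eq(c(0, 1, 2), c(1, 1, 0)) # 3
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("formulations differ in length", call. = FALSE)
  sum(as.integer(a) != as.integer(b))
}

#' @rdname hamming
#' @export
levenshtein_eq <- function(a, b) {
  if (length(a) != length(b)) stop("formulations differ in length", call. = FALSE)
  sum(abs(as.integer(a) - as.integer(b)))
}

#' Pairwise distance matrix over a set of formulations
#'
#' @param formulations list of integer formulations (>= 2), or a matrix
#'   with one formulation per row.
#' @param metric `"hamming"` or `"levenshtein_eq"`.
#' @param labels optional row labels (default: formulation keys).
#' @return an object of class `hdde_distmat`: list with the symmetric
#'   integer `matrix`, the `metric` tag and `summary` (mean and median
#'   off-diagonal distance).
#' @export
pairwise_matrix <- function(formulations, metric = c("hamming", "levenshtein_eq"),
                            labels = NULL) {
  metric <- match.arg(metric)
  if (is.matrix(formulations)) {
    formulations <- lapply(seq_len(nrow(formulations)),
                           function(i) formulations[i, ])
  }
  n <- length(formulations)
  if (n < 2) stop("need at least 2 formulations", call. = FALSE)
  fun <- if (metric == "hamming") hamming else levenshtein_eq
  m <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- fun(formulations[[i]], formulations[[j]])
    }
  }
  if (is.null(labels)) labels <- vapply(formulations, form_key, character(1))
  dimnames(m) <- list(labels, labels)
  off <- m[upper.tri(m)]
  structure(list(matrix = m, metric = metric,
                 summary = c(mean = mean(off), median = stats::median(off))),
            class = "hdde_distmat")
}

#' @export
print.hdde_distmat <- function(x, ...) {
  cat("Pairwise", x$metric, "distances over", nrow(x$matrix), "formulations:",
      "mean", format(x$summary["mean"], digits = 4),
      "| median", x$summary["median"], "\n")
  invisible(x)
}

#' Export a distance matrix as CSV
#'
#' @param dm an `hdde_distmat`.
#' @param path file path.
#' @param format `"square"` (matrix with labels) or `"long"`
#'   (`id_a,id_b,distance`, upper triangle).
#' @export
write_distmat_csv <- function(dm, path, format = c("square", "long")) {
  format <- match.arg(format)
  m <- dm$matrix
  if (format == "square") {
    utils::write.csv(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, row.names = FALSE)
  } else {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    utils::write.csv(data.frame(id_a = rownames(m)[idx[, 1]],
                                id_b = colnames(m)[idx[, 2]],
                                distance = m[idx]),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Similarity between consecutive generations
#'
#' Positionally matched per-target distance between a population and its
#' successor: how far each target moved in one generation.
#'
#' @param pop_a,pop_b populations (matrices, one formulation per row) of
#'   equal size, positionally matched.
#' @param metric `"hamming"` or `"levenshtein_eq"`.
#' @return list with `per_target` distances, `mean`, and
#'   `carried_fraction` (share of targets at distance 0).
#' @export
generation_similarity <- function(pop_a, pop_b,
                                  metric = c("hamming", "levenshtein_eq")) {
  metric <- match.arg(metric)
  if (!all(dim(pop_a) == dim(pop_b))) {
    stop("populations differ in size", call. = FALSE)
  }
  fun <- if (metric == "hamming") hamming else levenshtein_eq
  d <- vapply(seq_len(nrow(pop_a)), function(i) fun(pop_a[i, ], pop_b[i, ]),
              numeric(1))
  list(per_target = d, mean = mean(d), carried_fraction = mean(d == 0))
}
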