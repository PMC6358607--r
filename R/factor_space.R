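#' Define a culture factor with ordered dose levels
#'
#' A factor is one medium supplement (cytokine, small molecule, nutrient)
#' varied across an ordered grid of concentrations. Dose levels are
#' referenced internally by 0-based index; a zero concentration (factor
#' absent) is an ordinary grid point.
#'
#' @param name short unique identifier (e.g. `"ARG"`).
#' @param doses numeric vector of real concentrations, strictly ascending,
#'   length >= 2.
#' @param unit unit string for the concentrations (display only).
#' @return an object of class `hdde_factor`.
#' @examples
#' culture_factor("IL2", c(0, 5, 10, 20, 40), "ng/ml")
#' @export
culture_factor <- function(name, doses, unit = "") {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  doses <- as.numeric(doses)
  if (length(doses) < 2) {
    stop("factor '", name, "': at least 2 dose levels are required", call. = FALSE)
  }
  if (any(!is.finite(doses))) {
    stop("factor '", name, "': doses must be finite", call. = FALSE)
  }
  if (any(diff(doses) <= 0)) {
    stop("factor '", name, "': dose levels must be strictly ascending", call. = FALSE)
  }
  structure(
    list(name = name, doses = doses, unit = as.character(unit),
         n_levels = length(doses)),
    class = "hdde_factor"
  )
}

#' Assemble the discrete factor-dose search space
#'
#' @param factors list of [culture_factor()] objects with unique names.
#' @return an object of class `hdde_space` with elements `factors`, `D`
#'   (factor count) and `n_levels` (integer vector of levels per factor).
#' @examples
#' sp <- factor_space(list(
#'   culture_factor("A", c(0, 1, 2)),
#'   culture_factor("B", c(0, 10))
#' ))
#' sp$D
#' @export
factor_space <- function(factors) {
  stopifnot(is.list(factors), length(factors) >= 1)
  ok <- vapply(factors, inherits, logical(1), "hdde_factor")
  if (!all(ok)) stop("all elements must be culture_factor objects", call. = FALSE)
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("factor names must be unique: ", paste(nms[duplicated(nms)], collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(factors = factors, D = length(factors),
         n_levels = vapply(factors, `[[`, integer(1), "n_levels")),
    class = "hdde_space"
  )
}

#' @export
print.hdde_space <- function(x, ...) {
  cat("Discrete factor-dose space:", x$D, "factors,",
      format(total_combinations(x), big.mark = ","), "combinations\n")
  for (f in x$factors) {
    cat(sprintf("  %-10s %d levels: %s %s\n", f$name, f$n_levels,
                paste(f$doses, collapse = ", "), f$unit))
  }
  invisible(x)
}

# Convenience constructor: D factors with given level counts, unit grids.
# Doses default to 0 .. L-1 (abstract placeholder concentrations).
uniform_space <- function(n_levels, names = NULL) {
  D <- length(n_levels)
  if (is.null(names)) names <- paste0("F", seq_len(D))
  factor_space(lapply(seq_len(D), function(j) {
    culture_factor(names[j], seq(0, n_levels[j] - 1))
  }))
}

validate_formulation <- function(space, f) {
  f <- as.integer(f)
  if (length(f) != space$D) {
    stop("formulation length ", length(f), " != D = ", space$D, call. = FALSE)
  }
  if (any(is.na(f)) || any(f < 0L) || any(f >= space$n_levels)) {
    stop("invalid formulation: level index out of range", call. = FALSE)
  }
  f
}

#' Map a formulation to coded doses in [-1, 1]
#'
#' Each factor is coded independently and linearly: its lowest level maps
#' to -1 and its highest to +1, so a factor with L levels sends index k to
#' 2k/(L-1) - 1. This is the regression coding used by the post hoc
#' quadratic model.
#'
#' @param space an `hdde_space`.
#' @param f integer vector of 0-based dose-level indices (length D).
#' @return numeric vector of coded doses in \[-1, 1\].
#' @examples
#' sp <- uniform_space(c(5, 6))
#' coded_dose(sp, c(2, 1))  # 0.0, -0.6
#' @export
coded_dose <- function(space, f) {
  f <- validate_formulation(space, f)
  2 * f / (space$n_levels - 1) - 1
}

# Inverse of coded_dose (exact for on-grid codes).
decode_dose <- function(space, x) {
  stopifnot(length(x) == space$D)
  as.integer(round((x + 1) * (space$n_levels - 1) / 2))
}

#' Total number of formulations in a space
#'
#' Product of per-factor level counts. Returned as a double; because the
#' product can exceed the 2^53 exact-integer range of doubles for large
#' spaces, the exact value is also attached as a decimal string in
#' attribute `"exact"`.
#'
#' @param space an `hdde_space`.
#' @return double count with attribute `exact` (character).
#' @examples
#' total_combinations(uniform_space(rep(6, 15)))  # 6^15
#' @export
total_combinations <- function(space) {
  out <- prod(as.numeric(space$n_levels))
  attr(out, "exact") <- .exact_product(space$n_levels)
  out
}

# Exact product of small positive integers as a decimal string
# (schoolbook multiply on a base-10 digit vector, least significant first).
.exact_product <- function(ints) {
  digits <- c(1L)
  for (m in as.integer(ints)) {
    carry <- 0L
    for (i in seq_along(digits)) {
      v <- digits[i] * m + carry
      digits[i] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(digits), collapse = "")
}

#' Draw a uniform random formulation
#'
#' Each factor's level index is drawn independently and uniformly over its
#' grid, using the supplied stream.
#'
#' @param space an `hdde_space`.
#' @param rng an [rng_new()] stream.
#' @return integer vector of 0-based level indices.
#' @export
random_formulation <- function(space, rng) {
  with_rng(rng, {
    vapply(space$n_levels, function(L) sample.int(L, 1L) - 1L, integer(1))
  })
}

form_key <- function(f) paste(as.integer(f), collapse = "-")

key_to_form <- function(key) as.integer(strsplit(key, "-", fixed = TRUE)[[1]])

#' Read / write a factor-space configuration file
#'
#' The YAML layout is a list of factors, each with `name`, `unit` and an
#' explicit `doses` list; it round-trips losslessly.
#'
#' @param path file path.
#' @param space an `hdde_space` (for writing).
#' @return `read_factor_space()` returns an `hdde_space`.
#' @export
read_factor_space <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$factors)) cfg <- cfg$factors
  factor_space(lapply(cfg, function(fc) {
    culture_factor(fc$name, as.numeric(fc$doses),
                   if (is.null(fc$unit)) "" else fc$unit)
  }))
}

#' @rdname read_factor_space
#' @export
write_factor_space <- function(space, path) {
  yaml::write_yaml(list(factors = lapply(space$factors, function(f) {
    list(name = f$name, unit = f$unit, doses = as.list(f$doses))
  })), path)
  invisible(path)
}
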