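# Shared fixtures and independent oracles (kept deliberately naive).

space_2f <- function() {
  factor_space(list(
    culture_factor("A", c(0, 1, 2, 4, 8, 16), "ng/ml"),
    culture_factor("B", c(0, 5, 10, 20, 40), "uM")
  ))
}

space_uniform <- function(n_levels, names = NULL) {
  hdde:::uniform_space(n_levels, names)
}

# Exhaustive one-sided rank-sum p-value: probability, over all equally
# likely assignments of the pooled ranks to the two groups, that the
# trial group's rank sum is at least as large as observed.
ranksum_p_enum <- function(target, trial) {
  pooled <- c(target, trial)
  n <- length(target)
  m <- length(trial)
  r <- rank(pooled)
  obs <- sum(r[(n + 1):(n + m)])
  combs <- utils::combn(n + m, m)
  stats <- colSums(matrix(r[combs], nrow = m))
  mean(stats >= obs)
}

# Oracle selection decision built only on the enumeration above.
select_oracle <- function(target, trial, alpha) {
  if (!(stats::median(trial) > stats::median(target))) return("target")
  if (ranksum_p_enum(target, trial) < alpha) "trial" else "target"
}

# Brute-force Rosenbrock extrema by full grid enumeration.
rosen_extrema_brute <- function(grids) {
  pts <- as.matrix(expand.grid(grids))
  vals <- apply(pts, 1, rosenbrock)
  list(f_min = min(vals), f_max = max(vals))
}

# Deterministic landscape with one dominant optimum at the all-top corner.
dominant_landscape <- function(space, sigma = 0, seed = 1) {
  cell_landscape(space, K = 10,
                 mains = seq(1, 0.5, length.out = space$D),
                 quads = rep(0, space$D), sigma = sigma, seed = seed)
}

# True log-response argmax by full enumeration (small spaces only).
grid_argmax_mu <- function(landscape) {
  space <- landscape$space
  grid <- as.matrix(expand.grid(lapply(space$n_levels, function(L) 0:(L - 1))))
  mu <- apply(grid, 1, function(f) hdde:::cell_log_mu(landscape, as.integer(f)))
  as.integer(grid[which.max(mu), ])
}

candidate_levels <- function(run) {
  L <- grep("^L_", names(run$candidates))
  lapply(seq_len(nrow(run$candidates)),
         function(i) as.integer(run$candidates[i, L]))
}
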