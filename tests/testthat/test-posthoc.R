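# Small full-factorial library on a known landscape, all rows in generation 2.
factorial_library <- function(space, landscape, pc = exp(11)) {
  lib <- eval_library()
  grid <- expand.grid(lapply(space$n_levels, function(L) 0:(L - 1)))
  for (i in seq_len(nrow(grid))) {
    f <- as.integer(grid[i, ])
    out <- synth_response(f, landscape, generation = 2, n_replicates = 1)
    lib_add(lib, f, out$values, 2, out$censored)
  }
  lib_add_pc(lib, pc, 2)
  library_frame(lib, space)
}

known_landscape <- function(space) {
  inters <- matrix(0, 3, 3)
  inters[1, 2] <- 0.25
  inters[1, 3] <- -0.15
  inters[2, 3] <- 0.05
  cell_landscape(space, K = 10, mains = c(0.5, -0.3, 0.2),
                 quads = c(-0.2, 0.1, 0), inters = inters, sigma = 0, seed = 1)
}

test_that("uncensored data pass through imputation unchanged", {
  x <- c(1, 2, 3)
  expect_identical(impute_censored(x, c(FALSE, FALSE, FALSE), 5), x)
})

test_that("imputed values respect the truncation bound and recover the normal", {
  r <- rng_new(5)
  x <- with_rng(r, rnorm(2000, 5, 1))
  thr <- exp(unname(quantile(x, 0.2)))
  cens <- x < log(thr)
  obs <- ifelse(cens, log(thr), x)
  out <- impute_censored(obs, cens, thr, rng = r)
  expect_true(all(out[cens] < log(thr)))
  fit <- attr(out, "fit")
  expect_lt(abs(fit["mu"] - 5), 0.1)
  # deterministic variant is reproducible and also truncated
  out2 <- impute_censored(obs, cens, thr, deterministic = TRUE)
  expect_identical(out2, impute_censored(obs, cens, thr, deterministic = TRUE))
  expect_true(all(out2[cens] < log(thr)))
  expect_error(impute_censored(obs, rep(TRUE, length(obs)), thr, r), "all")
})

test_that("the design table has the full quadratic term set and drops generation 1", {
  sp <- space_uniform(c(3, 3), names = c("A", "B"))
  ls <- cell_landscape(sp, K = 8, sigma = 0)
  lib <- eval_library()
  lib_add(lib, c(0L, 0L), exp(8), 1)           # generation 1: excluded
  lib_add(lib, c(1L, 2L), rep(exp(8), 3), 2)
  lib_add(lib, c(2L, 0L), rep(exp(8), 2), 3)
  lib_add_pc(lib, exp(8), 1); lib_add_pc(lib, exp(8), 2); lib_add_pc(lib, exp(8), 3)
  des <- build_design(library_frame(lib, sp), sp)
  expect_equal(nrow(des), 5)  # 3 + 2 replicates, generation 1 gone
  tm <- attr(des, "terms")
  expect_equal(table(tm$type)[["main"]], 2)
  expect_equal(table(tm$type)[["quadratic"]], 2)
  expect_equal(table(tm$type)[["interaction"]], 1)
  # a coded dose of 0 zeroes its square and product columns
  mid <- des[des$M_A == 0, ]
  expect_true(all(mid$Q_A == 0 & mid$I_A_B == 0))
})

test_that("noise-free factorial data return the generating coefficients to 1e-8", {
  sp <- space_uniform(c(3, 3, 3), names = c("A", "B", "C"))
  ls <- known_landscape(sp)
  df <- factorial_library(sp, ls)
  res <- suppressWarnings(fit_quadratic(build_design(df, sp)))
  truth <- c("(Intercept)" = 10, A = 0.5, B = -0.3, C = 0.2,
             "A^2" = -0.2, "B^2" = 0.1, "C^2" = 0,
             "A*B" = 0.25, "A*C" = -0.15, "B*C" = 0.05)
  est <- res$estimate[match(names(truth), res$term)]
  expect_true(all(abs(est - truth) < 1e-8))
  # row order never matters for OLS
  df2 <- df[rev(seq_len(nrow(df))), ]
  res2 <- suppressWarnings(fit_quadratic(build_design(df2, sp)))
  expect_equal(sort(res2$estimate), sort(res$estimate), tolerance = 1e-10)
})

test_that("constant responses yield zero effects and no significance", {
  sp <- space_uniform(c(3, 3), names = c("A", "B"))
  flat <- cell_landscape(sp, K = 7, sigma = 0)
  df <- factorial_library(sp, flat)
  res <- suppressWarnings(fit_quadratic(build_design(df, sp)))
  eff <- res[res$type != "intercept", ]
  expect_true(all(abs(eff$estimate) < 1e-10))
  expect_false(any(eff$significant))
})

test_that("BH adjustment follows the step-up formula and preserves order", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.002, 0.5, 0.04, 0.9, 0.011)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_identical(order(adj[order(p)]), seq_along(p))  # monotone in sorted order
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the volcano table covers all factor-effect terms with strict significance", {
  sp <- space_uniform(c(3, 3, 3), names = c("A", "B", "C"))
  df <- factorial_library(sp, known_landscape(sp))
  res <- suppressWarnings(fit_quadratic(build_design(df, sp)))
  v <- volcano_table(res)
  D <- 3
  expect_equal(nrow(v), D + D + D * (D - 1) / 2)
  expect_false("(Intercept)" %in% v$term)
  # logworth is -log10 of the adjusted p; significance is strict at 0.05
  fake <- structure(
    data.frame(term = c("x", "y"), type = "main", estimate = c(1, -1),
               se = 1, p_raw = c(0.001, 0.05), aliased = FALSE,
               p_fdr = c(0.001, 0.05),
               logworth = -log10(c(0.001, 0.05)),
               significant = c(0.001, 0.05) < 0.05),
    class = c("hdde_regression", "data.frame"))
  fv <- volcano_table(fake)
  expect_equal(fv$logworth[fv$term == "x"], 3)
  expect_false(fv$significant[fv$term == "y"])
})
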