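test_that("hamming counts differing factors; dose-step distance sums discrepancies", {
  expect_equal(hamming(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(hamming(c(0, 1, 2), c(1, 1, 0)), 2)
  expect_equal(levenshtein_eq(c(0, 1, 2), c(1, 1, 0)), 3)
  expect_error(hamming(c(0, 1), c(0, 1, 2)), "length")
  expect_error(levenshtein_eq(c(0, 1), c(0)), "length")
})

test_that("metrics match independent re-counts and satisfy metric axioms", {
  sp <- space_uniform(rep(5, 4))
  r <- rng_new(23)
  for (i in 1:100) {
    a <- random_formulation(sp, r)
    b <- random_formulation(sp, r)
    c <- random_formulation(sp, r)
    # independent positional re-count
    expect_equal(hamming(a, b), sum(vapply(1:4, function(j) a[j] != b[j],
                                           logical(1))))
    expect_equal(levenshtein_eq(a, b),
                 sum(vapply(1:4, function(j) abs(a[j] - b[j]), numeric(1))))
    # bounds: hamming <= dose-steps <= hamming * (levels - 1)
    expect_lte(hamming(a, b), levenshtein_eq(a, b))
    expect_lte(levenshtein_eq(a, b), hamming(a, b) * 4)
    # triangle inequality for both metrics
    expect_lte(hamming(a, c), hamming(a, b) + hamming(b, c))
    expect_lte(levenshtein_eq(a, c), levenshtein_eq(a, b) + levenshtein_eq(b, c))
    # equality of the two metrics iff all differences are single steps
    if (all(abs(a - b) <= 1)) expect_equal(hamming(a, b), levenshtein_eq(a, b))
  }
})

test_that("pairwise matrices are symmetric with zero diagonal and correct summaries", {
  same <- list(c(0L, 0L, 0L), c(0L, 0L, 0L))
  dm0 <- pairwise_matrix(same, "hamming")
  expect_true(all(dm0$matrix == 0))
  # chain of single-step changes: pairwise hammings 1, 1, 2 -> mean 4/3
  chain <- list(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L))
  dm <- pairwise_matrix(chain, "hamming")
  expect_identical(dm$matrix, t(dm$matrix))
  expect_true(all(diag(dm$matrix) == 0))
  expect_equal(unname(dm$summary["mean"]), 4 / 3)
  expect_equal(unname(dm$summary["median"]), 1)
})

test_that("generation similarity reports movement and carried fraction", {
  pop <- rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L))
  gs <- generation_similarity(pop, pop)
  expect_equal(gs$mean, 0)
  expect_equal(gs$carried_fraction, 1.0)
  pop2 <- pop
  pop2[2, 1] <- 2L
  gs2 <- generation_similarity(pop, pop2, "levenshtein_eq")
  expect_equal(gs2$carried_fraction, 2 / 3)
  expect_equal(gs2$per_target, c(0, 1, 0))
  expect_error(generation_similarity(pop, pop2[1:2, ]), "size")
})

test_that("carried fraction agrees with the engine's own carried-over count", {
  sp <- space_uniform(rep(4, 4))
  ev <- random_cell_landscape(sp, n_strong_mains = 2L, n_inters = 2L, seed = 41)
  cfg <- engine_config(seed = 6, max_generations = 3)
  state <- engine_init(sp, cfg)
  res <- evaluate_batch(ev, engine_pending(state)$formulations, 3, 1)
  names(res$responses) <- vapply(engine_pending(state)$formulations,
                                 hdde:::form_key, character(1))
  state <- engine_ingest(state, res$responses, res$pc, NULL)
  state <- engine_propose(state)
  pend <- engine_pending(state)
  res <- evaluate_batch(ev, pend$formulations, 3, 2)
  names(res$responses) <- vapply(pend$formulations, hdde:::form_key, character(1))
  before <- state$population
  state <- engine_ingest(state, res$responses, res$pc, NULL)
  gs <- generation_similarity(before, state$population)
  expect_equal(gs$carried_fraction * state$NP,
               state$trace$n_carried[state$trace$generation == 2])
})
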