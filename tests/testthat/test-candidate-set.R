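test_that("competition against best admits freely below capacity", {
  cs <- candidate_set(cap = 3)
  cs <- compete_best(cs, c(0L, 0L), 0.5)
  expect_equal(length(cs$keys), 1)
  cs <- compete_best(cs, c(1L, 0L), 0.4)
  cs <- compete_best(cs, c(0L, 1L), 0.9)
  expect_equal(sort(cs$scores), c(0.4, 0.5, 0.9))
})

test_that("at capacity, entry needs a margin over the weakest member", {
  cs <- candidate_set(cap = 1)
  cs <- compete_best(cs, c(0L), 0.80)
  # pooled SD 0.04, margin 1: 0.83 is within noise, 0.90 is not
  cs1 <- compete_best(cs, c(1L), 0.83, sd_hat = 0.04, margin = 1)
  expect_identical(cs1$keys, cs$keys)
  cs2 <- compete_best(cs, c(1L), 0.90, sd_hat = 0.04, margin = 1)
  expect_identical(cs2$keys, "1")
  expect_equal(cs2$scores, 0.90)
  # strictly worse candidates never alter the set
  cs3 <- compete_best(cs, c(2L), 0.10, sd_hat = 0.04)
  expect_identical(cs3$keys, cs$keys)
  # without repeat measurements the 0.05 fallback applies
  cs4 <- compete_best(cs, c(1L), 0.84, sd_hat = NA_real_, margin = 1)
  expect_identical(cs4$keys, cs$keys)
  cs5 <- compete_best(cs, c(1L), 0.86, sd_hat = NA_real_, margin = 1)
  expect_identical(cs5$keys, "1")
})

test_that("clearing removes members outside the 10% score range and refills", {
  sp <- space_uniform(c(3, 3))
  cs <- candidate_set(cap = 10)
  cs <- compete_best(cs, c(0L, 0L), 1.00)
  cs <- compete_best(cs, c(1L, 0L), 0.95)
  cs <- compete_best(cs, c(2L, 0L), 0.85)
  res <- clearing(cs, sp, rng_new(1), fraction = 0.10)
  expect_identical(res$cleared_keys, "2-0")  # 0.85 < 0.90
  expect_equal(length(res$cset$keys), 2)
  expect_equal(length(res$replacements), 1)
  expect_true(all(res$cset$scores >= 0.9 * max(res$cset$scores)))
  # equal scores: nothing cleared
  cs2 <- candidate_set(cap = 10)
  for (k in 0:2) cs2 <- compete_best(cs2, c(k, 1L), 0.7)
  res2 <- clearing(cs2, sp, rng_new(1), fraction = 0.10)
  expect_length(res2$cleared_keys, 0)
  expect_length(res2$replacements, 0)
})

test_that("root perturbation enumerates single-step neighbours and samples one", {
  sp1 <- space_uniform(2)
  expect_identical(perturb_root(0L, sp1, rng_new(1)), 1L)
  sp <- space_uniform(c(3, 3))
  pool <- hdde:::perturb_pool(c(1L, 1L), sp)
  expect_equal(length(pool), 4)
  expect_setequal(vapply(pool, paste, character(1), collapse = ","),
                  c("0,1", "2,1", "1,0", "1,2"))
  # every draw is at dose-step distance exactly 1 from the root
  r <- rng_new(5)
  for (i in 1:50) {
    root <- random_formulation(sp, r)
    nb <- perturb_root(root, sp, r)
    expect_equal(levenshtein_eq(root, nb), 1)
  }
})
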