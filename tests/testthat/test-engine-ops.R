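test_that("population sizing follows the 3 x D + extra rule", {
  expect_identical(population_size(15), 45L)
  expect_identical(population_size(14, 17), 59L)
  expect_identical(population_size(1), 3L)
})

test_that("rand/1 mutation combines three distinct non-target donors", {
  # rows 2..4 identical: r2 - r3 vanishes whenever both land there
  pop <- rbind(c(9L, 9L), c(2L, 3L), c(2L, 3L), c(2L, 3L))
  d <- hdde:::de_mutate(1L, pop, F = 1, rng_new(1))
  expect_equal(d, c(2, 3))  # x_r1 + 1 * 0
  d2 <- hdde:::de_mutate(1L, pop, F = 7.5, rng_new(2))
  expect_equal(d2, c(2, 3))  # zero difference vector for any F
  # F = 0 reduces to a copy of some non-target member
  pop2 <- rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(3L, 3L))
  d3 <- hdde:::de_mutate(1L, pop2, F = 0, rng_new(3))
  expect_true(any(apply(pop2[-1, ], 1, function(r) all(r == d3))))
  expect_error(hdde:::de_mutate(1L, pop2[1:3, ], 1, rng_new(1)), "at least 4")
})

test_that("binomial crossover takes the donor with rate CR plus one forced position", {
  target <- rep(0, 15)
  donor <- rep(1, 15)
  expect_equal(hdde:::de_crossover(target, donor, CR = 1, rng_new(1)), donor)
  t0 <- hdde:::de_crossover(target, donor, CR = 0, rng_new(1))
  expect_equal(sum(t0 == 1), 1)  # only the forced position
  # expectation check: 1 + CR * (D - 1) donor positions on average
  r <- rng_new(11)
  counts <- vapply(1:2000, function(i) {
    sum(hdde:::de_crossover(target, donor, CR = 0.5, r) == 1)
  }, numeric(1))
  se <- sqrt(14 * 0.25 / 2000)
  expect_lt(abs(mean(counts) - (1 + 0.5 * 14)), 3 * se)
})

test_that("quantization rounds half away from zero and clips to the grid", {
  sp <- space_uniform(c(6, 6))
  expect_identical(quantize(sp, c(5.0, 2.0)), c(5L, 2L))
  expect_identical(quantize(sp, c(7.4, -1.2)), c(5L, 0L))
  expect_identical(quantize(space_uniform(6), 2.5), 3L)
  expect_error(quantize(sp, c(NaN, 1)), "non-finite")
})

test_that("normalized score is the mean response over the PC mean", {
  expect_equal(normalized_score(c(100, 110, 90), c(100, 110, 90)), 1.0)
  expect_equal(normalized_score(c(0, 0, 0), c(100, 110, 90)), 0.0)
  expect_equal(normalized_score(c(50, 60, 70), c(100, 100, 100)), 0.6)
  expect_error(normalized_score(c(1, 2), c(0, 0)), "must be > 0")
  expect_error(normalized_score(numeric(0), c(1)), "empty")
})

test_that("rank-sum selection promotes only clearly better trials", {
  expect_identical(select_winner(c(10, 11, 12), c(10, 11, 12)), "target")
  # complete separation: exact one-sided p = 1/choose(6,3) = 0.05 < 0.10
  expect_identical(select_winner(c(10, 11, 12), c(30, 31, 32), 0.10), "trial")
  # interleaved ranks: not significant, incumbent retained
  expect_identical(select_winner(c(10, 30, 12), c(11, 31, 13), 0.10), "target")
  # lower-median trials never win regardless of alpha
  expect_identical(select_winner(c(30, 31, 32), c(10, 11, 12), 0.99), "target")
  expect_error(select_winner(c(1), c(2, 3)), "2 replicates")
})

test_that("selection decisions match the exhaustive rank-enumeration oracle", {
  r <- rng_new(19)
  for (n in c(3, 4)) {
    for (i in 1:25) {
      target <- with_rng(r, round(runif(n, 0, 100), 3))
      trial <- with_rng(r, round(runif(n, 0, 100), 3))
      expect_identical(select_winner(target, trial, 0.10),
                       select_oracle(target, trial, 0.10),
                       info = paste("n =", n, "case", i))
    }
  }
})

test_that("convergence detection compares relative best-score steps to tol", {
  expect_false(detect_convergence(c(0.5, 0.9, 1.3), tol = 0.05, window = 2))
  expect_true(detect_convergence(c(1.00, 1.01, 1.005), tol = 0.05, window = 2))
  expect_true(detect_convergence(rep(0.7, 5), tol = 0.05, window = 2))
  expect_false(detect_convergence(c(1.0, 1.0), tol = 0.05, window = 2))  # short
})
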