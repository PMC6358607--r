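test_that("Rosenbrock values match hand arithmetic", {
  expect_equal(rosenbrock(rep(1, 15)), 0)
  expect_equal(rosenbrock(rep(0, 15)), 14)  # 14 terms of (1 - 0)^2
  expect_equal(rosenbrock(c(-1, 1)), 4)
  expect_error(rosenbrock(1), "at least 2")
})

test_that("chain-DP grid extrema match brute-force enumeration", {
  r <- rng_new(13)
  for (i in 1:8) {
    D <- with_rng(r, sample(3:5, 1))
    levels <- with_rng(r, sample(3:6, D, replace = TRUE))
    lo <- with_rng(r, runif(1, -3, -1))
    hi <- with_rng(r, runif(1, 1, 3))
    sp <- space_uniform(levels)
    bl <- benchmark_landscape(sp, lower = lo, upper = hi, noise_sd = 0, seed = i)
    brute <- rosen_extrema_brute(bl$grids)
    expect_equal(bl$extrema$f_min, brute$f_min)
    expect_equal(bl$extrema$f_max, brute$f_max)
  }
})

test_that("5-level [-2,2] grids contain the continuous optimum at all-ones", {
  sp <- space_uniform(rep(5, 15))
  bl <- benchmark_landscape(sp, seed = 1)
  expect_equal(bl$extrema$f_min, 0)
  expect_identical(bl$extrema$argmin, rep(3L, 15))  # coordinate 1 is index 3
})

test_that("benchmark scores are min-max normalized with PC == 1 at the optimum", {
  sp <- space_uniform(rep(5, 4))
  bl <- benchmark_landscape(sp, noise_sd = 0, seed = 2)
  expect_equal(benchmark_true_score(bl, bl$extrema$argmin), 1.0)
  expect_equal(benchmark_true_score(bl, bl$extrema$argmax), 0.0)
  expect_equal(benchmark_response(bl$extrema$argmin, bl, 3), rep(1, 3))
  # replicate noise has the configured SD
  bl2 <- benchmark_landscape(sp, noise_sd = 0.05, seed = 3)
  reps <- benchmark_response(rep(2L, 4), bl2, 10000)
  expect_gt(sd(reps), 0.045)
  expect_lt(sd(reps), 0.055)
})

test_that("synthetic counts follow the generative quadratic model exactly at sigma = 0", {
  sp1 <- space_uniform(c(5, 5))
  flat <- cell_landscape(sp1, K = 3, sigma = 0)
  expect_equal(synth_response(c(2L, 2L), flat, 1, 4)$values, rep(exp(3), 4))
  # single main effect: coded +1 vs -1 gives a count ratio of e^2
  sp2 <- space_uniform(c(2, 2))
  ls <- cell_landscape(sp2, K = 0, mains = c(1, 0), sigma = 0,
                       detection_threshold = 0)
  hi <- synth_response(c(1L, 0L), ls, 1, 1)$values
  lo <- synth_response(c(0L, 0L), ls, 1, 1)$values
  expect_equal(hi / lo, exp(2))
  # generation blocks shift the log response
  ls2 <- cell_landscape(sp2, K = 1, blocks = c(0, 0.5), sigma = 0,
                        detection_threshold = 0)
  expect_equal(synth_response(c(0L, 0L), ls2, 2, 1)$values /
                 synth_response(c(0L, 0L), ls2, 1, 1)$values, exp(0.5))
})

test_that("counts below the detection threshold are reported censored at it", {
  sp <- space_uniform(c(3, 3))
  ls <- cell_landscape(sp, K = 2, sigma = 0, detection_threshold = exp(5))
  out <- synth_response(c(1L, 1L), ls, 1, 3)
  expect_true(all(out$censored))
  expect_equal(out$values, rep(exp(5), 3))
})

test_that("landscape coefficient CSV round-trips to identical responses", {
  sp <- space_uniform(c(4, 3, 5), names = c("ARG", "IL2", "GLU"))
  ls <- random_cell_landscape(sp, seed = 17)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape_csv(ls, path)
  ls2 <- read_landscape_csv(path, sp, seed = 99)
  expect_equal(ls2$mains, ls$mains)
  expect_equal(ls2$quads, ls$quads)
  expect_equal(ls2$inters, ls$inters)
  expect_equal(ls2$K, ls$K)
  expect_equal(ls2$sigma, ls$sigma)
  f <- c(1L, 2L, 0L)
  expect_equal(hdde:::cell_log_mu(ls2, f), hdde:::cell_log_mu(ls, f))
})
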