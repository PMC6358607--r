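test_that("seeded runs are exactly reproducible", {
  sp <- space_uniform(c(4, 4, 4))
  cfg <- engine_config(seed = 3, max_generations = 5)
  r1 <- hdde_run(sp, cell_landscape(sp, mains = c(0.4, -0.2, 0.1), seed = 9), cfg)
  r2 <- hdde_run(sp, cell_landscape(sp, mains = c(0.4, -0.2, 0.1), seed = 9), cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$library, r2$library)
  expect_identical(r1$candidates, r2$candidates)
})

test_that("population size, unique-count bound and F/CR schedule invariants hold", {
  sp <- space_uniform(rep(4, 5))
  cfg <- engine_config(seed = 2, max_generations = 8)
  ev <- random_cell_landscape(sp, n_strong_mains = 2L, n_inters = 3L, seed = 21)
  run <- hdde_run(sp, ev, cfg)
  NP <- population_size(sp$D)
  expect_true(all(dim(run$state$population) == c(NP, sp$D)))
  tr <- run$trace
  gens <- nrow(tr)
  expect_true(all(diff(tr$unique_count) >= 0))
  expect_lte(max(tr$unique_count), NP * (gens + 1))
  expect_true(all(tr$F %in% c(cfg$F_init, cfg$F_reduced)))
  expect_true(all(tr$CR %in% c(cfg$CR_init, cfg$CR_reduced)))
  expect_true(all(diff(tr$F) <= 0))
  expect_true(all(diff(tr$CR) <= 0))
  # CR never drops before F does
  expect_true(all(tr$F[tr$CR == cfg$CR_reduced] == cfg$F_reduced))
  late <- tr[-1, ]
  expect_true(all(late$n_improved + late$n_carried <= NP))
  # library replicate rows appear only for distinct formulations
  lib <- run$library[!run$library$is_control, ]
  expect_equal(length(unique(lib$key)), utils::tail(tr$unique_count, 1))
})

test_that("with a noiseless evaluator and permissive alpha the best score never decreases", {
  sp <- space_uniform(rep(3, 4))
  ev <- dominant_landscape(sp, sigma = 0)
  cfg <- engine_config(seed = 4, alpha = 0.99, max_generations = 10,
                       carried_termination = FALSE)
  run <- hdde_run(sp, ev, cfg)
  expect_true(all(diff(run$trace$best_score) >= -1e-12))
})

test_that("the engine finds the enumerated grid optimum on small noiseless landscapes", {
  sp <- space_uniform(rep(3, 3))
  hits <- 0
  for (s in 1:10) {
    ev <- dominant_landscape(sp, sigma = 0, seed = s)
    truth <- grid_argmax_mu(ev)
    run <- hdde_run(sp, ev, engine_config(seed = s, alpha = 0.99,
                                          max_generations = 15))
    found <- candidate_levels(run)[[which.max(run$candidates$score)]]
    if (identical(found, truth)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("termination by carried-over streak fires only after the F reduction", {
  sp <- space_uniform(rep(6, 8))
  ev <- random_cell_landscape(sp, seed = 31)
  run <- hdde_run(sp, ev, engine_config(seed = 5))
  if (run$reason == "converged") {
    tr <- run$trace
    fgen <- min(tr$generation[tr$F == 0.5])
    expect_gte(nrow(tr), fgen + 2)
    last <- utils::tail(tr$n_carried, 2)
    expect_true(all(last >= ceiling(0.9 * population_size(sp$D))))
  } else {
    expect_identical(run$reason, "max_generations")
  }
})

test_that("trial formulations already in the library are reused, not re-measured", {
  sp <- space_uniform(c(3, 3))
  ev <- dominant_landscape(sp, sigma = 0)
  run <- hdde_run(sp, ev, engine_config(seed = 8, max_generations = 6,
                                        alpha = 0.99))
  lib <- run$library[!run$library$is_control, ]
  per_form <- table(lib$key)
  # every distinct formulation was measured in exactly one generation
  gens_per_form <- tapply(lib$generation, lib$key,
                          function(g) length(unique(g)))
  expect_true(all(gens_per_form == 1))
  expect_true(all(per_form == 3))
})
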