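test_that("population initialisation fills the box", {
  sp <- search_space(c(-2, 0), c(1, 5))
  set.seed(1)
  pop <- init_population(sp, 40)
  expect_true(all(sweep(pop, 2, sp$lb, ">=")))
  expect_true(all(sweep(pop, 2, sp$ub, "<=")))
  expect_equal(init_population(sp, 3, r = matrix(0, 3, 2)),
               matrix(sp$lb, 3, 2, byrow = TRUE))
  expect_equal(init_population(sp, 3, r = matrix(1, 3, 2)),
               matrix(sp$ub, 3, 2, byrow = TRUE))
  expect_error(search_space(c(1, 1), c(1, 2)), "strictly below")
})

test_that("smell intensity obeys the inverse-square law", {
  expect_equal(smell_intensity(0, 1, 2, r2 = 0), 0)
  expect_equal(smell_intensity(0, 1, 2, r2 = 1), 1 / (16 * pi),
               tolerance = 1e-9)
  near <- smell_intensity(0, 1, 1, r2 = 1)
  far <- smell_intensity(0, 1, 2, r2 = 1)
  expect_equal(near / far, 4, tolerance = 1e-9)
  # epsilon guard keeps zero distance finite
  expect_true(is.finite(smell_intensity(1, 2, 1, r2 = 1)))
  expect_error(smell_intensity(c(0, 0), 1, 2), "equal length")
})

test_that("density factor follows the exponential schedule", {
  expect_equal(density_factor(1, Inf), 2, tolerance = 1e-12)
  expect_equal(density_factor(300, 300), 2 * exp(-1), tolerance = 1e-12)
  expect_equal(density_factor(10, 50, C = 3), 3 * exp(-0.2))
  alphas <- vapply(1:50, density_factor, numeric(1), tmax = 50)
  expect_true(all(diff(alphas) < 0))
  expect_error(density_factor(0, 10), "1 <= t")
  expect_error(density_factor(11, 10), "1 <= t")
})

test_that("a degenerate collapsed population leaves the prey fixed", {
  sp <- search_space(-5, 5, dim = 3)
  prey <- rep(1.5, 3)
  pop <- matrix(1.5, 6, 3)  # everyone on the prey: d = 0, S = 0, I ~ 0
  set.seed(2)
  st <- hba_step(pop, rep(2.25 * 3, 6), sphere, prey, sphere(prey),
                 alpha = 0, space = sp, config = hba_config(pop_size = 6))
  expect_equal(st$positions, pop, tolerance = 1e-9)
  expect_equal(st$prey, prey, tolerance = 1e-9)
})

test_that("hba_step is greedy and respects the bounds", {
  sp <- search_space(-1, 1, dim = 4)
  set.seed(3)
  pop <- init_population(sp, 8)
  fit <- apply(pop, 1, sphere)
  best <- which.min(fit)
  for (rep in 1:20) {
    st <- hba_step(pop, fit, sphere, pop[best, ], fit[best],
                   alpha = 1.5, space = sp, config = hba_config(pop_size = 8))
    expect_true(all(st$fitnesses <= fit))       # a worse proposal never lands
    expect_true(all(st$positions >= -1 & st$positions <= 1))
    pop <- st$positions; fit <- st$fitnesses
  }
})

test_that("t-mutation is multiplicative, seeded and df-correct", {
  expect_equal(t_mutation(rep(0, 5), 3), rep(0, 5))  # fixed point at zero
  set.seed(4); m1 <- t_mutation(1:4, 2)
  set.seed(4); m2 <- t_mutation(1:4, 2)
  expect_identical(m1, m2)
  expect_error(t_mutation(1:3, 0), ">= 1")

  # at df = 1000 the draws are indistinguishable from standard normal
  set.seed(123)
  draws <- t_mutation(rep(1, 10000), 1000) - 1
  expect_gt(stats::ks.test(draws, "pnorm")$p.value, 0.01)
})

test_that("mutation df equals the iteration number (injected generator spy)", {
  seen_df <- integer(0)
  spy <- function(n, df) {
    seen_df <<- c(seen_df, rep(df, n))
    stats::rt(n, df)
  }
  sp <- search_space(-5, 5, dim = 2)
  cfg <- thba_config(pop_size = 4, max_iter = 5, mutation_prob = 1,
                     mutation_rdist = spy, seed = 10)
  thba_optimize(sphere, sp, cfg)
  # P = 1: every agent mutates every iteration, one df-draw per dimension,
  # and the df passed at iteration t is t
  expect_identical(seen_df, rep(1:5, each = 4 * 2))
})

test_that("HBA bookkeeping: history, bounds and evaluation counts", {
  sp <- search_space(-5, 5, dim = 5)
  for (s in 1:3) {
    run <- hba_optimize(sphere, sp, hba_config(pop_size = 12, max_iter = 40,
                                               seed = s))
    expect_true(all(diff(run$history) <= 0))
    expect_equal(run$best_fitness, run$history[length(run$history)])
    expect_true(all(run$best_position >= -5 & run$best_position <= 5))
    expect_identical(run$n_evaluations, 12L * (1L + 40L))
    expect_identical(run$n_mutation_evals, 0L)
  }
  one <- hba_optimize(sphere, sp, hba_config(pop_size = 5, max_iter = 1,
                                             seed = 1))
  expect_length(one$history, 1L)
  expect_identical(one$n_evaluations, 10L)  # init + one improvement round
  expect_error(hba_optimize(function(x) NaN, sp,
                            hba_config(pop_size = 4, max_iter = 2, seed = 1)),
               "non-finite fitness")
})

test_that("tHBA with P = 0 reduces exactly to HBA", {
  sp <- search_space(-5, 5, dim = 4)
  h <- hba_optimize(sphere, sp, hba_config(pop_size = 10, max_iter = 25,
                                           seed = 7))
  t0 <- thba_optimize(sphere, sp, thba_config(pop_size = 10, max_iter = 25,
                                              mutation_prob = 0, seed = 7))
  expect_identical(h$history, t0$history)
  expect_identical(h$best_position, t0$best_position)
  expect_identical(h$n_evaluations, t0$n_evaluations)
})

test_that("tHBA accounts for mutation evaluations exactly", {
  sp <- search_space(-5, 5, dim = 3)
  run <- thba_optimize(sphere, sp, thba_config(pop_size = 8, max_iter = 20,
                                               mutation_prob = 0.8, seed = 2))
  expect_identical(run$n_evaluations, 8L * 21L + run$n_mutation_evals)
  expect_true(all(diff(run$history) <= 0))
  expect_equal(run$evals_history[length(run$evals_history)],
               run$n_evaluations)
})

test_that("the GA baseline is elitist with a non-increasing history", {
  sp <- search_space(-5, 5, dim = 5)
  run <- ga_optimize(sphere, sp, ga_config(pop_size = 20, max_iter = 60,
                                           seed = 3))
  expect_true(all(diff(run$history) <= 0))
  expect_equal(run$best_fitness, run$history[length(run$history)])
  expect_lt(run$best_fitness, 0.5)
  expect_identical(run$n_evaluations, 20L + 19L * 60L)
})
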