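test_that("population initialization respects bounds, size and seed", {
  b <- cbind(rep(0, 3), rep(0.1, 3))
  set.seed(11)
  p1 <- de_init_population(b, 105)
  expect_equal(dim(p1), c(105, 3))
  expect_true(all(p1 >= 0 & p1 <= 0.1))
  set.seed(11)
  p2 <- de_init_population(b, 105)
  expect_identical(p1, p2)
  expect_error(de_init_population(b, 3), ">= 4")
})

test_that("population sizing is parameters times multiplier", {
  f <- function(x) sum(x^2)
  b1 <- cbind(rep(0, 3), rep(0.1, 3))     # one injection: 3 parameters
  r1 <- de_optimize(f, b1, de_settings(max_generations = 1), seed = 1)
  expect_equal(nrow(r1$population), 3 * 35)   # 105
  b2 <- cbind(rep(0, 6), rep(0.1, 6))     # two injections: 6 parameters
  r2 <- de_optimize(f, b2, de_settings(max_generations = 1), seed = 1)
  expect_equal(nrow(r2$population), 6 * 35)   # 210
})

test_that("best/1 mutation follows V = X_best + F (X_a - X_b)", {
  pop <- rbind(0.5, 0.3, 0.1)
  expect_equal(de_mutate_best1(pop, 1, 2, 3, F = 0.8), 0.66)
  expect_equal(de_mutate_best1(pop, 1, 2, 3, F = 0), 0.5)
  pop2 <- rbind(c(0.5, 1), c(0.3, 0.3), c(0.3, 0.3))
  # X_a = X_b collapses to the best individual
  expect_equal(de_mutate_best1(pop2, 1, 2, 3, F = 0.7), c(0.5, 1))
  expect_error(de_mutate_best1(pop, 1, 2, 2, F = 0.5), "distinct")
})

test_that("binomial crossover mixes mutant and target as drawn", {
  m <- c(1, 2, 3)
  t <- c(10, 20, 30)
  expect_equal(de_crossover_bin(m, t, C = 1), m)
  expect_equal(de_crossover_bin(m, t, C = 0), t)
  expect_equal(de_crossover_bin(m, t, C = 0, force_index = 2), c(10, 2, 30))
  # replaying recorded draws gives the hand-computed mix
  expect_equal(de_crossover_bin(m, t, C = 0.5, r = c(0.4, 0.9, 0.5)),
               c(1, 20, 3))
})

test_that("selection is greedy with ties favouring the trial", {
  expect_equal(as.numeric(de_select(1, 2, o_trial = 0.5, o_target = 1)), 1)
  expect_equal(as.numeric(de_select(1, 2, o_trial = 1, o_target = 1)), 1)
  expect_equal(as.numeric(de_select(1, 2, o_trial = 2, o_target = 1)), 2)
})

test_that("the stopping rule compares population spread to the mean", {
  expect_true(de_converged(rep(5, 10)))
  expect_false(de_converged(c(0, 200), atol = 0, tol = 0.01))   # sd 100 > 2
  expect_true(de_converged(c(1.0, 1.001), atol = 0, tol = 0.01))
  expect_error(de_converged(numeric(0)), "empty")
})

test_that("DE recovers the minimum of a convex quadratic", {
  xstar <- c(0.03, 0.07, 0.045)
  f <- function(x) sum((x - xstar)^2)
  res <- de_optimize(f, cbind(rep(0, 3), rep(0.1, 3)),
                     de_settings(tol = 1e-10, atol = 1e-14,
                                 max_generations = 500),
                     seed = 4)
  expect_true(res$converged)
  expect_lt(sqrt(sum((res$best - xstar)^2)), 1e-4)
  # identical seed and settings reproduce the run exactly
  res2 <- de_optimize(f, cbind(rep(0, 3), rep(0.1, 3)),
                      de_settings(tol = 1e-10, atol = 1e-14,
                                  max_generations = 500),
                      seed = 4)
  expect_identical(res$best, res2$best)
  expect_identical(res$history, res2$history)
})

test_that("elitism and bounds hold throughout the search", {
  f <- function(x) sum(100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2) + sum(x^2)
  res <- de_optimize(f, cbind(rep(-2, 4), rep(2, 4)),
                     de_settings(pop_multiplier = 8, tol = 0,
                                 max_generations = 40), seed = 2)
  expect_true(all(diff(res$history$best) <= 1e-14))
  expect_true(all(res$population >= -2 & res$population <= 2))
  expect_equal(res$best_objective, min(res$objectives))
  expect_equal(res$generations_run, 40)
  expect_false(res$converged)
})

test_that("planned injections beat the naive plan on a coarse mesh", {
  sc <- build_scenario(builtin_scenario(1, N = 32))
  naive <- evaluate_injections(sc, c(0.05, 0.05, 0.05), ht = 10)
  seeds <- c(101, 202, 303)
  objs <- numeric(0)
  for (s in seeds) {
    res <- optimize_injections(sc, np = 1,
                               settings = de_settings(pop_multiplier = 12,
                                                      max_generations = 150),
                               seed = s, ht = 10)
    expect_true(all(res$best_points >= 0 & res$best_points <= 0.1))
    expect_lte(res$best_objective, naive$objective)
    expect_equal(res$report$objective, res$best_objective)
    objs <- c(objs, res$best_objective)
  }
  # robustness: different seeds land on closely similar plans
  expect_lt(sd(objs), 0.05 * mean(objs) + 1e-8)
})
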