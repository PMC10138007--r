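test_that("built-in scenarios carry the reference geometry and settings", {
  c1 <- builtin_scenario(1)
  expect_equal(c1$domain$L, 0.1)
  expect_equal(c1$domain$N, 128L)
  expect_equal(length(c1$tumors), 1L)
  expect_equal(c1$tumors[[1]]$center, c(0.050, 0.050, 0.050))
  expect_equal(c1$tumors[[1]]$radius, 0.01)
  expect_equal(c1$treatment$Np, 1L)
  expect_equal(c1$treatment$t_end, 3000)
  expect_equal(c1$treatment$ht, 0.1)

  c2 <- builtin_scenario(2)
  expect_equal(tumor_centers(c2),
               rbind(c(0.040, 0.040, 0.040), c(0.060, 0.060, 0.060)))
  expect_equal(c2$treatment$Np, 2L)

  c3 <- builtin_scenario(3)
  expect_equal(tumor_centers(c3),
               rbind(c(0.045, 0.035, 0.040), c(0.045, 0.055, 0.045),
                     c(0.065, 0.055, 0.060)))
  expect_error(builtin_scenario(4), "1, 2 or 3")

  hp <- c1$healthy
  tp <- c1$tumor
  expect_equal(c(hp$k, hp$omega_b, hp$Q_m), c(0.51, 5.0e-4, 420))
  expect_equal(c(tp$k, tp$omega_b, tp$Q_m), c(0.64, 1.25e-3, 4200))
  expect_equal(c(c1$treatment$A, c1$treatment$r0), c(0.08e6, 1.9e-2))
})

test_that("tumor mask matches a brute-force distance check", {
  cfg <- scenario_config(N = 10, tumors = list(
    list(center = c(0.05, 0.05, 0.05), radius = 0.01)))
  sc <- build_scenario(cfg)
  coords <- (0:10) * 0.01
  count <- 0L
  for (k in 1:11) for (j in 1:11) for (i in 1:11) {
    d <- sqrt((coords[i] - 0.05)^2 + (coords[j] - 0.05)^2 +
                (coords[k] - 0.05)^2)
    inside <- d <= 0.01
    count <- count + inside
    expect_identical(sc$tumor_mask[i, j, k], inside)
  }
  expect_identical(sum(sc$tumor_mask), count)
  expect_gt(count, 0L)
})

test_that("masks partition the node set and fields take per-tissue values", {
  for (id in 1:3) {
    sc <- build_scenario(builtin_scenario(id, N = 16))
    nn <- (16 + 1)^3
    expect_equal(sum(sc$tumor_mask) + sum(sc$healthy_mask), nn)
    expect_false(any(sc$tumor_mask & sc$healthy_mask))
    expect_setequal(unique(as.vector(sc$k)), c(0.51, 0.64))
    expect_true(all(sc$Q_m[sc$tumor_mask] == 4200))
    expect_true(all(sc$Q_m[sc$healthy_mask] == 420))
    expect_true(all(sc$rho_c == 1000 * 4200))
  }
  sc0 <- build_scenario(scenario_config(N = 8, tumors = list()))
  expect_identical(sum(sc0$tumor_mask), 0L)
  expect_true(all(sc0$healthy_mask))
})

test_that("tumor node count scales with mesh volume", {
  n64 <- sum(build_scenario(builtin_scenario(1, N = 64))$tumor_mask)
  n128 <- sum(build_scenario(builtin_scenario(1, N = 128))$tumor_mask)
  expect_lt(abs(n128 / n64 - 8), 8 * 0.05)
})

test_that("invalid configurations are rejected with the offending key", {
  expect_error(scenario_config(N = 1), "'N'")
  expect_error(scenario_config(L = -1), "'L'")
  expect_error(scenario_config(tumors = list(
    list(center = c(0.095, 0.05, 0.05), radius = 0.01))), "inside the domain")
  expect_error(scenario_config(tumors = list(
    list(center = c(0.05, 0.05, 0.05), radius = -0.01))), "'radius'")
  expect_error(healthy_tissue(k = 0), "'k'")
  expect_error(tumor_tissue(omega_b = -1), "'omega_b'")
  expect_error(treatment_settings(Np = 0), "'Np'")
  expect_error(treatment_settings(ht = 0), "'ht'")
  expect_error(treatment_settings(T_damage = 30), "'T_damage'")
})

test_that("random scenarios are reproducible and non-overlapping", {
  a <- random_scenario(seed = 7, n_tumors = 3)
  b <- random_scenario(seed = 7, n_tumors = 3)
  expect_identical(a, b)
  ctrs <- tumor_centers(a)
  radii <- vapply(a$tumors, function(tm) tm$radius, numeric(1))
  for (i in 1:2) for (j in (i + 1):3) {
    d <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2))
    expect_gt(d, radii[i] + radii[j])
  }
  empty <- random_scenario(seed = 1, n_tumors = 0)
  expect_identical(length(empty$tumors), 0L)
  expect_error(
    random_scenario(seed = 1, n_tumors = 5, radius_range = c(0.02, 0.02),
                    margin = 0.02, max_tries = 20),
    "non-overlapping")
})
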