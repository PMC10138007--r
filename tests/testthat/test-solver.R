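test_that("harmonic-mean face conductivity is symmetric, bounded, exact", {
  expect_equal(face_conductivity(0.51, 0.51), 0.51)
  expect_equal(face_conductivity(0.51, 0.64), 0.5676522, tolerance = 1e-6)
  expect_equal(face_conductivity(0.51, 0.64), face_conductivity(0.64, 0.51))
  set.seed(42)
  k1 <- runif(50, 0.1, 2)
  k2 <- runif(50, 0.1, 2)
  kh <- face_conductivity(k1, k2)
  expect_true(all(kh >= pmin(k1, k2) - 1e-15))
  expect_true(all(kh <= pmax(k1, k2) + 1e-15))
  expect_error(face_conductivity(0, 0.5), "positive")
})

test_that("stability limit matches the diffusion-plus-decay bound and scalings", {
  sc <- build_scenario(builtin_scenario(1, N = 128))
  h2 <- (0.1 / 128)^2
  expect_equal(stability_limit(sc),
               h2 * 4.2e6 / (6 * 0.64 + h2 * 1.25e-3 * 1000 * 4200),
               tolerance = 1e-12)
  expect_lt(0.1, stability_limit(sc))  # the reference time step is stable
  # doubling k roughly halves the limit (decay term negligible)
  sc2 <- build_scenario(scenario_config(
    N = 32, tumors = list(),
    healthy = healthy_tissue(k = 2 * 0.51)))
  sc1 <- build_scenario(scenario_config(N = 32, tumors = list()))
  expect_equal(stability_limit(sc2) / stability_limit(sc1), 0.5,
               tolerance = 0.01)
  # doubling N roughly quarters it
  sc64 <- build_scenario(builtin_scenario(1, N = 64))
  sc128 <- build_scenario(builtin_scenario(1, N = 128))
  expect_equal(stability_limit(sc128) / stability_limit(sc64), 0.25,
               tolerance = 0.02)
  # simulate refuses an inadmissible step unless forced
  expect_error(simulate_treatment(sc1, t_end = 10, ht = 100), "stability")
})

test_that("single FTCS steps match hand-computed values", {
  sc <- build_scenario(scenario_config(N = 2, tumors = list()))
  # uniform 37, no SAR: every node gains ht * Q_m / rho_c
  f1 <- pennes_step(37, sc, ht = 0.1)
  expect_equal(as.vector(f1$values), rep(37 + 0.1 * 420 / 4.2e6, 27),
               tolerance = 1e-12)
  # uniform steady state T_a + Q_m / (omega_b rho_b c_b) = 37.2 is a fixed point
  f2 <- pennes_step(37.2, sc, ht = 0.1)
  expect_equal(as.vector(f2$values), rep(37.2, 27), tolerance = 1e-12)
  # ht = 0 is the identity
  T0 <- array(runif(27, 36, 40), c(3, 3, 3))
  f3 <- pennes_step(T0, sc, ht = 0)
  expect_identical(as.vector(f3$values), as.vector(T0))
})

test_that("the stepper agrees with a literal triple-loop oracle", {
  for (seed in 1:3) {
    sc <- raw_random_scenario(N = 4, seed = seed)
    np <- 5
    set.seed(100 + seed)
    T0 <- array(runif(np^3, 36, 42), c(np, np, np))
    qr <- array(runif(np^3, 0, 5e4), c(np, np, np))
    got <- pennes_step(T0, sc, qr = qr, ht = 0.05)
    want <- oracle_step(T0, sc$k, sc$perf, sc$Q_m, qr, sc$rho_c,
                        sc$domain$h, 0.05, sc$treatment$T_a)
    expect_equal(got$values, want, tolerance = 1e-12)
  }
  # two-tissue scenario with a Gaussian source: exercises the uniform sweep,
  # the sparse interface corrections, and the separable SAR evaluation
  cfg <- scenario_config(N = 4, tumors = list(
    list(center = c(0.05, 0.05, 0.05), radius = 0.03)))
  sc <- build_scenario(cfg)
  pts <- rbind(c(0.04, 0.05, 0.06), c(0.062, 0.041, 0.05))
  qr <- sar_field(sc, pts)
  set.seed(1)
  T0 <- array(runif(125, 36, 42), c(5, 5, 5))
  got <- pennes_step(T0, sc, points = pts, ht = 0.05)
  want <- oracle_step(T0, sc$k, sc$perf, sc$Q_m, qr, sc$rho_c,
                      sc$domain$h, 0.05, sc$treatment$T_a)
  expect_equal(got$values, want, tolerance = 1e-10)
})

test_that("the space-uniform limit reproduces the exponential solution", {
  sc <- build_scenario(scenario_config(N = 2, tumors = list()))
  fld <- simulate_treatment(sc, t_end = 3000, ht = 0.1)
  exact <- 37.2 - 0.2 * exp(-3000 / 2000)  # time constant rho_c / perf = 2000 s
  expect_lt(max(abs(fld$values - exact)), 1e-3)
  expect_equal(fld$time, 3000)
})

test_that("homogeneous tissues approach their perfusion steady states", {
  # healthy: 37 + 420/2100 = 37.2, tau = 2000 s
  sch <- build_scenario(scenario_config(N = 2, tumors = list()))
  fh <- simulate_treatment(sch, t_end = 10000, ht = 1)
  expect_lt(max(abs(fh$values - 37.2)), 1e-2)
  # tumor-everywhere: 37 + 4200/5250 = 37.8, tau = 800 s
  sct <- build_scenario(scenario_config(N = 2, tumors = list(),
                                        healthy = tumor_tissue()))
  ft <- simulate_treatment(sct, t_end = 4000, ht = 1)
  expect_lt(max(abs(ft$values - 37.8)), 1e-2)
})

test_that("heating from the 37 degree start is monotone at every node", {
  sc <- build_scenario(builtin_scenario(1, N = 8))
  fld <- temperature_field(array(37, c(9, 9, 9)), 0, sc$domain)
  for (s in 1:40) {
    nxt <- pennes_step(fld, sc, points = c(0.05, 0.05, 0.05), ht = 2)
    expect_true(all(nxt$values - fld$values >= -1e-12))
    fld <- nxt
  }
  expect_true(all(fld$values >= 37 - 1e-12))
})

test_that("a centred scenario yields a field with full cubic symmetry", {
  sc <- build_scenario(builtin_scenario(1, N = 16))
  fld <- simulate_treatment(sc, points = c(0.05, 0.05, 0.05),
                            t_end = 60, ht = 1)
  v <- fld$values
  rev_idx <- list(FALSE, TRUE)
  for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
    for (rx in rev_idx) for (ry in rev_idx) for (rz in rev_idx) {
      w <- aperm(v, perm)
      if (rx) w <- w[17:1, , ]
      if (ry) w <- w[, 17:1, ]
      if (rz) w <- w[, , 17:1]
      expect_lt(max(abs(w - v)), 1e-9)
    }
})

test_that("spatial error is second order on a manufactured steady problem", {
  # T*(x) = 37 + 0.5 cos(pi x/L) cos(pi y/L) cos(pi z/L) solves the steady
  # equation when Q_r = (3 k (pi/L)^2 + perf) (T* - 37); with Q_m present the
  # exact steady state shifts to T* + Q_m/perf.
  L <- 0.1
  err <- function(N) {
    sc <- build_scenario(scenario_config(L = L, N = N, tumors = list()))
    co <- sc$domain$coords
    cosx <- cos(pi * co / L)
    Tstar <- 37 + 0.5 * outer(outer(cosx, cosx), cosx)
    qr <- (3 * 0.51 * (pi / L)^2 + 2100) * (Tstar - 37)
    fld <- simulate_treatment(sc, qr = qr, t_end = 30000, ht = 2)
    max(abs(fld$values - (Tstar + 420 / 2100)))
  }
  ratio <- err(12) / err(24)
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})

test_that("temporal error is first order in the time step", {
  sc <- build_scenario(scenario_config(N = 2, tumors = list()))
  exact <- 37.2 - 0.2 * exp(-200 / 2000)
  e1 <- abs(simulate_treatment(sc, t_end = 200, ht = 10)$values[1, 1, 1] - exact)
  e2 <- abs(simulate_treatment(sc, t_end = 200, ht = 5)$values[1, 1, 1] - exact)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.5)
})

test_that("an unstable forced run aborts with a diagnostic", {
  sc <- build_scenario(builtin_scenario(1, N = 8))
  expect_error(
    simulate_treatment(sc, points = c(0.05, 0.05, 0.05),
                       t_end = 1e6, ht = 5000, force = TRUE,
                       check_every = 10),
    "unstable|non-finite")
})
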