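# Literal triple-loop transcription of the FTCS update with harmonic-mean
# face conductivities and mirror-node zero-flux boundaries.  Kept as naive
# as possible so it can serve as an independent oracle for the fast stepper.
oracle_step <- function(T, k, perf, qm, qr, rhoc, h, ht, t_a) {
  np <- dim(T)[1]
  mir <- function(p) if (p < 1) 2L else if (p > np) np - 1L else p
  hm <- function(a, b) 2 * a * b / (a + b)
  out <- array(NA_real_, dim(T))
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (kk in 1:np) for (jj in 1:np) for (ii in 1:np) {
    Tc <- T[ii, jj, kk]
    kc <- k[ii, jj, kk]
    flux <- 0
    for (d in offs) {
      i2 <- mir(ii + d[1]); j2 <- mir(jj + d[2]); k2 <- mir(kk + d[3])
      flux <- flux + hm(kc, k[i2, j2, k2]) * (T[i2, j2, k2] - Tc) / h^2
    }
    out[ii, jj, kk] <- Tc + ht / rhoc[ii, jj, kk] *
      (flux + perf[ii, jj, kk] * (t_a - Tc) +
         qm[ii, jj, kk] + qr[ii, jj, kk])
  }
  out
}

# Scenario-shaped object with fully random heterogeneous fields; every node
# differs from the reference tissue, so the stepper's exact per-node path is
# exercised throughout.
raw_random_scenario <- function(N = 4, L = 0.1, seed = 1) {
  set.seed(seed)
  np <- N + 1L
  dims <- c(np, np, np)
  sc <- list(
    domain = list(L = L, N = N, h = L / N, coords = (0:N) * (L / N)),
    k = array(runif(np^3, 0.3, 0.8), dims),
    omega_b = array(runif(np^3, 2e-4, 2e-3), dims),
    Q_m = array(runif(np^3, 100, 5000), dims),
    rho_c = array(runif(np^3, 3e6, 5e6), dims),
    tumor_mask = array(FALSE, dims),
    healthy_mask = array(TRUE, dims),
    treatment = treatment_settings(),
    healthy = healthy_tissue(),
    tumor = tumor_tissue()
  )
  sc$perf <- sc$omega_b * 1000 * 4200
  class(sc) <- "tp_scenario"
  sc
}
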