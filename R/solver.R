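#' Harmonic-mean face conductivity
#'
#' Thermal conductivity at the midpoint between two adjacent nodes of a
#' piecewise-homogeneous medium, estimated by the harmonic mean
#' `2 k1 k2 / (k1 + k2)`.  The harmonic mean preserves flux continuity
#' across a material interface; it is symmetric and bounded by its
#' arguments.  Vectorized over both arguments.
#'
#' @param k1,k2 conductivities of the two adjacent nodes, W/(m.degC)
#' @return Face conductivity, W/(m.degC).
#' @examples
#' face_conductivity(0.51, 0.64)
#' @export
face_conductivity <- function(k1, k2) {
  if (any(!is.finite(k1)) || any(!is.finite(k2)) || any(k1 <= 0) || any(k2 <= 0))
    stop("conductivities must be positive and finite", call. = FALSE)
  2 * k1 * k2 / (k1 + k2)
}

#' Explicit-scheme stability limit
#'
#' Largest admissible time step for the forward-Euler update of the
#' discretized bioheat equation, from the standard diffusion-plus-decay
#' bound: `ht_max = h^2 rho_c / (6 k_max + h^2 perf_max)` with
#' `perf = omega_b rho_b c_b`.  [simulate_treatment()] refuses a time step
#' above this limit unless forced.
#'
#' @param scenario a `tp_scenario`
#' @return Maximum stable time step, s.
#' @export
stability_limit <- function(scenario) {
  h2 <- scenario$domain$h^2
  h2 * min(scenario$rho_c) / (6 * max(scenario$k) + h2 * max(scenario$perf))
}

#' Construct a temperature field object
#'
#' @param values `(N+1)^3` numeric array, degC
#' @param time simulation time the field corresponds to, s
#' @param domain the scenario's domain description
#' @param trace optional per-interval min/max trace matrix
#' @return An object of class `tp_field`.
#' @keywords internal
#' @export
temperature_field <- function(values, time, domain, trace = NULL) {
  structure(list(values = values, time = time, domain = domain, trace = trace),
            class = "tp_field")
}

#' @export
print.tp_field <- function(x, ...) {
  cat("<tp_field> t =", x$time, "s, range [",
      format(min(x$values), digits = 6), ",",
      format(max(x$values), digits = 6), "] degC\n")
  invisible(x)
}

.field_values <- function(T, scenario) {
  np <- scenario$domain$N + 1L
  v <- if (inherits(T, "tp_field")) T$values else T
  if (is.null(dim(v))) {
    if (length(v) == 1L) v <- array(v, c(np, np, np)) else dim(v) <- c(np, np, np)
  }
  if (!all(dim(v) == np))
    stop("temperature field does not match the scenario grid", call. = FALSE)
  v
}

.run_kernel <- function(T0, scenario, points, qr, ht, n_steps, t_start,
                        trace_stride = 0L, check_every = 500L) {
  hp <- scenario$healthy
  inj <- NULL
  if (!is.null(points)) {
    points <- injection_set(points, scenario$domain$L)
    if (nrow(points) > 0) inj <- points
  }
  if (!is.null(qr)) {
    qr <- as.double(qr)
    if (length(qr) == 1L) qr <- rep(qr, length(scenario$k))
  }
  tr <- scenario$treatment
  res <- pennes_run_cpp(
    as.double(T0), as.double(scenario$k), as.double(scenario$perf),
    as.double(scenario$Q_m), as.double(scenario$rho_c),
    qr, inj, tr$A, tr$r0,
    as.integer(scenario$domain$N), scenario$domain$L, ht,
    as.integer(n_steps), tr$T_a, t_start,
    hp$k, hp$omega_b * hp$rho_b * hp$c_b, hp$Q_m, hp$rho * hp$c,
    as.integer(trace_stride), as.integer(check_every))
  np <- scenario$domain$N + 1L
  dim(res$values) <- c(np, np, np)
  res
}

#' Advance the temperature field by one FTCS step
#'
#' Applies one forward-time central-space update of the discretized bioheat
#' equation: every node gains `ht/rho_c` times the sum of its six
#' harmonic-mean face fluxes, the perfusion exchange `perf (T_a - T)`, the
#' metabolic heat `Q_m`, and the SAR source `Q_r`.  Boundary nodes use
#' zero-flux mirroring: a missing neighbour is replaced by the node's
#' interior mirror image (independently per axis at edges and corners).
#'
#' @param T current temperature field (`tp_field`, array, or a scalar for a
#'   uniform field), degC
#' @param scenario a `tp_scenario`
#' @param points injection points defining the SAR source (optional)
#' @param qr explicit per-node SAR field, W/m^3 (optional alternative to
#'   `points`; a scalar is recycled)
#' @param ht time step, s (>= 0; `ht = 0` returns the input unchanged)
#' @return A `tp_field` at time `time(T) + ht`.
#' @export
pennes_step <- function(T, scenario, points = NULL, qr = NULL,
                        ht = scenario$treatment$ht) {
  if (!is.null(points) && !is.null(qr))
    stop("give either 'points' or 'qr', not both", call. = FALSE)
  if (ht < 0) stop("'ht' must be >= 0", call. = FALSE)
  t0 <- if (inherits(T, "tp_field")) T$time else 0
  v <- .field_values(T, scenario)
  res <- .run_kernel(v, scenario, points, qr, ht, n_steps = 1L, t_start = t0)
  temperature_field(res$values, res$time, scenario$domain)
}

#' Simulate a hyperthermia treatment session
#'
#' Integrates the bioheat equation from the uniform initial temperature
#' `T_init` over the session duration using `n_steps = round(t_end / ht)`
#' explicit FTCS steps.  The SAR source is held fixed for the whole session
#' (injection sites do not move and the source model is time-independent).
#' The run aborts with a diagnostic if non-finite temperatures appear, and
#' refuses a time step above [stability_limit()] unless `force = TRUE`.
#'
#' @param scenario a `tp_scenario`
#' @param points injection points (`Np x 3` matrix or coordinate vector);
#'   an empty set simulates the unheated baseline
#' @param qr explicit per-node SAR field, W/m^3 (alternative to `points`)
#' @param t_end session duration, s
#' @param ht time step, s
#' @param T_init initial tissue temperature, degC
#' @param force run even if `ht` exceeds the stability limit
#' @param trace_stride record the field's min/max every this many steps
#'   (0 = only at the final step)
#' @param check_every steps between non-finite checks
#' @return A `tp_field` holding the final temperatures; element `trace` is a
#'   matrix of per-interval `step`, `time`, `T_min`, `T_max`.
#' @examples
#' sc <- build_scenario(builtin_scenario(1, N = 8))
#' fld <- simulate_treatment(sc, tumor_centers(sc), t_end = 60, ht = 1)
#' @export
simulate_treatment <- function(scenario, points = NULL, qr = NULL,
                               t_end = scenario$treatment$t_end,
                               ht = scenario$treatment$ht,
                               T_init = scenario$treatment$T_init,
                               force = FALSE, trace_stride = 0L,
                               check_every = 500L) {
  if (!inherits(scenario, "tp_scenario"))
    stop("'scenario' must be built with build_scenario()", call. = FALSE)
  if (!is.null(points) && !is.null(qr))
    stop("give either 'points' or 'qr', not both", call. = FALSE)
  if (ht <= 0) stop("'ht' must be > 0", call. = FALSE)
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  hmax <- stability_limit(scenario)
  if (ht > hmax && !force)
    stop(sprintf(paste0("time step ht = %g s exceeds the explicit stability",
                        " limit %.6g s; reduce ht or use force = TRUE"),
                 ht, hmax), call. = FALSE)
  n_steps <- as.integer(round(t_end / ht))
  np <- scenario$domain$N + 1L
  T0 <- array(T_init, c(np, np, np))
  res <- .run_kernel(T0, scenario, points, qr, ht, n_steps, t_start = 0,
                     trace_stride = trace_stride, check_every = check_every)
  temperature_field(res$values, res$time, scenario$domain, trace = res$trace)
}
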