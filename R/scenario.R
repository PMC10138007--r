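#' Tissue parameter sets
#'
#' Thermal and perfusion parameters for one tissue type, in SI units:
#' thermal conductivity `k` (W/(m.degC)), blood perfusion rate `omega_b`
#' (1/s), tissue and blood densities `rho`, `rho_b` (kg/m^3), metabolic heat
#' `Q_m` (W/m^3), tissue and blood specific heats `c`, `c_b` (J/(kg.degC)).
#' The defaults of `healthy_tissue()` and `tumor_tissue()` are the standard
#' literature values for soft tissue used by the built-in scenarios (tumor
#' tissue conducts heat better, is perfused 2.5x faster, and produces 10x
#' the metabolic heat).
#'
#' @param k thermal conductivity, W/(m.degC)
#' @param omega_b blood perfusion rate, 1/s
#' @param rho tissue density, kg/m^3
#' @param rho_b blood density, kg/m^3
#' @param Q_m metabolic heat generation, W/m^3
#' @param c tissue specific heat, J/(kg.degC)
#' @param c_b blood specific heat, J/(kg.degC)
#' @return A named list of class `tp_tissue`.
#' @examples
#' healthy_tissue()
#' tumor_tissue(omega_b = 1e-3)
#' @export
tissue_parameters <- function(k, omega_b, rho, rho_b, Q_m, c, c_b) {
  p <- list(k = k, omega_b = omega_b, rho = rho, rho_b = rho_b,
            Q_m = Q_m, c = c, c_b = c_b)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tissue parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(p, class = "tp_tissue")
}

#' @rdname tissue_parameters
#' @export
healthy_tissue <- function(k = 0.51, omega_b = 5.0e-4, rho = 1000, rho_b = 1000,
                           Q_m = 420, c = 4200, c_b = 4200) {
  tissue_parameters(k, omega_b, rho, rho_b, Q_m, c, c_b)
}

#' @rdname tissue_parameters
#' @export
tumor_tissue <- function(k = 0.64, omega_b = 1.25e-3, rho = 1000, rho_b = 1000,
                         Q_m = 4200, c = 4200, c_b = 4200) {
  tissue_parameters(k, omega_b, rho, rho_b, Q_m, c, c_b)
}

#' Treatment settings
#'
#' Session-level settings: the SAR source shape (`A`, peak volumetric heating
#' in W/m^3, and `r0`, the Gaussian coverage radius in metres, both set by
#' the injected ferrofluid volume), the number of injections `Np`, session
#' duration `t_end` and solver time step `ht` (seconds), arterial blood
#' temperature `T_a`, initial tissue temperature `T_init`, and the ablation
#' threshold `T_damage` (all degC).  Defaults describe a 50-minute session
#' with a 0.1 s step and the conventional 43 degC necrosis threshold.
#'
#' @param A SAR peak strength, W/m^3
#' @param r0 SAR coverage radius, m
#' @param Np number of injection points
#' @param t_end session duration, s
#' @param ht solver time step, s
#' @param T_a arterial blood temperature, degC
#' @param T_init initial tissue temperature, degC
#' @param T_damage ablation threshold, degC
#' @return A named list of class `tp_treatment`.
#' @export
treatment_settings <- function(A = 0.08e6, r0 = 1.9e-2, Np = 1,
                               t_end = 3000, ht = 0.1,
                               T_a = 37, T_init = 37, T_damage = 43) {
  tr <- list(A = A, r0 = r0, Np = Np, t_end = t_end, ht = ht,
             T_a = T_a, T_init = T_init, T_damage = T_damage)
  for (nm in names(tr))
    if (!is.numeric(tr[[nm]]) || length(tr[[nm]]) != 1L || !is.finite(tr[[nm]]))
      stop("treatment setting '", nm, "' must be a single finite number",
           call. = FALSE)
  if (A <= 0) stop("treatment setting 'A' must be > 0", call. = FALSE)
  if (r0 <= 0) stop("treatment setting 'r0' must be > 0", call. = FALSE)
  if (Np < 1 || Np != round(Np))
    stop("treatment setting 'Np' must be a positive integer", call. = FALSE)
  if (t_end <= 0) stop("treatment setting 't_end' must be > 0", call. = FALSE)
  if (ht <= 0) stop("treatment setting 'ht' must be > 0", call. = FALSE)
  if (T_damage <= T_init)
    stop("treatment setting 'T_damage' must exceed 'T_init'", call. = FALSE)
  tr$Np <- as.integer(Np)
  structure(tr, class = "tp_treatment")
}

#' Declarative scenario configuration
#'
#' Describes a cubic tissue domain of side `L` metres discretized into `N`
#' intervals per axis (so `(N+1)^3` nodes at spacing `h = L/N`), a set of
#' spherical tumors, the tissue parameter sets, and the treatment settings.
#' The configuration is validated on construction: every sphere must lie
#' fully inside the domain and all parameters must be positive.
#'
#' @param L domain side length, m
#' @param N number of grid intervals per axis (>= 2)
#' @param tumors list of tumors, each `list(center = c(x, y, z), radius = r)`
#'   in metres
#' @param healthy,tumor tissue parameter sets, see [tissue_parameters()]
#' @param treatment treatment settings, see [treatment_settings()]
#' @return An object of class `tp_config`.
#' @seealso [builtin_scenario()], [build_scenario()], [random_scenario()]
#' @examples
#' cfg <- scenario_config(N = 16, tumors = list(
#'   list(center = c(0.05, 0.05, 0.05), radius = 0.01)))
#' @export
scenario_config <- function(L = 0.1, N = 128, tumors = list(),
                            healthy = healthy_tissue(),
                            tumor = tumor_tissue(),
                            treatment = treatment_settings()) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("domain key 'L' must be a single positive number", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("domain key 'N' must be an integer >= 2", call. = FALSE)
  if (!inherits(healthy, "tp_tissue")) healthy <- do.call(tissue_parameters, healthy)
  if (!inherits(tumor, "tp_tissue")) tumor <- do.call(tissue_parameters, tumor)
  if (!inherits(treatment, "tp_treatment"))
    treatment <- do.call(treatment_settings, treatment)
  if (!is.list(tumors)) stop("'tumors' must be a list", call. = FALSE)
  for (ti in seq_along(tumors)) {
    tm <- tumors[[ti]]
    if (!is.list(tm) || is.null(tm$center) || is.null(tm$radius))
      stop("tumor ", ti, " must be a list with keys 'center' and 'radius'",
           call. = FALSE)
    if (length(tm$center) != 3L || !is.numeric(tm$center))
      stop("tumor ", ti, ": key 'center' must be a numeric 3-vector",
           call. = FALSE)
    if (!is.numeric(tm$radius) || length(tm$radius) != 1L || tm$radius <= 0)
      stop("tumor ", ti, ": key 'radius' must be a single positive number",
           call. = FALSE)
    if (any(tm$center - tm$radius < 0) || any(tm$center + tm$radius > L))
      stop("tumor ", ti, " does not fit inside the domain [0, L]^3",
           call. = FALSE)
    tumors[[ti]] <- list(center = as.numeric(tm$center),
                         radius = as.numeric(tm$radius))
  }
  structure(list(domain = list(L = L, N = as.integer(N)),
                 tumors = tumors, healthy = healthy, tumor = tumor,
                 treatment = treatment),
            class = "tp_config")
}

#' @export
print.tp_config <- function(x, ...) {
  cat("<tp_config> cubic domain L =", x$domain$L, "m, N =", x$domain$N,
      "intervals,", length(x$tumors), "tumor(s)\n")
  for (tm in x$tumors)
    cat("  tumor: center (", paste(format(tm$center), collapse = ", "),
        ") r =", tm$radius, "m\n")
  cat("  treatment: Np =", x$treatment$Np, ", t_end =", x$treatment$t_end,
      "s, ht =", x$treatment$ht, "s\n")
  invisible(x)
}

#' Built-in validation scenarios
#'
#' Three reference scenarios on a 0.1 m cubic domain with tumors of radius
#' 0.01 m and a 50-minute session (`t_end = 3000` s, `ht = 0.1` s):
#' \describe{
#'   \item{1}{one tumor at the domain centre (0.050, 0.050, 0.050), one
#'     injection (`Np = 1`);}
#'   \item{2}{two tumors at (0.040, 0.040, 0.040) and (0.060, 0.060, 0.060),
#'     `Np = 2`;}
#'   \item{3}{three tumors at (0.045, 0.035, 0.040), (0.045, 0.055, 0.045)
#'     and (0.065, 0.055, 0.060), `Np = 3` for the naive one-injection-per-
#'     tumor plan (optimized plans for this geometry do better with two
#'     injections; pass `np = 2` to [optimize_injections()]).}
#' }
#'
#' @param id scenario number, 1, 2 or 3
#' @param N grid intervals per axis (default 128, the mesh established by a
#'   grid-independence study)
#' @return A [scenario_config()] object.
#' @export
builtin_scenario <- function(id, N = 128) {
  if (length(id) != 1L || !id %in% c(1, 2, 3))
    stop("scenario id must be 1, 2 or 3", call. = FALSE)
  centers <- switch(as.character(id),
    "1" = list(c(0.050, 0.050, 0.050)),
    "2" = list(c(0.040, 0.040, 0.040), c(0.060, 0.060, 0.060)),
    "3" = list(c(0.045, 0.035, 0.040), c(0.045, 0.055, 0.045),
               c(0.065, 0.055, 0.060)))
  tumors <- lapply(centers, function(cc) list(center = cc, radius = 0.01))
  scenario_config(L = 0.1, N = N, tumors = tumors,
                  treatment = treatment_settings(Np = length(tumors)))
}

#' Tumor centres of a configuration
#'
#' Convenience accessor returning the tumor centres as an `n x 3` matrix,
#' e.g. to build the naive one-injection-per-tumor plan.
#'
#' @param config a [scenario_config()] object
#' @return Numeric matrix with one row per tumor.
#' @export
tumor_centers <- function(config) {
  if (inherits(config, "tp_scenario")) config <- config$config
  do.call(rbind, lapply(config$tumors, function(tm) tm$center))
}

#' Randomized scenario fixture
#'
#' Generates a reproducible configuration with `n_tumors` non-overlapping
#' spheres placed uniformly at random, keeping at least `margin` metres of
#' clearance from the domain faces.  Tissue and treatment parameters default
#' to the standard values.  Intended for property-style tests.
#'
#' @param seed RNG seed (integer)
#' @param n_tumors number of tumors (>= 0)
#' @param radius_range range to draw tumor radii from, m
#' @param margin clearance from the domain boundary, m
#' @param L,N domain side length and intervals per axis
#' @param max_tries placement attempts before giving up
#' @return A [scenario_config()] object.
#' @export
random_scenario <- function(seed, n_tumors = 1,
                            radius_range = c(0.008, 0.012),
                            margin = 0.005, L = 0.1, N = 32,
                            max_tries = 1000) {
  if (n_tumors < 0 || n_tumors != round(n_tumors))
    stop("'n_tumors' must be a non-negative integer", call. = FALSE)
  if (max(radius_range) + margin >= L / 2)
    stop("'radius_range' plus 'margin' leave no room inside the domain",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tumors <- list()
  tries <- 0L
  while (length(tumors) < n_tumors) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n_tumors, " non-overlapping tumors after ",
           max_tries, " attempts", call. = FALSE)
    r <- runif(1, radius_range[1], radius_range[2])
    lo <- r + margin
    hi <- L - r - margin
    ctr <- runif(3, lo, hi)
    ok <- TRUE
    for (tm in tumors)
      if (sqrt(sum((ctr - tm$center)^2)) <= r + tm$radius) { ok <- FALSE; break }
    if (ok) tumors[[length(tumors) + 1L]] <- list(center = ctr, radius = r)
  }
  np <- max(1L, as.integer(n_tumors))
  scenario_config(L = L, N = N, tumors = tumors,
                  treatment = treatment_settings(Np = np))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build the discrete simulation domain
#'
#' Discretizes a configuration onto the node-centred grid: `(N+1)^3` nodes at
#' coordinates `i * h`, `h = L/N`.  A node belongs to the tumor mask iff it
#' lies within (or on the surface of) any tumor sphere; ties on the surface
#' count as tumor, which is conservative toward ablating the whole tumor.
#' Per-node property fields (`k`, `omega_b`, `Q_m`, `rho_c`, and the
#' perfusion heat-transfer coefficient `perf = omega_b * rho_b * c_b`) take
#' the healthy or tumor value of the corresponding tissue parameter.
#'
#' @param config a [scenario_config()] object
#' @return An object of class `tp_scenario` with elements `domain`
#'   (`L`, `N`, `h`, node coordinates `coords`), the per-node fields, logical
#'   masks `tumor_mask` / `healthy_mask`, and the originating `config`.
#' @examples
#' sc <- build_scenario(builtin_scenario(1, N = 16))
#' sum(sc$tumor_mask)
#' @export
build_scenario <- function(config) {
  if (!inherits(config, "tp_config"))
    stop("'config' must be a tp_config (see scenario_config())", call. = FALSE)
  L <- config$domain$L
  N <- config$domain$N
  h <- L / N
  np <- N + 1L
  coords <- (0:N) * h
  dims <- c(np, np, np)

  mask <- array(FALSE, dims)
  for (tm in config$tumors) {
    d2 <- outer(outer((coords - tm$center[1])^2, (coords - tm$center[2])^2,
                      "+"),
                (coords - tm$center[3])^2, "+")
    mask <- mask | (d2 <= tm$radius^2)
  }

  hp <- config$healthy
  tp <- config$tumor
  fld <- function(hv, tv) {
    a <- array(hv, dims)
    if (any(mask)) a[mask] <- tv
    a
  }
  scenario <- list(
    domain = list(L = L, N = N, h = h, coords = coords),
    k = fld(hp$k, tp$k),
    omega_b = fld(hp$omega_b, tp$omega_b),
    Q_m = fld(hp$Q_m, tp$Q_m),
    rho_c = fld(hp$rho * hp$c, tp$rho * tp$c),
    perf = fld(hp$omega_b * hp$rho_b * hp$c_b,
               tp$omega_b * tp$rho_b * tp$c_b),
    tumor_mask = mask,
    healthy_mask = !mask,
    treatment = config$treatment,
    healthy = hp,
    tumor = tp,
    config = config
  )
  class(scenario) <- "tp_scenario"
  scenario
}

#' @export
print.tp_scenario <- function(x, ...) {
  nt <- sum(x$tumor_mask)
  nn <- length(x$tumor_mask)
  cat("<tp_scenario> ", x$domain$N, " intervals/axis (",
      format(nn, big.mark = ","), " nodes), h = ", format(x$domain$h),
      " m\n  tumor nodes: ", format(nt, big.mark = ","), " (",
      format(100 * nt / nn, digits = 3), "% of domain)\n", sep = "")
  invisible(x)
}
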