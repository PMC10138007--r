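#' Injection set
#'
#' Validates a set of nanoparticle injection points: an `Np x 3` matrix of
#' coordinates in metres, every point inside the closed domain `[0, L]^3`.
#' A zero-row matrix is allowed and denotes a pure-baseline run with no
#' external heating.
#'
#' @param points numeric `Np x 3` matrix (or length-3 vector for a single
#'   injection)
#' @param L domain side length, m
#' @return The validated matrix with columns `x`, `y`, `z`.
#' @export
injection_set <- function(points, L) {
  if (is.null(points)) points <- matrix(numeric(0), ncol = 3)
  if (is.numeric(points) && is.null(dim(points))) {
    if (length(points) %% 3L != 0L)
      stop("injection coordinates must come in (x, y, z) triples",
           call. = FALSE)
    points <- matrix(points, ncol = 3, byrow = TRUE)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must be an Np x 3 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  if (nrow(points) > 0 && (any(!is.finite(points)) ||
                           any(points < 0) || any(points > L)))
    stop("injection points must lie inside the domain [0, ", L, "]^3",
         call. = FALSE)
  colnames(points) <- c("x", "y", "z")
  points
}

#' Gaussian SAR heat-source field
#'
#' Evaluates the specific absorption rate produced by a set of nanoparticle
#' injections as a per-node field:
#' `Q_r(x) = sum_i A * exp(-||x - x0_i||^2 / r0^2)` (W/m^3).
#' Each injection contributes a radially symmetric Gaussian of peak `A` at
#' its injection point and coverage radius `r0`; contributions superpose.
#' The Gaussian is evaluated over the whole domain with no cutoff radius.
#'
#' @param scenario a `tp_scenario` (or a domain list with `L`, `N`)
#' @param points injection points, see [injection_set()]; an empty set gives
#'   the all-zero field
#' @param A SAR peak strength, W/m^3 (default: the scenario's treatment value)
#' @param r0 SAR coverage radius, m (default: the scenario's treatment value)
#' @return `(N+1)^3` numeric array, W/m^3.
#' @examples
#' sc <- build_scenario(builtin_scenario(1, N = 8))
#' q <- sar_field(sc, c(0.05, 0.05, 0.05))
#' max(q)  # = A at the injection node
#' @export
sar_field <- function(scenario, points, A = NULL, r0 = NULL) {
  dom <- if (inherits(scenario, "tp_scenario")) scenario$domain
         else list(L = scenario$L, N = scenario$N,
                   coords = (0:scenario$N) * (scenario$L / scenario$N))
  if (is.null(A))
    A <- if (inherits(scenario, "tp_scenario")) scenario$treatment$A else
      stop("'A' must be given when 'scenario' is a bare domain", call. = FALSE)
  if (is.null(r0))
    r0 <- if (inherits(scenario, "tp_scenario")) scenario$treatment$r0 else
      stop("'r0' must be given when 'scenario' is a bare domain", call. = FALSE)
  if (A <= 0) stop("'A' must be > 0", call. = FALSE)
  if (r0 <= 0) stop("'r0' must be > 0", call. = FALSE)
  points <- injection_set(points, dom$L)
  np <- dom$N + 1L
  coords <- dom$coords
  field <- array(0, c(np, np, np))
  for (i in seq_len(nrow(points))) {
    d2 <- outer(outer((coords - points[i, 1])^2, (coords - points[i, 2])^2,
                      "+"),
                (coords - points[i, 3])^2, "+")
    field <- field + A * exp(-d2 / r0^2)
  }
  field
}
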