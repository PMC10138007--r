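#' Tumor and healthy damage fractions
#'
#' Scores a temperature field against the ablation threshold.  A node counts
#' as damaged when its temperature reaches the threshold (`T >= T_damage`,
#' inclusive).  `Nt` is the percentage of tumor nodes damaged, `Nh` the
#' percentage of healthy nodes damaged, and `beta` is 1 exactly when every
#' tumor node is damaged (full ablation), else 0.  Percentages are node
#' counts within each mask.
#'
#' @param T temperature field (`tp_field` or array), degC
#' @param scenario a `tp_scenario`
#' @param T_damage ablation threshold, degC
#' @param allow_empty_tumor if `TRUE`, a scenario without tumor nodes yields
#'   `Nt = NA` and `beta = NA` instead of an error
#' @return A list with elements `Nt`, `Nh` (percent) and `beta` (0/1).
#' @export
damage_fractions <- function(T, scenario, T_damage = scenario$treatment$T_damage,
                             allow_empty_tumor = FALSE) {
  v <- .field_values(T, scenario)
  hot <- v >= T_damage
  n_tum <- sum(scenario$tumor_mask)
  n_hea <- sum(scenario$healthy_mask)
  if (n_tum == 0 && !allow_empty_tumor)
    stop("scenario has no tumor nodes; tumor damage is undefined ",
         "(use allow_empty_tumor = TRUE for baseline fixtures)", call. = FALSE)
  Nt <- if (n_tum > 0) 100 * sum(hot & scenario$tumor_mask) / n_tum else NA_real_
  Nh <- if (n_hea > 0) 100 * sum(hot & scenario$healthy_mask) / n_hea else NA_real_
  beta <- if (n_tum > 0) as.integer(Nt == 100) else NA_integer_
  list(Nt = Nt, Nh = Nh, beta = beta)
}

#' Treatment-plan objective
#'
#' The scalar minimized by the planner:
#' `O = 300 - Nt - (100 - Nh) - 100 * beta`.
#' Partial and total tumor damage reduce the objective while healthy-tissue
#' damage penalizes it; when the tumor is fully ablated (`Nt = 100`,
#' `beta = 1`) the objective reduces exactly to the healthy damage
#' percentage `Nh`.  An untouched domain scores 200; the ideal plan scores 0.
#'
#' @param Nt tumor damage, percent
#' @param Nh healthy damage, percent
#' @param beta full-ablation indicator, 0 or 1
#' @return Objective value (dimensionless).
#' @export
damage_objective <- function(Nt, Nh, beta) {
  if (any(Nt < 0 | Nt > 100, na.rm = TRUE) ||
      any(Nh < 0 | Nh > 100, na.rm = TRUE))
    stop("'Nt' and 'Nh' must be percentages in [0, 100]", call. = FALSE)
  if (any(!beta %in% c(0, 1), na.rm = TRUE))
    stop("'beta' must be 0 or 1", call. = FALSE)
  300 - Nt - (100 - Nh) - 100 * beta
}

#' Evaluate an injection plan
#'
#' Runs the full pipeline for a candidate plan: simulate the session with
#' the SAR source at the given injection points, score the final field with
#' [damage_fractions()], and attach the [damage_objective()].
#'
#' @param scenario a `tp_scenario`
#' @param points injection points (`Np x 3` matrix or coordinate vector)
#' @param ... further arguments passed to [simulate_treatment()]
#'   (e.g. `t_end`, `ht`)
#' @return An object of class `tp_damage`: a list with `Nt`, `Nh`, `beta`,
#'   `objective`, the injection `points`, and the final-field time `time`.
#' @examples
#' sc <- build_scenario(builtin_scenario(1, N = 16))
#' evaluate_injections(sc, tumor_centers(sc), t_end = 600, ht = 2)
#' @export
evaluate_injections <- function(scenario, points, ...) {
  points <- injection_set(points, scenario$domain$L)
  fld <- simulate_treatment(scenario, points = points, ...)
  dmg <- damage_fractions(fld, scenario)
  structure(list(Nt = dmg$Nt, Nh = dmg$Nh, beta = dmg$beta,
                 objective = damage_objective(dmg$Nt, dmg$Nh, dmg$beta),
                 points = points, time = fld$time),
            class = "tp_damage")
}

#' @export
print.tp_damage <- function(x, ...) {
  cat("<tp_damage> at t =", x$time, "s\n")
  cat(sprintf("  tumor damage   Nt = %.4f%%\n", x$Nt))
  cat(sprintf("  healthy damage Nh = %.4f%%\n", x$Nh))
  cat(sprintf("  full ablation  beta = %d\n", x$beta))
  cat(sprintf("  objective      O(p) = %.6f\n", x$objective))
  invisible(x)
}

#' @export
as.data.frame.tp_damage <- function(x, ...) {
  pts <- as.vector(t(x$points))
  nms <- as.vector(t(outer(seq_len(nrow(x$points)),
                           c("X", "Y", "Z"),
                           function(i, a) paste0(a, i))))
  out <- as.data.frame(as.list(setNames(pts, nms)))
  out$Nt <- x$Nt
  out$Nh <- x$Nh
  out$beta <- x$beta
  out$objective <- x$objective
  out
}
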