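#' Differential-evolution settings
#'
#' Settings for the best/1/bin differential-evolution optimizer.  The
#' population holds `pop_multiplier` individuals per optimized parameter
#' (3 coordinates per injection), 35 by default.  `F` is the mutation
#' factor; a length-2 vector dithers it uniformly once per generation.
#' `C` is the binomial crossover constant.  The run stops when the
#' population objective spread satisfies
#' `sd(O) <= atol + tol * |mean(O)|` (population standard deviation) or
#' after `max_generations` generations, in which case the attempt is
#' flagged unsuccessful.
#'
#' @param pop_multiplier individuals per optimized parameter
#' @param F mutation factor, or interval for per-generation dither
#' @param C crossover constant in `[0, 1]`
#' @param atol,tol absolute / relative convergence tolerances
#' @param max_generations generation cap
#' @param force_mutant_index always take at least one (uniformly chosen)
#'   coordinate from the mutant during crossover, so a trial can never be a
#'   verbatim copy of its target; disable for a literal binomial rule
#' @return A list of class `tp_de_settings`.
#' @export
de_settings <- function(pop_multiplier = 35, F = c(0.5, 1.0), C = 0.7,
                        atol = 0, tol = 0.01, max_generations = 10000,
                        force_mutant_index = TRUE) {
  if (pop_multiplier < 1) stop("'pop_multiplier' must be >= 1", call. = FALSE)
  if (!length(F) %in% 1:2 || any(!is.finite(F)))
    stop("'F' must be a number or a length-2 dither interval", call. = FALSE)
  if (C < 0 || C > 1) stop("'C' must lie in [0, 1]", call. = FALSE)
  if (max_generations < 1) stop("'max_generations' must be >= 1", call. = FALSE)
  structure(list(pop_multiplier = as.integer(pop_multiplier), F = F, C = C,
                 atol = atol, tol = tol,
                 max_generations = as.integer(max_generations),
                 force_mutant_index = isTRUE(force_mutant_index)),
            class = "tp_de_settings")
}

#' Initialize a DE population
#'
#' Draws `pop_size` individuals with independent uniform coordinates within
#' the bounds.  best/1 mutation needs the best individual plus two others
#' distinct from the target, so at least 4 individuals are required.
#'
#' @param bounds `nparam x 2` matrix of `[low, high]` per coordinate
#' @param pop_size number of individuals (>= 4)
#' @return `pop_size x nparam` matrix.
#' @export
de_init_population <- function(bounds, pop_size) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 2] < bounds[, 1]))
    stop("'bounds' must be an nparam x 2 [low, high] matrix", call. = FALSE)
  if (pop_size < 4)
    stop("'pop_size' must be >= 4 for best/1 mutation", call. = FALSE)
  nparam <- nrow(bounds)
  pop <- matrix(runif(pop_size * nparam), nrow = pop_size)
  sweep(sweep(pop, 2, bounds[, 2] - bounds[, 1], "*"), 2, bounds[, 1], "+")
}

#' best/1 mutation
#'
#' Mutant vector `V = X_best + F * (X_a - X_b)` built from the population's
#' best individual and two distinct others.
#'
#' @param population individuals matrix (rows = individuals)
#' @param best_idx,a_idx,b_idx row indices of the best individual and the
#'   two difference individuals; all three must be distinct
#' @param F mutation factor
#' @return Mutant vector.
#' @export
de_mutate_best1 <- function(population, best_idx, a_idx, b_idx, F) {
  if (a_idx == b_idx || a_idx == best_idx || b_idx == best_idx)
    stop("mutation indices must be distinct", call. = FALSE)
  population[best_idx, ] + F * (population[a_idx, ] - population[b_idx, ])
}

#' Binomial crossover
#'
#' Mixes mutant and target: coordinate `i` is taken from the mutant when the
#' uniform draw `r[i] <= C`, otherwise from the target.  When `force_index`
#' is given (the default behaviour of the optimizer picks it uniformly),
#' that coordinate is always taken from the mutant so the trial differs from
#' its target even at `C = 0`.
#'
#' @param mutant,target equal-length numeric vectors
#' @param C crossover constant in `[0, 1]`
#' @param r uniform draws, one per coordinate (drawn internally if omitted;
#'   pass explicitly for reproducible unit checks)
#' @param force_index coordinate always inherited from the mutant, or `NULL`
#' @return Trial vector.
#' @export
de_crossover_bin <- function(mutant, target, C, r = NULL, force_index = NULL) {
  n <- length(mutant)
  if (length(target) != n) stop("vector lengths differ", call. = FALSE)
  if (is.null(r)) r <- runif(n)
  take <- r <= C
  if (!is.null(force_index)) take[force_index] <- TRUE
  ifelse(take, mutant, target)
}

#' Greedy selection
#'
#' The trial replaces the target when its objective is at least as good
#' (ties favour the trial).
#'
#' @param trial,target candidate vectors
#' @param o_trial,o_target their objective values
#' @return The surviving vector, with attribute `objective`.
#' @export
de_select <- function(trial, target, o_trial, o_target) {
  if (o_trial <= o_target) structure(trial, objective = o_trial)
  else structure(target, objective = o_target)
}

#' DE convergence test
#'
#' The population has converged when the (population) standard deviation of
#' its objectives is within `atol + tol * |mean|`.
#'
#' @param objectives numeric vector of objective values
#' @param atol,tol absolute and relative tolerances
#' @return Logical flag.
#' @export
de_converged <- function(objectives, atol = 0, tol = 0.01) {
  if (length(objectives) == 0) stop("empty objective vector", call. = FALSE)
  m <- mean(objectives)
  s <- sqrt(mean((objectives - m)^2))
  s <= atol + tol * abs(m)
}

#' Minimize a function with differential evolution (best/1/bin)
#'
#' Generation-synchronous best/1/bin DE over box bounds: each generation
#' builds one trial per parent from the parent population's best individual
#' (mutation), binomial crossover against the parent, clipping of
#' out-of-bounds coordinates to the bounds, and greedy selection.  Stops on
#' [de_converged()] or after `max_generations`.
#'
#' @param fn objective function taking a parameter vector
#' @param bounds `nparam x 2` matrix of `[low, high]` per coordinate
#' @param settings a [de_settings()] object
#' @param pop_size population size (default
#'   `nrow(bounds) * settings$pop_multiplier`)
#' @param seed RNG seed for reproducibility (optional)
#' @param verbose print per-generation best/mean/sd
#' @return A list of class `tp_opt`: `best` (vector), `best_objective`,
#'   `generations_run`, `converged`, `history` (data frame of per-generation
#'   `best`, `mean`, `sd`), `population`, `objectives`, `seed`,
#'   `n_evaluations`.
#' @examples
#' f <- function(x) sum((x - 0.03)^2)
#' res <- de_optimize(f, cbind(0, rep(0.1, 3)), de_settings(tol = 1e-8),
#'                    seed = 1)
#' res$best
#' @export
de_optimize <- function(fn, bounds, settings = de_settings(), pop_size = NULL,
                        seed = NULL, verbose = FALSE) {
  bounds <- as.matrix(bounds)
  nparam <- nrow(bounds)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pop_size)) pop_size <- nparam * settings$pop_multiplier
  pop <- de_init_population(bounds, pop_size)
  obj <- apply(pop, 1, fn)
  n_eval <- pop_size
  hist_best <- hist_mean <- hist_sd <- numeric(0)
  converged <- FALSE
  gen <- 0L

  while (gen < settings$max_generations) {
    gen <- gen + 1L
    Fg <- if (length(settings$F) == 2L)
      runif(1, settings$F[1], settings$F[2]) else settings$F
    best_idx <- which.min(obj)
    new_pop <- pop
    new_obj <- obj
    for (r in seq_len(pop_size)) {
      pool <- setdiff(seq_len(pop_size), c(best_idx, r))
      ab <- if (length(pool) >= 2) sample(pool, 2L) else sample(pool, 2L, replace = TRUE)
      mutant <- pop[best_idx, ] + Fg * (pop[ab[1], ] - pop[ab[2], ])
      jrand <- if (settings$force_mutant_index) sample.int(nparam, 1L) else NULL
      trial <- de_crossover_bin(mutant, pop[r, ], settings$C,
                                force_index = jrand)
      trial <- pmin(pmax(trial, bounds[, 1]), bounds[, 2])
      o_trial <- fn(trial)
      n_eval <- n_eval + 1L
      if (o_trial <= obj[r]) {
        new_pop[r, ] <- trial
        new_obj[r] <- o_trial
      }
    }
    pop <- new_pop
    obj <- new_obj
    m <- mean(obj)
    s <- sqrt(mean((obj - m)^2))
    hist_best <- c(hist_best, min(obj))
    hist_mean <- c(hist_mean, m)
    hist_sd <- c(hist_sd, s)
    if (verbose)
      message(sprintf("gen %4d  best %.6f  mean %.6f  sd %.3g",
                      gen, min(obj), m, s))
    if (de_converged(obj, settings$atol, settings$tol)) {
      converged <- TRUE
      break
    }
  }

  best_idx <- which.min(obj)
  structure(list(best = pop[best_idx, ],
                 best_objective = obj[best_idx],
                 generations_run = gen,
                 converged = converged,
                 history = data.frame(generation = seq_along(hist_best),
                                      best = hist_best, mean = hist_mean,
                                      sd = hist_sd),
                 population = pop, objectives = obj,
                 seed = seed, n_evaluations = n_eval),
            class = "tp_opt")
}

#' @export
print.tp_opt <- function(x, ...) {
  cat("<tp_opt>", if (x$converged) "converged" else "NOT converged",
      "after", x$generations_run, "generation(s),", x$n_evaluations,
      "evaluations\n  best objective:", format(x$best_objective), "\n")
  invisible(x)
}

#' Optimize nanoparticle injection sites
#'
#' Searches for `np` injection points (3 coordinates each, bounded by the
#' domain cube) that minimize the damage objective
#' `O = 300 - Nt - (100 - Nh) - 100 beta`: full tumor ablation with the
#' least healthy-tissue damage.  Each candidate plan is scored by a full
#' session simulation ([evaluate_injections()]); identical candidates reuse
#' cached objective values, since the objective is a pure function of the
#' coordinates.
#'
#' @param scenario a `tp_scenario`
#' @param np number of injection points to place
#' @param settings a [de_settings()] object
#' @param seed RNG seed (recorded in the result)
#' @param pop_size population size override (default `3 np * pop_multiplier`)
#' @param cache reuse objective values of previously seen candidates
#' @param verbose print per-generation progress
#' @param ... passed to [simulate_treatment()] (e.g. `t_end`, `ht`)
#' @return A `tp_opt` (see [de_optimize()]) with `best_points` as an
#'   `np x 3` matrix and a `report` from [evaluate_injections()] at the
#'   optimum.
#' @export
optimize_injections <- function(scenario, np = scenario$treatment$Np,
                                settings = de_settings(), seed = NULL,
                                pop_size = NULL, cache = TRUE,
                                verbose = FALSE, ...) {
  if (!inherits(scenario, "tp_scenario"))
    stop("'scenario' must be built with build_scenario()", call. = FALSE)
  if (np < 1 || np != round(np))
    stop("'np' must be a positive integer", call. = FALSE)
  L <- scenario$domain$L
  bounds <- cbind(rep(0, 3 * np), rep(L, 3 * np))
  memo <- new.env(parent = emptyenv())
  fn <- function(x) {
    key <- if (cache) paste(sprintf("%.17g", x), collapse = ",") else NULL
    if (!is.null(key) && !is.null(memo[[key]])) return(memo[[key]])
    pts <- matrix(x, ncol = 3, byrow = TRUE)
    val <- evaluate_injections(scenario, pts, ...)$objective
    if (!is.null(key)) memo[[key]] <- val
    val
  }
  res <- de_optimize(fn, bounds, settings = settings, pop_size = pop_size,
                     seed = seed, verbose = verbose)
  res$best_points <- injection_set(matrix(res$best, ncol = 3, byrow = TRUE), L)
  res$report <- evaluate_injections(scenario, res$best_points, ...)
  res
}
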