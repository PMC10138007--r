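#' Write an optimization results table
#'
#' Serializes a homogeneous list of results — [optimize_injections()] /
#' [de_optimize()] outputs (`tp_opt`) or [evaluate_injections()] reports
#' (`tp_damage`) — as a CSV table with one row per run, coordinate columns
#' `X1,Y1,Z1[,X2,...]`, the objective column `O(p)`, and footer rows `Mean`
#' and `SD` computed per column (sample standard deviation; a single run
#' gets an SD row of zeros).
#'
#' @param results list of `tp_opt` or `tp_damage` objects (a single object
#'   is wrapped)
#' @param path output CSV path
#' @return The full table (runs + footer) as a data frame, invisibly.
#' @export
write_results_csv <- function(results, path) {
  if (inherits(results, c("tp_opt", "tp_damage"))) results <- list(results)
  if (!length(results)) stop("'results' is empty", call. = FALSE)
  rows <- lapply(results, function(r) {
    if (inherits(r, "tp_opt"))
      list(points = r$best_points, objective = r$best_objective)
    else if (inherits(r, "tp_damage"))
      list(points = r$points, objective = r$objective)
    else stop("'results' must contain tp_opt or tp_damage objects",
              call. = FALSE)
  })
  nps <- vapply(rows, function(r) nrow(r$points), integer(1))
  if (length(unique(nps)) != 1L)
    stop("all results in one table must have the same number of injections",
         call. = FALSE)
  np <- nps[1]
  mat <- do.call(rbind, lapply(rows, function(r)
    c(as.vector(t(r$points)), r$objective)))
  cn <- c(as.vector(t(outer(seq_len(np), c("X", "Y", "Z"),
                            function(i, a) paste0(a, i)))), "O(p)")
  colnames(mat) <- cn
  mu <- colMeans(mat)
  sdv <- if (nrow(mat) > 1) apply(mat, 2, stats::sd) else rep(0, ncol(mat))
  tab <- data.frame(run = c(as.character(seq_len(nrow(mat))), "Mean", "SD"),
                    rbind(mat, mu, sdv), check.names = FALSE)
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(tab)
}

#' Write a run manifest
#'
#' Persists everything needed to reproduce a run as JSON: the configuration
#' snapshot, package version, explicit RNG seeds, timestamps and an index
#' of the files the run produced.
#'
#' @param path output JSON path
#' @param config the [scenario_config()] used
#' @param seeds integer vector of RNG seeds
#' @param outputs named character vector/list of produced files
#' @param extra optional named list of additional metadata
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds = integer(0),
                           outputs = list(), extra = list()) {
  man <- c(list(
    software = "thermoplan",
    version = as.character(utils::packageVersion("thermoplan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    config = rapply(unclass(config), unclass, how = "replace"),
    outputs = outputs), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Plot a mid-plane slice of a temperature field
#'
#' Base-graphics heatmap of one axis-aligned slice with the ablation
#' isotherm drawn as a contour, and the tumor outline when a scenario is
#' given.  Convenience for quick inspection; use [write_vtk()] + ParaView
#' for full 3D rendering.
#'
#' @param T a `tp_field`
#' @param scenario optional `tp_scenario` for the tumor outline
#' @param axis slicing axis, `"x"`, `"y"` or `"z"`
#' @param index node index of the slice (default: mid-plane)
#' @param threshold isotherm to highlight, degC
#' @param ... passed to [graphics::image()]
#' @return The slice matrix, invisibly.
#' @export
plot_slice <- function(T, scenario = NULL, axis = "z", index = NULL,
                       threshold = 43, ...) {
  dom <- if (inherits(T, "tp_field")) T$domain else scenario$domain
  v <- if (inherits(T, "tp_field")) T$values else .field_values(T, scenario)
  np <- dim(v)[1]
  if (is.null(index)) index <- (np + 1L) %/% 2L
  sl <- switch(axis, x = v[index, , ], y = v[, index, ], z = v[, , index],
               stop("'axis' must be 'x', 'y' or 'z'", call. = FALSE))
  co <- dom$coords
  graphics::image(co, co, sl, useRaster = TRUE,
                  xlab = "m", ylab = "m",
                  main = sprintf("T at t = %g s (%s-slice %d)",
                                 if (inherits(T, "tp_field")) T$time else NA,
                                 axis, index), ...)
  if (any(sl >= threshold) && any(sl < threshold))
    graphics::contour(co, co, sl, levels = threshold, add = TRUE, lwd = 2)
  if (!is.null(scenario)) {
    msk <- switch(axis, x = scenario$tumor_mask[index, , ],
                  y = scenario$tumor_mask[, index, ],
                  z = scenario$tumor_mask[, , index])
    if (any(msk) && any(!msk))
      graphics::contour(co, co, msk + 0, levels = 0.5, add = TRUE,
                        lty = 2, drawlabels = FALSE)
  }
  invisible(sl)
}
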