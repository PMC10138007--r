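#' Export a temperature field to legacy VTK
#'
#' Writes an ASCII legacy-VTK `STRUCTURED_POINTS` dataset with point-data
#' scalars `temperature_C` (degC, full double precision, so a read-back
#' reproduces the array bit-exactly) and, when a scenario is supplied,
#' `tissue_mask` (0 healthy, 1 tumor).  Origin is (0,0,0) and spacing is
#' the grid spacing `h`, so the file can be loaded directly into ParaView
#' or any VTK-based viewer (e.g. to render the 43 degC damage isosurface).
#'
#' @param T a `tp_field` (or bare `(N+1)^3` array if `scenario` is given)
#' @param scenario a `tp_scenario`, used for the grid geometry and the
#'   tumor mask; optional when `T` is a `tp_field`
#' @param path output file path
#' @param title dataset title line
#' @return `path`, invisibly.
#' @seealso [read_vtk()]
#' @export
write_vtk <- function(T, scenario = NULL, path, title = "thermoplan field") {
  if (inherits(T, "tp_field")) {
    dom <- T$domain
    values <- T$values
  } else {
    if (is.null(scenario)) stop("a bare array needs a 'scenario'", call. = FALSE)
    dom <- scenario$domain
    values <- .field_values(T, scenario)
  }
  np <- dom$N + 1L
  if (!all(dim(values) == np))
    stop("field and domain dimensions disagree", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", np, np, np),
               "ORIGIN 0 0 0",
               paste("SPACING", format(dom$h, digits = 17),
                     format(dom$h, digits = 17), format(dom$h, digits = 17)),
               paste("POINT_DATA", np^3),
               "SCALARS temperature_C double",
               "LOOKUP_TABLE default"), con)
  # x varies fastest, matching both R's column-major layout and VTK order
  writeLines(sprintf("%.17g", as.vector(values)), con)
  if (!is.null(scenario)) {
    writeLines(c("SCALARS tissue_mask int", "LOOKUP_TABLE default"), con)
    writeLines(as.character(as.integer(as.vector(scenario$tumor_mask))), con)
  }
  invisible(path)
}

#' Read a legacy VTK STRUCTURED_POINTS file
#'
#' Parses the ASCII subset written by [write_vtk()] (one or more point-data
#' scalar fields on a structured-points grid).
#'
#' @param path file path
#' @return A list with `dimensions`, `origin`, `spacing`, and `fields`
#'   (named list of arrays in grid shape).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  grab <- function(prefix) {
    ln <- grep(paste0("^", prefix), lines, value = TRUE)
    if (!length(ln)) stop("VTK file lacks ", prefix, " line", call. = FALSE)
    as.numeric(strsplit(trimws(sub(prefix, "", ln[1])), "\\s+")[[1]])
  }
  dims <- grab("DIMENSIONS")
  origin <- grab("ORIGIN")
  spacing <- grab("SPACING")
  n <- prod(dims)
  starts <- grep("^SCALARS", lines)
  fields <- list()
  for (idx in seq_along(starts)) {
    s <- starts[idx]
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    from <- s + 2L  # skip LOOKUP_TABLE
    to <- if (idx < length(starts)) starts[idx + 1L] - 1L else length(lines)
    toks <- unlist(strsplit(trimws(lines[from:to]), "\\s+"), use.names = FALSE)
    vals <- as.numeric(toks[nzchar(toks)])
    if (length(vals) != n)
      stop("field '", name, "' has ", length(vals), " values, expected ", n,
           call. = FALSE)
    fields[[name]] <- array(vals, dims)
  }
  list(dimensions = dims, origin = origin, spacing = spacing, fields = fields)
}
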