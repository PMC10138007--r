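.cfg_known <- list(
  top = c("domain", "tumors", "tissue", "treatment", "optimizer"),
  domain = c("L", "N"),
  tumor = c("center", "radius"),
  tissue = c("healthy", "tumor"),
  tissue_keys = c("k", "omega_b", "rho", "rho_b", "Q_m", "c", "c_b"),
  treatment = c("A", "r0", "Np", "t_end", "ht", "T_a", "T_init", "T_damage"),
  optimizer = c("pop_multiplier", "F", "C", "atol", "tol", "max_generations",
                "force_mutant_index")
)

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key '", bad[1], "' in ", where, " section", call. = FALSE)
}

#' Read a scenario configuration file
#'
#' Parses a YAML configuration with sections `domain` (`L`, `N`), `tumors`
#' (list of `center`/`radius` entries), `tissue` (`healthy` and `tumor`
#' parameter maps with keys `k`, `omega_b`, `rho`, `rho_b`, `Q_m`, `c`,
#' `c_b`), `treatment` (`A`, `r0`, `Np`, `t_end`, `ht`, `T_a`, `T_init`,
#' `T_damage`) and an optional `optimizer` section matching
#' [de_settings()].  All values are SI (metres, seconds, W/m^3, degC).
#' Omitted optional keys take the documented defaults; unknown or invalid
#' keys raise an error naming the key.
#'
#' @param path path to the YAML file
#' @return A list with elements `config` (a [scenario_config()]) and `de`
#'   (a [de_settings()]).
#' @seealso [write_config()]
#' @examples
#' cfg <- read_config(system.file("extdata", "scenario1.yaml",
#'                                package = "thermoplan"))
#' cfg$config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file is not a YAML mapping", call. = FALSE)
  .check_keys(raw, .cfg_known$top, "top-level")
  # a bare `N:` key is a YAML 1.1 boolean; undo that reading
  if (!is.null(raw$domain))
    names(raw$domain)[names(raw$domain) %in% c("FALSE", "n")] <- "N"
  if (is.null(raw$domain) || is.null(raw$domain$L) || is.null(raw$domain$N))
    stop("config must provide domain keys 'L' and 'N'", call. = FALSE)
  .check_keys(raw$domain, .cfg_known$domain, "domain")
  tumors <- raw$tumors %||% list()
  for (i in seq_along(tumors))
    .check_keys(tumors[[i]], .cfg_known$tumor, paste0("tumors[", i, "]"))
  tissue <- raw$tissue %||% list()
  .check_keys(tissue, .cfg_known$tissue, "tissue")
  healthy <- do.call(healthy_tissue, .validated_tissue(tissue$healthy, "tissue.healthy"))
  tumor <- do.call(tumor_tissue, .validated_tissue(tissue$tumor, "tissue.tumor"))
  trt <- raw$treatment %||% list()
  .check_keys(trt, .cfg_known$treatment, "treatment")
  treatment <- do.call(treatment_settings, trt)
  config <- scenario_config(L = raw$domain$L, N = raw$domain$N,
                            tumors = tumors, healthy = healthy, tumor = tumor,
                            treatment = treatment)
  de <- raw$optimizer %||% list()
  .check_keys(de, .cfg_known$optimizer, "optimizer")
  if (!is.null(de$F)) de$F <- as.numeric(unlist(de$F))
  list(config = config, de = do.call(de_settings, de))
}

.validated_tissue <- function(x, where) {
  x <- x %||% list()
  .check_keys(x, .cfg_known$tissue_keys, where)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration file
#'
#' Serializes a configuration (and optionally DE settings) to the YAML
#' dialect understood by [read_config()], so that write -> read round-trips.
#'
#' @param config a [scenario_config()] object
#' @param path output file path
#' @param de optional [de_settings()] to include as the `optimizer` section
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, de = NULL) {
  if (!inherits(config, "tp_config"))
    stop("'config' must be a tp_config", call. = FALSE)
  out <- list(
    domain = list(L = config$domain$L, N = config$domain$N),
    tumors = lapply(config$tumors, function(tm)
      list(center = tm$center, radius = tm$radius)),
    tissue = list(healthy = unclass(config$healthy),
                  tumor = unclass(config$tumor)),
    treatment = unclass(config$treatment)
  )
  if (!is.null(de)) out$optimizer <- unclass(de)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
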