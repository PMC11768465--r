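# Multi-page TIFF interchange with JSON sidecars.
#
# Stacks are written one page per time point as 32-bit TIFF samples; the
# sidecar (<path>.json) carries the temporal metadata (gate spacing or the
# dense time grid), which is never inferred from the pixel data.  Axis
# convention: (row, column, time).

sidecar_path <- function(path) paste0(path, ".json")

# the tiff writer stores samples in [0, 1]; pages are rescaled by a
# factor recorded in the sidecar so arbitrary intensities round-trip
stack_scale <- function(x) max(max(abs(x)), 1e-12)

#' Write an image stack to multi-page TIFF
#'
#' @param x a [gated_stack()], or a dense `height x width x n_bins` array
#'   with a `grid` supplied.
#' @param path output TIFF path; the metadata sidecar is written next to
#'   it as `<path>.json`.
#' @param grid the [time_grid()] of a dense stack.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, grid = NULL) {
  sc <- stack_scale(x)
  if (inherits(x, "gated_stack")) {
    meta <- list(type = "gated", n_gates = dim(x)[3],
                 gate_spacing = gate_spacing(x), scale = sc)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(grid)) stop("dense stacks require a 'grid'")
    meta <- list(type = "dense", n_bins = dim(x)[3], scale = sc,
                 grid = list(t_start = grid$t_start, dt = grid$dt,
                             n_bins = grid$n_bins))
  } else stop("'x' must be a gated_stack or 3D array")
  pages <- lapply(seq_len(dim(x)[3]), function(k)
    matrix(as.numeric(x[, , k]) / sc, dim(x)[1], dim(x)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' @param path TIFF path written by [write_stack()] (or any multi-page
#'   float TIFF with identically shaped pages).
#' @param gate_spacing gate spacing (ns) when no sidecar is present.
#' @return A [gated_stack()], or a list `(values, grid)` for a dense
#'   stack.
#' @export
read_stack <- function(path, gate_spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged TIFF: pages have differing shapes")
  arr <- array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages)))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$scale)) arr <- arr * meta$scale
    if (identical(meta$type, "dense"))
      return(list(values = arr,
                  grid = time_grid(meta$grid$t_start, meta$grid$dt,
                                   meta$grid$n_bins)))
    gate_spacing <- meta$gate_spacing
  }
  if (is.null(gate_spacing))
    stop("gate spacing not found: no sidecar and no 'gate_spacing' given")
  gated_stack(arr, gate_spacing)
}

#' Write estimation results
#'
#' Writes the lifetime map as a two-page 32-bit float TIFF (lifetime page
#' plus binary validity page), the summary table as CSV, and a JSON
#' provenance record (seed, configuration, package version).
#'
#' @param map a [lifetime_map()].
#' @param summary a data frame (e.g. from [summarize_map()]).
#' @param prefix output path prefix; files are `<prefix>_lifetime.tiff`,
#'   `<prefix>_summary.csv`, `<prefix>_provenance.json`.
#' @param seed the master seed used for the run (recorded, not applied).
#' @param config optional configuration list recorded in the provenance.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(map, summary, prefix, seed = NA, config = NULL) {
  stopifnot(inherits(map, "lifetime_map"), is.data.frame(summary))
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir)
  paths <- c(lifetime = paste0(prefix, "_lifetime.tiff"),
             summary = paste0(prefix, "_summary.csv"),
             provenance = paste0(prefix, "_provenance.json"))
  tau <- map$tau
  tau[!map$valid] <- 0
  sc <- stack_scale(tau)
  tiff::writeTIFF(list(tau / sc, matrix(as.numeric(map$valid), nrow(tau))),
                  paths[["lifetime"]], bits.per.sample = 32L)
  jsonlite::write_json(list(type = "lifetime", scale = sc,
                            pages = c("lifetime", "validity")),
                       sidecar_path(paths[["lifetime"]]),
                       auto_unbox = TRUE, digits = NA)
  write.csv(summary, paths[["summary"]], row.names = FALSE)
  prov <- list(seed = seed, method = map$method,
               package = "flimgate",
               version = as.character(utils::packageVersion("flimgate")),
               config = config)
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read and write run configurations
#'
#' A run configuration merges the simulation, model and training settings
#' with the protocol, seed and output paths; it round-trips losslessly
#' through YAML so every run can write its fully resolved configuration
#' beside its outputs.
#'
#' @param config a named list (nested lists of scalars/vectors).
#' @param path YAML file path.
#' @return `write_run_config()`: `path`, invisibly;
#'   `read_run_config()`: the configuration list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
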