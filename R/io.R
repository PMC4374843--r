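#' Write a density grid as TSV with a JSON sidecar
#'
#' Writes the tabulated density as tab-separated text (columns `variable`,
#' `abscissa`, `density`) plus a JSON sidecar (`<path>.json`) recording the
#' parameters, normalization constant and evaluation method, so a table on
#' disk is self-describing.
#'
#' @param grid A `density_grid`.
#' @param path Output TSV path.
#' @param sidecar Write the JSON sidecar too?
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(grid, path, sidecar = TRUE) {
  stopifnot(inherits(grid, "density_grid"))
  utils::write.table(as.data.frame(grid), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (sidecar) {
    meta <- list(schema = "decoyburst/density-grid/1",
                 variable = grid$variable,
                 params = unclass(grid$params),
                 log_kappa = grid$log_kappa,
                 origin_mass = grid$origin_mass,
                 origin_exponent = grid$origin_exponent,
                 method = grid$method,
                 n_grid = length(grid$x))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and write run configurations
#'
#' A run configuration is a flat JSON object holding the circuit parameters
#' (`a0`, `a1`, `kp`, `b`, `y`, `kb`, `gamma_b`) plus any command-specific
#' options (for example `seed`, `t_end`, `n_samples`). Re-reading a written
#' configuration reproduces it exactly.
#'
#' @param config Named list (must include the circuit parameters).
#' @param path JSON file path.
#' @return `write_run_config()`: `path`, invisibly. `read_run_config()`: a
#'   named list with element `params` (a [gene_params()]) and any further
#'   options.
#' @export
write_run_config <- function(config, path) {
  if (inherits(config$params, "gene_params")) {
    config <- c(unclass(config$params),
                config[setdiff(names(config), "params")])
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pnames <- intersect(names(raw), c("a0", "a1", "kp", "b", "y", "kb",
                                    "gamma_b"))
  c(list(params = do.call(gene_params, raw[pnames])),
    raw[setdiff(names(raw), pnames)])
}
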