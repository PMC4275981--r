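#' Default run configuration
#'
#' Collects every tunable of the pipeline in one place with the canonical
#' defaults: G4 scan pattern (G>=3 N1-25)3 G>=3; 1,000 matched control
#' sets; association windows of 0 bp for annotation tracks, 300 bp (the
#' ChIP shearing size) for helicase and polymerase peaks and 5,000 bp for
#' the damage mark; 0 and 500 bp robustness windows; q < 0.05 significance
#' calls; add-one empirical P-values.
#'
#' @param ... overrides for any field.
#' @return a named list of class `g4_config`.
#' @export
g4_config <- function(...) {
  cfg <- list(
    scan = scan_params(),
    n_sets = 1000L,
    seed = 1L,
    windows = c(annotation = 0, pfh1 = 300, cdc20 = 300, gh2a = 5000),
    robustness_windows = c(0, 500),
    q_threshold = 0.05,
    p_mode = "add-one")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_g4("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "g4_config")
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version and input
#' file checksums so deterministic stages can be re-run bit-for-bit and
#' stochastic ones seed-for-seed.
#'
#' @param path output JSON path.
#' @param config a [g4_config()] (or any list).
#' @param inputs character vector of input file paths (md5-summed).
#' @param extra optional named list of extra fields.
#' @export
write_manifest <- function(path, config, inputs = character(), extra = list()) {
  cfg <- unclass(config)
  cfg$scan <- unclass(cfg$scan)
  manifest <- c(list(
    package = "g4screen",
    version = as.character(packageVersion("g4screen")),
    config = cfg,
    inputs = as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
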