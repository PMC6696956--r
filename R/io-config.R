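#' Default run configuration
#'
#' A single JSON-serialisable document holding the seed and per-module
#' parameter blocks at their documented defaults. Every pipeline run logs
#' the resolved configuration and seed to stderr.
#'
#' @param seed integer seed driving all randomness.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  assert_scalar_number(seed, "seed")
  structure(list(
    seed = as.integer(seed),
    synthetic = list(genome_length = 200000, gc = 0.45,
                     background_depth = 10, overdispersion = 10,
                     qpcr_noise_sd = 0.15),
    att = list(window = 1000, min_core_len = 10),
    enrichment = list(min_fold = 3, min_len = 5000, smooth_window = 501,
                      merge_gap = 1000, background_stat = "median"),
    qpcr = list(r2_threshold = 0.95, slope = -3.3219, intercept = 20,
                n_standards = 5),
    competition = list(dilution_factor = 200, cycles = 12,
                       spi_rate = list(wt = 0.006, delta = 0)),
    compare = list(k = 21, sketch_size = 1000, mash_hit_threshold = 70,
                   ani_fragment_len = 1020, ani_species_threshold = 85)
  ), class = "run_config")
}

#' Read / write a JSON run configuration
#'
#' Values present in the file override the documented defaults; everything
#' else is filled in from [default_run_config()].
#'
#' @param path path to the JSON document.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  for (block in intersect(names(user), names(cfg))) {
    if (block == "seed") next
    for (key in names(user[[block]])) cfg[[block]][[key]] <- user[[block]][[key]]
  }
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config` list.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

validate_run_config <- function(cfg) {
  assert_scalar_number(cfg$seed, "seed")
  assert_scalar_number(cfg$synthetic$gc, "synthetic$gc", min = 0, max = 1)
  assert_scalar_number(cfg$synthetic$background_depth,
                       "synthetic$background_depth", min = 1e-9)
  assert_scalar_number(cfg$enrichment$min_fold, "enrichment$min_fold", min = 1)
  assert_scalar_number(cfg$competition$dilution_factor,
                       "competition$dilution_factor", min = 1 + 1e-9)
  assert_scalar_number(cfg$qpcr$r2_threshold, "qpcr$r2_threshold",
                       min = 0, max = 1)
  invisible(cfg)
}
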