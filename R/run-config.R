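#' Read a pipeline run configuration from YAML
#'
#' A run configuration bundles everything `run_pipeline()` needs into a
#' file: the data directory (and optional schema column mapping), filter
#' thresholds, sampler settings for both models, seeds, the no-controls
#' toggle and an output directory. Every field is optional; defaults match
#' the function defaults.
#'
#' ```yaml
#' data_dir: path/to/tables
#' out_dir: results
#' no_controls: true
#' sdt: {chains: 4, iter: 2000, warmup: 500, seed: 1}
#' zoib: {chains: 2, iter: 1500, adapt: 800, seed: 2}
#' schema:
#'   detection_trials: {resp: say_true}
#' ```
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML run configurations requires the yaml package",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) raw <- list()
  cfg <- utils::modifyList(
    list(data_dir = NULL, out_dir = NULL, no_controls = FALSE,
         sdt = list(), zoib = list(), schema = NULL),
    raw
  )
  if (is.null(cfg$data_dir)) {
    stop("run configuration must name a data_dir", call. = FALSE)
  }
  cfg$sdt <- do.call(sdt_control, cfg$sdt)
  cfg$zoib <- do.call(zoib_control, cfg$zoib)
  if (!is.null(cfg$schema)) {
    cfg$schema <- lapply(cfg$schema, unlist)
  }
  structure(cfg, class = "run_config")
}

#' Run the pipeline from a YAML configuration
#'
#' @param config path to a YAML file or a [read_run_config()] result.
#' @param quiet suppress stage messages.
#' @return The [run_pipeline()] result.
#' @export
run_pipeline_config <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  study <- read_study_tables(config$data_dir, schema = config$schema)
  run_pipeline(study, out_dir = config$out_dir,
               no_controls = isTRUE(config$no_controls),
               sdt_ctrl = config$sdt, zoib_ctrl = config$zoib,
               quiet = quiet)
}
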