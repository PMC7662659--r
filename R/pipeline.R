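# Config-driven orchestration of the full workflow:
# trim -> denoise -> split -> select (on train) -> train -> evaluate.

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' `input` is either a path to a wide-CSV dataset or a [synthetic_spec()];
#' `config` may also be loaded from a YAML/JSON file via
#' [read_pipeline_config()]. Validation refuses unresolvable task/classifier
#' cells, in particular the BPNN classifier on the full spectral range.
#'
#' @param input dataset path or a `synthetic_spec`.
#' @param trim `c(lo, hi)` trim window, or `NULL` to skip.
#' @param wavelet a [wavelet_config()], or `NULL` to skip denoising.
#' @param selection character vector of variable inputs to run, from
#'   `"full"`, `"uve_spa"`, `"ga_pls"`.
#' @param classifiers character vector of classifier kinds.
#' @param parameters optional named list kind -> headline parameter.
#' @param tasks character vector from `"origins"`, `"varieties_within"`,
#'   `"all_varieties"`; `"varieties_within"` runs once per origin.
#' @param partition_seed seed for the stratified split.
#' @param seed seed for selection and classifier training.
#' @param selection_args named list (per variable input) of extra selection
#'   arguments, e.g. `list(ga_pls = list(config = ga_pls_config(...)))`.
#' @param use_design_counts use the design's `n_train` column for the split
#'   when the input is synthetic (default TRUE).
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = synthetic_spec(),
                            trim = c(700, 3450),
                            wavelet = wavelet_config(),
                            selection = c("uve_spa", "ga_pls"),
                            classifiers = c("ELM", "RF", "RBF", "PLSDA",
                                            "BPNN"),
                            parameters = list(),
                            tasks = c("origins", "varieties_within",
                                      "all_varieties"),
                            partition_seed = 1L, seed = 1L,
                            selection_args = list(),
                            use_design_counts = TRUE,
                            output_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  ok_sel <- c("full", "uve_spa", "ga_pls")
  bad <- setdiff(config$selection, ok_sel)
  if (length(bad)) abort(paste0("unknown selection method: ", bad[1]))
  config$classifiers <- toupper(config$classifiers)
  bad <- setdiff(config$classifiers, c("ELM", "RF", "RBF", "PLSDA", "BPNN"))
  if (length(bad)) abort(paste0("unknown classifier: ", bad[1]))
  bad <- setdiff(config$tasks,
                 c("origins", "varieties_within", "all_varieties"))
  if (length(bad)) abort(paste0("unknown task: ", bad[1]))
  if ("BPNN" %in% config$classifiers && "full" %in% config$selection) {
    abort("invalid config: BPNN with the full spectral range is not supported")
  }
  if (is.character(config$input) && !file.exists(config$input)) {
    abort(paste0("input file not found: ", config$input))
  }
  config
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields mirror the arguments of [pipeline_config()]; `input` may be
#' a file path or the string `"synthetic"`, and `wavelet` a mapping with
#' `basis`/`level`/`threshold_rule` keys.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!length(path) || !nzchar(path) || !file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  args$input <- if (identical(raw$input, "synthetic") || is.null(raw$input)) {
    do.call(synthetic_spec, raw$synthetic %||% list())
  } else {
    raw$input
  }
  if (!is.null(raw$trim)) args$trim <- as.numeric(raw$trim)
  if (!is.null(raw$wavelet)) {
    args$wavelet <- do.call(wavelet_config, raw$wavelet)
  }
  for (f in c("selection", "classifiers", "tasks")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  for (f in c("partition_seed", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- as.integer(raw[[f]])
  }
  if (!is.null(raw$output_dir)) args$output_dir <- raw$output_dir
  do.call(pipeline_config, args)
}

#' Run the full classification workflow
#'
#' Stages: load or generate -> trim -> denoise -> stratified split ->
#' wavelength selection fitted on the training rows (once per task and
#' variable input) -> classifier training -> test-set evaluation. Artifacts
#' (report table CSV, partition JSON, manifest JSON) are written to
#' `config$output_dir` when set. Rerunning with an identical config
#' reproduces all outputs: every stochastic stage consumes only the recorded
#' seeds.
#'
#' @param config a [pipeline_config()].
#' @return list with `reports` (list of `eval_report`), `table` (tibble from
#'   [build_report_tables()]), `partition`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  data <- stage("load", {
    if (is.character(config$input)) read_spectra(config$input)
    else generate_spectra(config$input)
  })
  if (!is.null(config$trim)) {
    data <- stage("trim", trim_range(data, config$trim[1], config$trim[2]))
  }
  if (!is.null(config$wavelet)) {
    data <- stage("denoise", denoise_spectra(data, config$wavelet))
  }
  n_train_counts <- NULL
  if (config$use_design_counts && inherits(config$input, "synthetic_spec") &&
      "n_train" %in% names(config$input$design)) {
    d <- config$input$design
    n_train_counts <- stats::setNames(d$n_train, d$variety)
  }
  partition <- stage("split", stratified_split(
    data, seed = config$partition_seed, n_train = n_train_counts))
  cells <- tidyr::expand_grid(
    task = config$tasks, variable_input = config$selection,
    classifier = config$classifiers) |>
    dplyr::filter(!(.data$classifier == "BPNN" &
                      .data$variable_input == "full"))
  cells <- dplyr::bind_rows(purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    if (row$task == "varieties_within") {
      tidyr::expand_grid(row[, c("variable_input", "classifier")],
                         task = "varieties_within",
                         origin = unique(data$origin))
    } else {
      dplyr::mutate(row, origin = NA_character_)
    }
  }))
  # fit each selection once per (task, origin, variable_input) and share it
  # across classifiers through run_task's deterministic seeding
  reports <- purrr::map(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    stage(paste("evaluate", row$task, row$variable_input, row$classifier),
          run_task(
            data, task = row$task, variable_input = row$variable_input,
            classifier = row$classifier,
            origin = if (is.na(row$origin)) NULL else row$origin,
            parameter = config$parameters[[row$classifier]],
            partition = partition,
            selection_args =
              config$selection_args[[row$variable_input]] %||% list(),
            seed = config$seed))
  })
  table <- build_report_tables(reports)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mirwalnut")),
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    partition_seed = config$partition_seed, seed = config$seed,
    n_samples = nrow(data), n_variables = length(wavenumbers(data)),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_table(table, file.path(config$output_dir, "reports.csv"))
    write_partition(partition, file.path(config$output_dir,
                                         "partition.json"))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(reports = reports, table = table, partition = partition,
       manifest = manifest)
}
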