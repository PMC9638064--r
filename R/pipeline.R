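#' Default pipeline configuration
#'
#' Builds the declarative configuration [run_pipeline()] consumes.
#' Either `input` (paths to an on-disk dataset) or `synthetic` (a
#' [synthetic_spec()]) must be supplied. Every choice the method leaves
#' open surfaces here: normalization scale, gene prefilter,
#' discretization width, ranking depth, IFS depth, SVM cost.
#'
#' @param input `NULL`, or
#'   `list(matrix_path=, annotation_path=, format=)` for
#'   [read_dataset()].
#' @param synthetic `NULL`, or a [synthetic_spec()].
#' @param train_patients patient IDs for the training cohort; default
#'   `"P1"` (the simulator's first patient).
#' @param normalize apply [normalize_counts()] (default TRUE).
#' @param scale library-size target for normalization.
#' @param min_cells_frac gene prefilter threshold ([filter_genes()]).
#' @param sigma_factor discretization width ([discretize()]).
#' @param top_n ranking depth ([mrmr_rank()]), default 50.
#' @param K IFS depth ([build_ifs_curve()]); defaults to `top_n`.
#' @param cost SVM cost parameter.
#' @param seed seed recorded in the report (the synthetic spec carries
#'   its own generation seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            train_patients = "P1",
                            normalize = TRUE, scale = 1e4,
                            min_cells_frac = 0.01, sigma_factor = 0.5,
                            top_n = 50, K = top_n, cost = 1, seed = 0) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of `input` or `synthetic` must be given")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the arguments of [pipeline_config()]; a `synthetic`
#' block holds [synthetic_spec()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_config() needs the yaml package")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  }
  do.call(pipeline_config, raw)
}

#' Run the full marker-discovery pipeline
#'
#' Executes read/generate, normalize, gene filter, cohort split, mRMR
#' ranking on the training cohort, the IFS/LOOCV curve, peak-panel
#' selection, and cross-patient validation. With `outdir` set, writes
#' `ranking.tsv`, `ifs_curve.tsv`, `panel.tsv` and `report.json`.
#' Deterministic given the configuration: two runs with the same config
#' produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()] (or a YAML path for
#'   [read_config()]).
#' @param outdir optional output directory for artifacts.
#' @param verbose emit stage progress messages.
#' @return The [validate_panel()] `CohortReport`, with extra elements
#'   `ranking`, `curve`, `selection` and `truth` (ground truth when the
#'   input was synthetic).
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  ds <- stage("input", {
    if (!is.null(config$synthetic)) {
      say("generating synthetic dataset")
      gen <- generate_dataset(config$synthetic)
      truth <- gen$truth
      gen$dataset
    } else {
      say("reading ", config$input$matrix_path)
      do.call(read_dataset, config$input)
    }
  })
  if (config$normalize) {
    say("normalizing (scale = ", config$scale, ")")
    ds <- stage("normalize", normalize_counts(ds, scale = config$scale))
  }
  ds <- stage("filter", filter_genes(ds, config$min_cells_frac))
  say(length(ds$gene_ids), " genes after filtering")
  split <- stage("split", split_cohorts(ds, config$train_patients))
  train <- split$train
  say("training cohort: ", length(train$cell_ids), " cells; ",
      length(split$validation), " validation patient(s)")

  dm <- stage("discretize", discretize(train, config$sigma_factor))
  top_n <- min(config$top_n, length(train$gene_ids))
  say("mRMR ranking (top ", top_n, ")")
  ranking <- stage("mrmr", mrmr_rank(dm, tissue_labels(train), top_n))
  K <- min(config$K, top_n)
  say("IFS curve over k = 1..", K)
  curve <- stage("ifs", build_ifs_curve(train, ranking, K = K,
                                        cost = config$cost,
                                        verbose = verbose))
  selection <- stage("select", select_optimal_panel(curve))
  say("selected k_opt = ", selection$k_opt,
      " (LOOCV MCC ", sprintf("%.4f", selection$mcc_opt), ")")
  report <- stage("validate", {
    validate_panel(train, split$validation, selection$panel,
                   cost = config$cost,
                   config = config_snapshot(config), seed = config$seed)
  })
  report$ranking <- ranking
  report$curve <- curve
  report$selection <- selection
  report$truth <- truth

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_ranking_tsv(ranking, file.path(outdir, "ranking.tsv"))
    write_ifs_tsv(curve, file.path(outdir, "ifs_curve.tsv"))
    data.table::fwrite(
      data.table::data.table(rank = seq_along(selection$panel),
                             gene_id = selection$panel),
      file.path(outdir, "panel.tsv"), sep = "\t")
    write_report(report, file.path(outdir, "report.json"))
    say("artifacts written to ", outdir)
  }
  report
}

## plain-list config for embedding in the JSON report
config_snapshot <- function(config) {
  snap <- unclass(config)
  if (!is.null(snap$synthetic)) snap$synthetic <- unclass(snap$synthetic)
  snap
}
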