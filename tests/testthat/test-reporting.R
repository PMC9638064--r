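test_that("cohort validation pools per-patient counts exactly", {
  prep <- prepared_small(seed = 33, cells_per_patient_per_class = 30)
  rel <- relevance_scores(discretize(prep$split$train),
                          tissue_labels(prep$split$train))
  panel <- names(sort(rel, decreasing = TRUE))[1:5]
  rep <- validate_panel(prep$split$train, prep$split$validation, panel)
  expect_s3_class(rep, "CohortReport")
  expect_equal(nrow(rep$per_patient), 2)
  expect_equal(rep$pooled$counts$TP, sum(rep$per_patient$TP))
  expect_equal(rep$pooled$counts$FN, sum(rep$per_patient$FN))
  expect_equal(sum(unlist(rep$pooled$counts[c("TP", "TN", "FP", "FN")])),
               sum(lengths(lapply(prep$split$validation, `[[`, "cell_ids"))))
  # training resubstitution is reported too
  expect_equal(sum(unlist(rep$train$counts[c("TP", "TN", "FP", "FN")])),
               length(prep$split$train$cell_ids))

  empty <- validate_panel(prep$split$train, list(), panel)
  expect_equal(nrow(empty$per_patient), 0)
  expect_true(is.na(empty$pooled$mcc))
  expect_error(validate_panel(prep$split$train, prep$split$validation,
                              c(panel, "NOPE")),
               "absent from validation patient.*NOPE")
})

test_that("a single-class validation patient reports MCC 0 with a warning", {
  prep <- prepared_small(seed = 37, cells_per_patient_per_class = 20)
  v1 <- prep$split$validation[[1]]
  tumor_only <- scmrmr:::subset_cells(v1, v1$annotations$tissue == "tumor")
  panel <- prep$split$train$gene_ids[1:4]
  expect_warning(
    rep <- validate_panel(prep$split$train, list(PX = tumor_only), panel),
    "single tissue class")
  expect_equal(rep$per_patient$mcc, 0)
})

test_that("report JSON round-trips all counts exactly", {
  prep <- prepared_small(seed = 39, cells_per_patient_per_class = 20)
  panel <- prep$split$train$gene_ids[1:4]
  rep <- validate_panel(prep$split$train, prep$split$validation, panel,
                        config = list(cost = 1), seed = 39)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$panel, rep$panel)
  expect_equal(back$train$counts$TP, rep$train$counts$TP)
  expect_equal(back$pooled$counts$FP, rep$pooled$counts$FP)
  expect_equal(back$per_patient$TN, rep$per_patient$TN)
  expect_equal(back$per_patient$mcc, rep$per_patient$mcc, tolerance = 1e-15)
  expect_equal(back$seed, 39)
})

test_that("the QC embedding is seeded, shaped and separates the classes", {
  skip_if_not_installed("Rtsne")
  prep <- prepared_small(seed = 43, cells_per_patient_per_class = 40)
  train <- prep$split$train
  panel <- intersect(prep$truth$marker_gene_ids, train$gene_ids)
  actual <- tissue_labels(train)
  emb1 <- embed_cells_qc(train, panel, actual, actual, seed = 7,
                         perplexity = 10)
  expect_equal(nrow(emb1), length(train$cell_ids))
  expect_equal(names(emb1), c("cell_id", "tsne1", "tsne2",
                              "predicted", "actual"))
  emb2 <- embed_cells_qc(train, panel, actual, actual, seed = 7,
                         perplexity = 10)
  expect_identical(emb1, emb2)
  xy <- as.matrix(emb1[, c("tsne1", "tsne2")])
  c1 <- colMeans(xy[actual == 1, ])
  c0 <- colMeans(xy[actual == 0, ])
  spread <- mean(c(sqrt(rowSums(sweep(xy[actual == 1, ], 2, c1)^2)),
                   sqrt(rowSums(sweep(xy[actual == 0, ], 2, c0)^2))))
  expect_gt(sqrt(sum((c1 - c0)^2)), spread)
  expect_error(embed_cells_qc(train, panel, actual, actual, perplexity = 1e4),
               "perplexity")
})

test_that("the pipeline is byte-reproducible and labels failing stages", {
  spec <- small_spec(seed = 47, cells_per_patient_per_class = 20)
  cfg <- pipeline_config(synthetic = spec, top_n = 10, K = 6, seed = 47)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- suppressMessages(run_pipeline(cfg, outdir = d1))
  r2 <- suppressMessages(run_pipeline(cfg, outdir = d2))
  for (f in c("ranking.tsv", "ifs_curve.tsv", "panel.tsv", "report.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_equal(r1$selection$k_opt, r2$selection$k_opt)

  bad <- pipeline_config(input = list(matrix_path = "/nonexistent.mtx",
                                      annotation_path = "/nonexistent.csv"),
                         train_patients = "P1")
  expect_error(suppressMessages(run_pipeline(bad)), "stage 'input'")
  expect_error(pipeline_config(), "exactly one")
})

test_that("a YAML configuration drives the same run as the R API", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synthetic:",
               "  n_patients: 2",
               "  cells_per_patient_per_class: 20",
               "  n_genes: 60",
               "  n_markers: 4",
               "  marker_log2fc: 3",
               "  n_redundant_blocks: 0",
               "  block_size: 1",
               "  seed: 53",
               "top_n: 8",
               "K: 5",
               "seed: 53"), path)
  cfg <- read_config(path)
  expect_s3_class(cfg, "pipeline_config")
  r_yaml <- suppressMessages(run_pipeline(cfg))
  cfg_r <- pipeline_config(
    synthetic = synthetic_spec(n_patients = 2, cells_per_patient_per_class = 20,
                               n_genes = 60, n_markers = 4, marker_log2fc = 3,
                               n_redundant_blocks = 0, block_size = 1,
                               seed = 53),
    top_n = 8, K = 5, seed = 53)
  r_api <- suppressMessages(run_pipeline(cfg_r))
  expect_identical(r_yaml$selection, r_api$selection)
  expect_identical(r_yaml$per_patient, r_api$per_patient)
})
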