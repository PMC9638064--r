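test_that("dense CSV fixture round-trips with annotations attached", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id,c1,c2,c3,c4",
               "gA,0,2,4,0",
               "gB,1,1,1,1",
               "gC,5,0,0,3"),
             file.path(dir, "matrix.csv"))
  writeLines(c("cell_id,patient_id,tissue",
               "c1,P1,tumor", "c2,P1,normal", "c3,P2,tumor", "c4,P2,normal"),
             file.path(dir, "annotations.csv"))
  ds <- read_dataset(file.path(dir, "matrix.csv"),
                     file.path(dir, "annotations.csv"),
                     format = "dense_csv")
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(ds$gene_ids, c("gA", "gB", "gC"))
  expect_equal(ds$annotations$patient_id, c("P1", "P1", "P2", "P2"))
  expect_false(ds$normalized)
  expect_equal(unname(as.matrix(ds$values)["gC", ]), c(5, 0, 0, 3))
})

test_that("mtx triplet entries absent from the file are zeros", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 4 2",
               "1 2 7",
               "3 4 9"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2", "c3", "c4"), file.path(dir, "barcodes.tsv"))
  writeLines(c("cell_id,patient_id,tissue",
               "c1,P1,tumor", "c2,P1,normal", "c3,P1,tumor", "c4,P1,normal"),
             file.path(dir, "annotations.csv"))
  ds <- read_dataset(file.path(dir, "matrix.mtx"),
                     file.path(dir, "annotations.csv"),
                     format = "mtx_triplet")
  m <- as.matrix(ds$values)
  expect_equal(sum(m != 0), 2)
  expect_equal(m["gA", "c2"], 7)
  expect_equal(m["gC", "c4"], 9)
  expect_equal(sum(m == 0), 10)
})

test_that("write/read round trip is value-exact for both formats", {
  gen <- generate_dataset(small_spec(seed = 3))
  for (fmt in c("mtx_triplet", "dense_csv")) {
    dir <- withr::local_tempdir()
    write_dataset(gen$dataset, dir, format = fmt)
    mat <- file.path(dir, if (fmt == "mtx_triplet") "matrix.mtx" else "matrix.csv")
    back <- read_dataset(mat, file.path(dir, "annotations.csv"), format = fmt)
    # value-exact (storage mode may legitimately differ between formats)
    expect_true(all(as.matrix(back$values) == as.matrix(gen$dataset$values)))
    expect_identical(dimnames(back$values), dimnames(gen$dataset$values))
    expect_identical(back$annotations, gen$dataset$annotations)
  }
})

test_that("malformed inputs fail loudly and name the problem", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id,c1,c2", "gA,1,2", "gA,3,4"), file.path(dir, "dup.csv"))
  writeLines(c("cell_id,patient_id,tissue", "c1,P1,tumor", "c2,P1,normal"),
             file.path(dir, "ann.csv"))
  expect_error(read_dataset(file.path(dir, "dup.csv"), file.path(dir, "ann.csv"),
                            format = "dense_csv"),
               "duplicate gene IDs: gA")

  writeLines(c("gene_id,c1,c2,c3", "gA,1,2,3"), file.path(dir, "wide.csv"))
  expect_error(read_dataset(file.path(dir, "wide.csv"), file.path(dir, "ann.csv"),
                            format = "dense_csv"),
               "3 cells.*2 rows")

  writeLines(c("cell_id,patient_id,tissue", "c1,P1,tumour", "c2,P1,normal"),
             file.path(dir, "bad.csv"))
  writeLines(c("gene_id,c1,c2", "gA,1,2"), file.path(dir, "ok.csv"))
  expect_error(read_dataset(file.path(dir, "ok.csv"), file.path(dir, "bad.csv"),
                            format = "dense_csv"),
               "unknown tissue")
})

test_that("normalization matches the scalar formula and drops empty cells", {
  m <- matrix(c(10, 10,
                90, 190),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  ann <- data.frame(cell_id = c("c1", "c2"), patient_id = "P1",
                    tissue = c("tumor", "normal"), stringsAsFactors = FALSE)
  ds <- normalize_counts(ExpressionDataset(m, ann))
  v <- as.matrix(ds$values)
  # same raw count, smaller library -> larger normalized value
  expect_equal(v["gA", "c1"], log(1 + 10 * 1e4 / 100))
  expect_equal(v["gA", "c2"], log(1 + 10 * 1e4 / 200))
  expect_gt(v["gA", "c1"], v["gA", "c2"])
  expect_true(ds$normalized)
  expect_error(normalize_counts(ds), "already normalized")

  m2 <- cbind(m, c3 = c(0, 0))
  ann2 <- rbind(ann, data.frame(cell_id = "c3", patient_id = "P1",
                                tissue = "tumor"))
  expect_warning(ds2 <- normalize_counts(ExpressionDataset(m2, ann2)),
                 "zero total count")
  expect_equal(ds2$cell_ids, c("c1", "c2"))
})

test_that("normalization maps zeros to zero and preserves within-cell order", {
  gen <- generate_dataset(small_spec(seed = 5))
  nds <- normalize_counts(gen$dataset)
  raw <- as.matrix(gen$dataset$values)[, nds$cell_ids]
  nrm <- as.matrix(nds$values)
  expect_true(all(nrm[raw == 0] == 0))
  for (j in c(1, 17, 40)) {
    expect_equal(order(nrm[, j]), order(raw[, j]))
  }
})

test_that("gene filter keeps boundary genes and matches a brute-force recount", {
  # gene in exactly 1 of 100 cells survives at the 1% threshold
  m <- matrix(0, 2, 100, dimnames = list(c("gA", "gB"), sprintf("c%d", 1:100)))
  m["gA", 1] <- 1
  m["gB", ] <- 2
  ann <- data.frame(cell_id = colnames(m), patient_id = "P1",
                    tissue = rep(c("tumor", "normal"), 50),
                    stringsAsFactors = FALSE)
  ds <- ExpressionDataset(m, ann)
  expect_message(kept <- filter_genes(ds, 0.01), "kept 2 of 2")
  expect_equal(kept$gene_ids, c("gA", "gB"))
  # threshold 0 is the identity
  expect_message(all_kept <- filter_genes(ds, 0), "kept 2 of 2")
  expect_equal(all_kept$gene_ids, ds$gene_ids)

  gen <- generate_dataset(small_spec(seed = 7, dropout_extra = 0.4))
  frac <- 0.25
  expect_message(f <- filter_genes(gen$dataset, frac), "kept")
  counts <- as.matrix(gen$dataset$values)
  survivors <- rownames(counts)[
    rowSums(counts > 0) >= ceiling(frac * ncol(counts))]
  expect_identical(f$gene_ids, survivors)

  # no gene reaches 100% detection here -> everything would be removed
  m3 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("gX", "gY"), c("c1", "c2")))
  ds3 <- ExpressionDataset(m3, data.frame(cell_id = c("c1", "c2"),
                                          patient_id = "P1",
                                          tissue = c("tumor", "normal")))
  expect_error(filter_genes(ds3, 1), "removed all")
})

test_that("cohort split partitions cells and keeps gene order", {
  prep <- prepared_small(seed = 9)
  sp <- prep$split
  all_cells <- c(sp$train$cell_ids,
                 unlist(lapply(sp$validation, `[[`, "cell_ids")))
  expect_setequal(all_cells, prep$ds$cell_ids)
  expect_equal(length(all_cells), length(unique(all_cells)))
  expect_equal(names(sp$validation), c("P2", "P3"))
  for (v in sp$validation) expect_identical(v$gene_ids, prep$ds$gene_ids)
  # counts agree with generator bookkeeping
  expect_equal(length(sp$train$cell_ids),
               unname(prep$truth$cells_per_patient[["P1"]]))
  expect_equal(length(sp$validation$P2$cell_ids),
               unname(prep$truth$cells_per_patient[["P2"]]))

  everyone <- split_cohorts(prep$ds, c("P1", "P2", "P3"))
  expect_length(everyone$validation, 0)
  expect_error(split_cohorts(prep$ds, "P9"), "unknown patient")
})

test_that("a single-tissue validation patient triggers a warning", {
  ds <- tiny_dataset()
  ds$annotations$tissue <- c("tumor", "normal", "tumor", "tumor")
  ds2 <- ExpressionDataset(ds$values, ds$annotations)
  expect_warning(split_cohorts(ds2, "P1"), "only 'tumor' cells")
})
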