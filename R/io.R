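#' Read a labelled expression matrix from disk
#'
#' Supports the 10x-style Matrix Market triplet layout (`matrix.mtx` with
#' `features.tsv` and `barcodes.tsv` next to it, 1-based indices, entries
#' absent from the triplet file are zeros) and a dense delimited layout
#' (genes as rows, first column gene IDs, header row of cell barcodes).
#' Cells are returned in the order of the annotation table.
#'
#' @param matrix_path path to the `.mtx` file or the dense CSV/TSV.
#' @param annotation_path CSV with columns `cell_id`, `patient_id`,
#'   `tissue` (`tumor`/`normal`).
#' @param format `"mtx_triplet"` or `"dense_csv"`.
#' @param features_path,barcodes_path override the default
#'   `features.tsv` / `barcodes.tsv` located next to the `.mtx` file.
#' @return An [ExpressionDataset()] with `normalized = FALSE`.
#' @export
read_dataset <- function(matrix_path, annotation_path,
                         format = c("mtx_triplet", "dense_csv"),
                         features_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(annotation_path)) stop("annotation file not found: ", annotation_path)

  if (format == "mtx_triplet") {
    dir <- dirname(matrix_path)
    if (is.null(features_path)) features_path <- file.path(dir, "features.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    if (!file.exists(features_path)) stop("features file not found: ", features_path)
    if (!file.exists(barcodes_path)) stop("barcodes file not found: ", barcodes_path)
    m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    genes <- data.table::fread(features_path, header = FALSE, sep = "\t")[[1]]
    cells <- data.table::fread(barcodes_path, header = FALSE, sep = "\t")[[1]]
    if (nrow(m) != length(genes)) {
      stop("matrix declares ", nrow(m), " genes but features file lists ",
           length(genes))
    }
    if (ncol(m) != length(cells)) {
      stop("matrix declares ", ncol(m), " cells but barcodes file lists ",
           length(cells))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    dt <- data.table::fread(matrix_path, header = TRUE)
    genes <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- genes
  }

  ann <- as.data.frame(data.table::fread(annotation_path,
                                         colClasses = "character"))
  if (nrow(ann) != ncol(m)) {
    stop("matrix has ", ncol(m), " cells but annotation table has ",
         nrow(ann), " rows")
  }
  missing_cells <- setdiff(ann$cell_id, colnames(m))
  if (length(missing_cells) > 0) {
    stop("annotation lists barcode(s) absent from the matrix: ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  m <- m[, ann$cell_id, drop = FALSE]
  ExpressionDataset(m, ann, normalized = FALSE)
}

#' Write a dataset to disk
#'
#' Inverse of [read_dataset()]: writes either `matrix.mtx` +
#' `features.tsv` + `barcodes.tsv` or a dense `matrix.csv`, plus
#' `annotations.csv`, into `dir`.
#'
#' @param ds an [ExpressionDataset()].
#' @param dir output directory (created if absent).
#' @param format `"mtx_triplet"` or `"dense_csv"`.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir, format = c("mtx_triplet", "dense_csv")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "ExpressionDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann_path <- file.path(dir, "annotations.csv")
  data.table::fwrite(ds$annotations, ann_path)
  if (format == "mtx_triplet") {
    mtx_path <- file.path(dir, "matrix.mtx")
    m <- methods::as(methods::as(ds$values, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(m, mtx_path)
    writeLines(ds$gene_ids, file.path(dir, "features.tsv"))
    writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
    paths <- c(mtx_path, file.path(dir, c("features.tsv", "barcodes.tsv")), ann_path)
  } else {
    mtx_path <- file.path(dir, "matrix.csv")
    dt <- data.table::data.table(gene_id = ds$gene_ids)
    dt <- cbind(dt, as.data.frame(as.matrix(ds$values)))
    data.table::fwrite(dt, mtx_path)
    paths <- c(mtx_path, ann_path)
  }
  invisible(paths)
}
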