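#' Labelled single-cell expression dataset
#'
#' Container for a genes x cells expression matrix together with per-cell
#' annotations. Rows are genes, columns are cells. Raw counts are
#' non-negative integers; after [normalize_counts()] the values are
#' non-negative reals and the `normalized` flag is set. The positive class
#' throughout the package is `"tumor"`: a true positive is a tumor cell
#' called tumor.
#'
#' @param values genes x cells numeric matrix, dense or a
#'   [Matrix::sparseMatrix()]. Row names (gene IDs) and column names (cell
#'   barcodes) are required and must be unique.
#' @param annotations data.frame with columns `cell_id`, `patient_id` and
#'   `tissue` (values `"tumor"` or `"normal"`), one row per cell, in the
#'   same order as the matrix columns.
#' @param normalized logical flag; `FALSE` for raw counts.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `annotations`, `normalized`.
#' @export
ExpressionDataset <- function(values, annotations, normalized = FALSE) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene IDs as rownames and cell barcodes as colnames")
  }
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell barcodes")
  }
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  req <- c("cell_id", "patient_id", "tissue")
  missing_cols <- setdiff(req, names(annotations))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(annotations) != ncol(values)) {
    stop("matrix has ", ncol(values), " cells but annotation table has ",
         nrow(annotations), " rows")
  }
  if (!all(annotations$cell_id == cell_ids)) {
    stop("annotation cell_id order does not match matrix columns")
  }
  bad <- setdiff(unique(annotations$tissue), c("tumor", "normal"))
  if (length(bad) > 0) {
    stop("unknown tissue value(s): ", paste(bad, collapse = ", "),
         " (expected 'tumor' or 'normal')")
  }
  if (!normalized) {
    v <- if (methods::is(values, "sparseMatrix")) values@x else values
    if (any(v < 0) || any(v != round(v))) {
      stop("raw counts must be non-negative integers")
    }
  }
  structure(
    list(values = values,
         gene_ids = gene_ids,
         cell_ids = cell_ids,
         annotations = annotations,
         normalized = isTRUE(normalized)),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  nt <- sum(x$annotations$tissue == "tumor")
  cat(sprintf("ExpressionDataset: %d genes x %d cells (%d tumor / %d normal), %d patient(s), %s\n",
              length(x$gene_ids), length(x$cell_ids),
              nt, length(x$cell_ids) - nt,
              length(unique(x$annotations$patient_id)),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Binary tissue labels of a dataset
#'
#' @param ds an [ExpressionDataset()].
#' @return Integer vector, one per cell: 1 for tumor (positive class),
#'   0 for normal.
#' @export
tissue_labels <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  as.integer(ds$annotations$tissue == "tumor")
}

## column subset keeping annotations in step
subset_cells <- function(ds, idx) {
  ExpressionDataset(ds$values[, idx, drop = FALSE],
                    ds$annotations[idx, , drop = FALSE],
                    normalized = ds$normalized)
}

## row subset by gene ID or index
subset_genes <- function(ds, genes) {
  ExpressionDataset(ds$values[genes, , drop = FALSE],
                    ds$annotations,
                    normalized = ds$normalized)
}

## dense numeric cells x genes matrix for a gene set (classifier input)
cells_by_genes <- function(ds, genes) {
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing) > 0) {
    stop("gene(s) absent from dataset: ", paste(missing, collapse = ", "))
  }
  t(as.matrix(ds$values[genes, , drop = FALSE]))
}
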