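#' Library-size normalization with log transform
#'
#' Scales each cell to a common library size and applies `log1p`: a raw
#' count `c` in a cell with total count `S` becomes
#' `log(1 + c * scale / S)`. Cells with zero total count are dropped with
#' a warning. The transform is monotone within a cell, so it preserves the
#' per-cell ordering of genes.
#'
#' @param ds an [ExpressionDataset()] holding raw counts.
#' @param scale target library size (default `1e4`, the common convention
#'   for 10x data).
#' @return A normalized [ExpressionDataset()].
#' @export
normalize_counts <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$normalized) stop("dataset is already normalized")
  if (!(is.numeric(scale) && length(scale) == 1 && scale > 0)) {
    stop("`scale` must be a positive number")
  }
  totals <- Matrix::colSums(ds$values)
  empty <- totals == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero total count dropped: ",
            paste(utils::head(ds$cell_ids[empty], 5), collapse = ", "))
    ds <- subset_cells(ds, !empty)
    totals <- totals[!empty]
  }
  v <- ds$values
  if (methods::is(v, "sparseMatrix")) {
    v <- methods::as(v, "CsparseMatrix")
    ## column scaling on the nonzero slots only; zeros map to log1p(0) = 0
    col_of <- rep.int(seq_len(ncol(v)), diff(v@p))
    v@x <- log1p(v@x * scale / totals[col_of])
  } else {
    v <- log1p(sweep(v, 2, scale / totals, `*`))
  }
  ExpressionDataset(v, ds$annotations, normalized = TRUE)
}

#' Drop genes detected in too few cells
#'
#' Keeps genes with a nonzero value in at least
#' `ceiling(min_cells_frac * n_cells)` cells; gene order is preserved.
#' `min_cells_frac = 0` keeps every gene.
#'
#' @param ds an [ExpressionDataset()] (raw or normalized).
#' @param min_cells_frac fraction of cells in `[0, 1]` (default 0.01).
#' @return The filtered [ExpressionDataset()].
#' @export
filter_genes <- function(ds, min_cells_frac = 0.01) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!(is.numeric(min_cells_frac) && length(min_cells_frac) == 1 &&
        min_cells_frac >= 0 && min_cells_frac <= 1)) {
    stop("`min_cells_frac` must be a single number in [0, 1]")
  }
  need <- ceiling(min_cells_frac * length(ds$cell_ids))
  detected <- Matrix::rowSums(ds$values > 0)
  keep <- detected >= need
  if (!any(keep)) {
    stop("gene filter at min_cells_frac = ", min_cells_frac,
         " removed all ", length(keep), " genes")
  }
  message("filter_genes: kept ", sum(keep), " of ", length(keep),
          " genes (removed ", sum(!keep), ")")
  if (all(keep)) ds else subset_genes(ds, which(keep))
}

#' Partition a dataset into a training cohort and per-patient validation sets
#'
#' The training set pools the cells of `train_patients`; every remaining
#' patient becomes one validation dataset. Every cell lands in exactly one
#' output and gene order is identical across all outputs.
#'
#' @param ds an [ExpressionDataset()].
#' @param train_patients character vector of patient IDs to train on.
#' @return List with elements `train` (an [ExpressionDataset()]) and
#'   `validation` (named list of [ExpressionDataset()], one per held-out
#'   patient, names sorted).
#' @export
split_cohorts <- function(ds, train_patients) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (length(train_patients) == 0) stop("`train_patients` must be nonempty")
  patients <- ds$annotations$patient_id
  unknown <- setdiff(train_patients, patients)
  if (length(unknown) > 0) {
    stop("unknown patient ID(s): ", paste(unknown, collapse = ", "))
  }
  train <- subset_cells(ds, patients %in% train_patients)
  rest <- sort(setdiff(unique(patients), train_patients))
  validation <- lapply(rest, function(p) subset_cells(ds, patients == p))
  names(validation) <- rest
  for (p in rest) {
    tiss <- unique(validation[[p]]$annotations$tissue)
    if (length(tiss) < 2) {
      warning("validation patient ", p, " has only '", tiss,
              "' cells; its MCC will be uninformative")
    }
  }
  list(train = train, validation = validation)
}
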