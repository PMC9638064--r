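#' Confusion counts for one binary evaluation
#'
#' Positive class is tumor: TP = tumor called tumor, TN = normal called
#' normal, FP = normal called tumor, FN = tumor called normal.
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return Object of class `ConfusionCounts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "ConfusionCounts")
}

## tally predictions vs actual 0/1 labels
tally_confusion <- function(predicted, actual) {
  confusion_counts(TP = sum(predicted == 1 & actual == 1),
                   TN = sum(predicted == 0 & actual == 0),
                   FP = sum(predicted == 1 & actual == 0),
                   FN = sum(predicted == 0 & actual == 1))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' confusion-matrix correlation in `[-1, 1]`. Unlike accuracy it is not
#' inflated by class imbalance: a majority-class predictor on 90/10
#' labels scores accuracy 0.9 but MCC 0. If any factor of the
#' denominator is zero the MCC is 0 by convention.
#'
#' @param counts a [confusion_counts()] object, or a vector/list with
#'   named elements `TP`, `TN`, `FP`, `FN`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  counts <- unlist(counts[c("TP", "TN", "FP", "FN")])
  if (anyNA(counts)) stop("counts must provide TP, TN, FP and FN")
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero confusion counts")
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  f <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  if (any(f == 0)) return(0)
  ## divide by each sqrt factor in turn: no overflow, full double precision
  (TP * TN - FP * FN) / sqrt(f[1]) / sqrt(f[2]) / sqrt(f[3]) / sqrt(f[4])
}

#' Leave-one-out cross-validated predictions for a gene set
#'
#' Runs exactly N rounds on N cells: round r trains the linear SVM on
#' all cells but r (feature standardization refit inside the fold, so no
#' information from the held-out cell leaks into scaling) and predicts
#' cell r. A fold whose training set contains a single class predicts
#' the training majority class, with a warning. Deterministic given its
#' inputs.
#'
#' @param ds a normalized [ExpressionDataset()].
#' @param gene_set character vector of gene IDs to use as features.
#' @param labels binary labels (1 = tumor); defaults to the dataset's
#'   tissue annotations.
#' @param cost,bias,tol,max_epochs passed to the SVM (see
#'   [fit_classifier()]).
#' @return List: `predicted` (integer 0/1 per cell), `counts`
#'   (a [confusion_counts()]), `mcc`, `n_fits`.
#' @export
loocv_predict <- function(ds, gene_set, labels = tissue_labels(ds),
                          cost = 1, bias = 1, tol = 0.01, max_epochs = 200) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  labels <- as_binary_labels(labels)
  n <- length(ds$cell_ids)
  if (length(labels) != n) stop("labels length does not match cell count")
  if (n < 3) stop("LOOCV needs at least 3 cells")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  X <- cells_by_genes(ds, gene_set)
  ysign <- ifelse(labels == 1L, 1L, -1L)
  res <- cpp_linear_svm_loocv(X, as.integer(ysign), cost, bias, tol, max_epochs)
  if (res$degenerate_folds > 0) {
    warning(res$degenerate_folds,
            " LOOCV fold(s) had a single-class training set; ",
            "majority-class prediction used")
  }
  predicted <- as.integer(res$predicted > 0)
  counts <- tally_confusion(predicted, labels)
  list(predicted = predicted, counts = counts, mcc = mcc(counts),
       n_fits = res$n_fits)
}

#' Build the incremental-feature-selection curve
#'
#' For each k = 1..K evaluates the nested prefix S_k (top-k genes of the
#' mRMR ranking) by [loocv_predict()] and records its confusion counts
#' and MCC - the curve whose peak locates the final panel.
#'
#' @param ds a normalized [ExpressionDataset()] (the training cohort).
#' @param ranking a [mrmr_rank()] result on this cohort.
#' @param K number of prefixes to evaluate (default 50, the conventional
#'   top-50 feature).
#' @param labels binary labels (1 = tumor); defaults to the dataset's
#'   annotations.
#' @param cost SVM cost parameter.
#' @param verbose emit a progress message per k.
#' @return Object of class `IfsCurve`: `table`
#'   (data.frame k/mcc/TP/TN/FP/FN), `genes` (the K ranked genes),
#'   `n_cells`.
#' @export
build_ifs_curve <- function(ds, ranking, K = 50, labels = tissue_labels(ds),
                            cost = 1, verbose = FALSE) {
  stopifnot(inherits(ranking, "MrmrRanking"))
  if (!(K >= 1 && K <= length(ranking$ranked_genes))) {
    stop("`K` must lie in [1, ", length(ranking$ranked_genes), "]")
  }
  K <- as.integer(K)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    res <- loocv_predict(ds, ranking$ranked_genes[seq_len(k)], labels,
                         cost = cost)
    cc <- res$counts
    rows[[k]] <- data.frame(k = k, mcc = res$mcc, TP = cc$TP, TN = cc$TN,
                            FP = cc$FP, FN = cc$FN)
    if (verbose) {
      message(sprintf("IFS k = %d/%d: MCC = %.4f", k, K, res$mcc))
    }
  }
  structure(
    list(table = do.call(rbind, rows),
         genes = ranking$ranked_genes[seq_len(K)],
         n_cells = length(ds$cell_ids)),
    class = "IfsCurve"
  )
}

#' @export
print.IfsCurve <- function(x, ...) {
  best <- which.max(x$table$mcc)
  cat(sprintf("IfsCurve: K = %d over %d cells; best MCC %.4f at k = %d\n",
              nrow(x$table), x$n_cells, x$table$mcc[best], x$table$k[best]))
  invisible(x)
}

#' Pick the optimal panel from an IFS curve
#'
#' Returns the smallest k attaining the global maximum MCC (ties go to
#' the smaller k - use relatively few genes for the same performance)
#' and the corresponding gene panel.
#'
#' @param curve an [build_ifs_curve()] result.
#' @return List: `k_opt`, `panel` (character vector of k_opt genes),
#'   `mcc_opt`.
#' @export
select_optimal_panel <- function(curve) {
  stopifnot(inherits(curve, "IfsCurve"))
  if (nrow(curve$table) == 0) stop("empty IFS curve")
  m <- curve$table$mcc
  k_opt <- curve$table$k[which(m >= max(m) - 1e-12)[1]]
  list(k_opt = k_opt,
       panel = curve$genes[seq_len(k_opt)],
       mcc_opt = m[curve$table$k == k_opt])
}

#' Write an IFS curve as TSV
#'
#' Columns: `k`, `mcc`, `TP`, `TN`, `FP`, `FN`.
#'
#' @param curve an [build_ifs_curve()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ifs_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "IfsCurve"))
  data.table::fwrite(curve$table, path, sep = "\t")
  invisible(path)
}
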