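#' Discretize normalized expression into three states per gene
#'
#' Each gene's values are coded against its pooled mean and standard
#' deviation over all cells (both classes together, so no label
#' information enters the representation): below `mu - sigma_factor*sd`
#' is -1, above `mu + sigma_factor*sd` is +1, otherwise 0. A constant
#' gene (sd = 0) maps entirely to state 0. These ternary codes are the
#' input to the mutual-information estimator.
#'
#' @param ds a normalized [ExpressionDataset()].
#' @param sigma_factor half-width of the middle band in sd units
#'   (default 0.5, the common convention for discretized mRMR on
#'   continuous features).
#' @return Object of class `DiscretizedMatrix`: `states` (genes x cells
#'   integer matrix in \{-1, 0, +1\}), `bin_edges` (per-gene `low`/`high`
#'   thresholds), `gene_ids`, `cell_ids`.
#' @export
discretize <- function(ds, sigma_factor = 0.5) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!ds$normalized) stop("discretize() expects a normalized dataset")
  if (!(is.numeric(sigma_factor) && length(sigma_factor) == 1 && sigma_factor >= 0)) {
    stop("`sigma_factor` must be a single non-negative number")
  }
  x <- as.matrix(ds$values)
  n <- ncol(x)
  mu <- rowMeans(x)
  sdv <- sqrt(rowMeans((x - mu)^2))  # population sd: the band is a descriptive cut
  lo <- mu - sigma_factor * sdv
  hi <- mu + sigma_factor * sdv
  states <- matrix(0L, nrow(x), n, dimnames = dimnames(x))
  states[x < lo] <- -1L
  states[x > hi] <- 1L
  structure(
    list(states = states,
         bin_edges = cbind(low = lo, high = hi),
         gene_ids = ds$gene_ids,
         cell_ids = ds$cell_ids),
    class = "DiscretizedMatrix"
  )
}

## plug-in MI (bits) from small integer codes in 1..nx and 1..ny
mi_codes <- function(x, y, nx, ny) {
  joint <- tabulate((x - 1L) * ny + y, nbins = nx * ny)
  n <- length(x)
  p <- joint / n
  px <- rowSums(matrix(p, nx, ny, byrow = TRUE))
  py <- colSums(matrix(p, nx, ny, byrow = TRUE))
  pp <- as.vector(t(outer(px, py)))  # matches joint's (x-major) layout
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / pp[nz]))
}

#' Mutual information between two discrete vectors
#'
#' Plug-in (maximum-likelihood) estimate in bits from the joint
#' histogram of observed states:
#' `I = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )`, with empty joint cells
#' contributing zero. Symmetric in its arguments and non-negative up to
#' floating error.
#'
#' @param x,y equal-length vectors of discrete states (any integer-like
#'   or factor coding).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: length(x) = ", length(x),
         ", length(y) = ", length(y))
  }
  if (length(x) == 0) stop("vectors must have length >= 1")
  xf <- as.integer(factor(x))
  yf <- as.integer(factor(y))
  mi_codes(xf, yf, max(xf), max(yf))
}

## ternary states (-1/0/1) -> codes 1..3, done once for a whole matrix
ternary_codes <- function(states) states + 2L

#' Per-gene relevance: mutual information with the class label
#'
#' The relevance term D of the mRMR criterion: `D(g) = I(g, t)` between
#' each gene's discretized states and the binary tissue label.
#'
#' @param dm a [discretize()]d matrix.
#' @param labels binary label vector (1 = tumor), one per cell.
#' @return Named numeric vector of relevances in bits.
#' @export
relevance_scores <- function(dm, labels) {
  stopifnot(inherits(dm, "DiscretizedMatrix"))
  labels <- as_binary_labels(labels)
  if (length(labels) != ncol(dm$states)) {
    stop("labels length ", length(labels), " does not match ",
         ncol(dm$states), " cells")
  }
  codes <- ternary_codes(dm$states)
  lab <- labels + 1L
  rel <- vapply(seq_len(nrow(codes)),
                function(g) mi_codes(codes[g, ], lab, 3L, 2L),
                numeric(1))
  stats::setNames(rel, dm$gene_ids)
}

## coerce assorted label encodings to integer 0/1 (1 = tumor/positive)
as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("tumor", "normal"))
    if (length(bad) > 0) stop("unknown label value(s): ", paste(bad, collapse = ", "))
    return(as.integer(labels == "tumor"))
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("binary labels must be 0/1")
  labels
}

#' Greedy Max-Relevance Min-Redundancy gene ranking
#'
#' Ranks genes by the mRMR difference criterion. The first pick maximizes
#' relevance `I(g, t)`; every later step picks, among the remaining
#' candidates, the gene maximizing
#' `I(g, t) - (1/m) * sum over selected g_i of I(g, g_i)`,
#' where `m` is the number of genes already selected. The redundancy sums
#' are maintained incrementally: each step adds one column of
#' candidate-vs-newly-selected MI values rather than recomputing the
#' penalty from scratch. Ties in the criterion go to the
#' lowest-input-index gene, so a fixed gene order fixes the ranking.
#'
#' @param dm a [discretize()]d matrix.
#' @param labels binary label vector (1 = tumor), one per cell.
#' @param n_select how many genes to rank (<= number of genes; the
#'   remaining genes are left unranked).
#' @return Object of class `MrmrRanking`: `ranked_genes`, `relevance`
#'   (full named vector, bits), `step_scores` (criterion value of each
#'   pick at selection time) and `redundancy` (mean-MI penalty of each
#'   pick at selection time).
#' @export
mrmr_rank <- function(dm, labels, n_select) {
  stopifnot(inherits(dm, "DiscretizedMatrix"))
  n_genes <- nrow(dm$states)
  if (!(is.numeric(n_select) && length(n_select) == 1 &&
        n_select >= 1 && n_select <= n_genes)) {
    stop("`n_select` must lie in [1, ", n_genes, "]")
  }
  n_select <- as.integer(n_select)
  relevance <- relevance_scores(dm, labels)
  codes <- ternary_codes(dm$states)

  selected <- integer(n_select)
  step_scores <- numeric(n_select)
  step_redundancy <- numeric(n_select)
  remaining <- rep(TRUE, n_genes)
  redsum <- numeric(n_genes)  # sum of MI with selected genes, per candidate

  for (step in seq_len(n_select)) {
    m <- step - 1L
    score <- if (m == 0L) relevance else relevance - redsum / m
    score[!remaining] <- -Inf
    pick <- which.max(score)  # ties -> lowest index
    selected[step] <- pick
    step_scores[step] <- score[pick]
    step_redundancy[step] <- if (m == 0L) 0 else redsum[pick] / m
    remaining[pick] <- FALSE
    if (step < n_select) {
      pick_codes <- codes[pick, ]
      for (g in which(remaining)) {
        redsum[g] <- redsum[g] + mi_codes(codes[g, ], pick_codes, 3L, 3L)
      }
    }
  }
  structure(
    list(ranked_genes = dm$gene_ids[selected],
         relevance = relevance,
         step_scores = step_scores,
         redundancy = step_redundancy,
         n_candidates = n_genes),
    class = "MrmrRanking"
  )
}

#' @export
print.MrmrRanking <- function(x, ...) {
  cat(sprintf("MrmrRanking: %d of %d genes ranked; top: %s\n",
              length(x$ranked_genes), x$n_candidates,
              paste(utils::head(x$ranked_genes, 5), collapse = ", ")))
  invisible(x)
}

#' Write an mRMR ranking as TSV
#'
#' Columns: `rank`, `gene_id`, `relevance_bits`, `step_score`.
#'
#' @param ranking a [mrmr_rank()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ranking_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "MrmrRanking"))
  dt <- data.table::data.table(
    rank = seq_along(ranking$ranked_genes),
    gene_id = ranking$ranked_genes,
    relevance_bits = unname(ranking$relevance[ranking$ranked_genes]),
    step_score = ranking$step_scores
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
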