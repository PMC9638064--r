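#' 2-D t-SNE embedding of cells on a gene panel, for QC plots
#'
#' Embeds the panel-restricted normalized expression with t-SNE and
#' attaches the predicted and actual labels per cell, so false calls can
#' be plotted against the embedding. Visualization only: coordinates
#' carry no numeric contract beyond shape and seed-determinism.
#'
#' @param ds a normalized [ExpressionDataset()].
#' @param panel nonempty character vector of gene IDs.
#' @param predicted,actual per-cell binary labels (1 = tumor).
#' @param seed integer seed for the embedding.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `n_cells - 1 >= 3 * perplexity`.
#' @return data.frame with columns `cell_id`, `tsne1`, `tsne2`,
#'   `predicted`, `actual`.
#' @export
embed_cells_qc <- function(ds, panel, predicted, actual, seed = 0,
                           perplexity = 30) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (length(panel) == 0) stop("`panel` must be nonempty")
  if (!requireNamespace("Rtsne", quietly = TRUE)) {
    stop("embed_cells_qc() needs the Rtsne package")
  }
  n <- length(ds$cell_ids)
  predicted <- as_binary_labels(predicted)
  actual <- as_binary_labels(actual)
  if (length(predicted) != n || length(actual) != n) {
    stop("predicted/actual labels must have one entry per cell")
  }
  if (n - 1 < 3 * perplexity) {
    stop("perplexity ", perplexity, " is too large for ", n,
         " cells; need n - 1 >= 3 * perplexity (try perplexity <= ",
         floor((n - 1) / 3), ")")
  }
  X <- cells_by_genes(ds, panel)
  coords <- with_local_seed(seed, {
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = ncol(X) > 50)$Y
  })
  data.frame(cell_id = ds$cell_ids,
             tsne1 = coords[, 1], tsne2 = coords[, 2],
             predicted = predicted, actual = actual,
             stringsAsFactors = FALSE)
}
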