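# Small fixture builders shared across test files.

# hand-sized dataset: values chosen so every path (zeros, ties, both
# classes, two patients) is exercised
tiny_dataset <- function(normalized = FALSE) {
  m <- matrix(c(0, 2, 4, 0,
                1, 1, 1, 1,
                5, 0, 0, 3),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("c1", "c2", "c3", "c4")))
  ann <- data.frame(cell_id = colnames(m),
                    patient_id = c("P1", "P1", "P2", "P2"),
                    tissue = c("tumor", "normal", "tumor", "normal"),
                    stringsAsFactors = FALSE)
  ExpressionDataset(m, ann, normalized = normalized)
}

# small planted-marker dataset for fast end-to-end tests
small_spec <- function(seed = 11, ...) {
  args <- list(n_patients = 3, cells_per_patient_per_class = 40,
               n_genes = 100, n_markers = 5, marker_log2fc = 3,
               n_redundant_blocks = 1, block_size = 5, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_spec, args)
}

prepared_small <- function(seed = 11, ...) {
  gen <- generate_dataset(small_spec(seed, ...))
  ds <- suppressMessages(filter_genes(normalize_counts(gen$dataset), 0.01))
  list(ds = ds, truth = gen$truth,
       split = split_cohorts(ds, "P1"))
}
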