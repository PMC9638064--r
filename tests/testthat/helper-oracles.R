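# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths. They share no code with the package.

# plug-in mutual information (bits) from an explicit joint count table
mi_bruteforce <- function(x, y) {
  stopifnot(length(x) == length(y))
  ux <- sort(unique(x))
  uy <- sort(unique(y))
  n <- length(x)
  total <- 0
  for (a in ux) {
    for (b in uy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        pa <- sum(x == a) / n
        pb <- sum(y == b) / n
        total <- total + pab * log2(pab / (pa * pb))
      }
    }
  }
  total
}

# greedy mRMR recomputing the redundancy penalty from scratch each step
mrmr_naive <- function(states, labels, n_select) {
  n_genes <- nrow(states)
  selected <- integer(0)
  remaining <- seq_len(n_genes)
  rel <- vapply(seq_len(n_genes),
                function(g) mi_bruteforce(states[g, ], labels),
                numeric(1))
  for (step in seq_len(n_select)) {
    best <- NA_integer_
    best_score <- -Inf
    for (g in remaining) {
      red <- if (length(selected) == 0) {
        0
      } else {
        mean(vapply(selected,
                    function(s) mi_bruteforce(states[g, ], states[s, ]),
                    numeric(1)))
      }
      score <- rel[g] - red
      if (score > best_score + 1e-12) {  # ties -> lowest index (first seen)
        best_score <- score
        best <- g
      }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# wrap a raw states matrix as the package's DiscretizedMatrix
as_discretized <- function(states) {
  if (is.null(rownames(states))) {
    rownames(states) <- sprintf("g%03d", seq_len(nrow(states)))
  }
  if (is.null(colnames(states))) {
    colnames(states) <- sprintf("c%03d", seq_len(ncol(states)))
  }
  structure(list(states = states,
                 bin_edges = cbind(low = rep(NA_real_, nrow(states)),
                                   high = rep(NA_real_, nrow(states))),
                 gene_ids = rownames(states),
                 cell_ids = colnames(states)),
            class = "DiscretizedMatrix")
}

# random ternary states matrix + labels for property tests
random_instance <- function(seed, n_genes = 8, n_cells = 60) {
  set.seed(seed)
  states <- matrix(sample(c(-1L, 0L, 1L), n_genes * n_cells, replace = TRUE),
                   n_genes, n_cells)
  labels <- sample(c(0L, 1L), n_cells, replace = TRUE)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
  list(states = states, labels = labels)
}
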