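#' Specification of a synthetic two-class single-cell dataset
#'
#' Describes a multi-patient tumor-versus-normal count dataset with known
#' ground truth: a small set of truly discriminative marker genes, blocks
#' of genes mutually redundant with a marker, and a majority of
#' uninformative genes. Counts are negative binomial (Gamma-Poisson);
#' markers have their mean multiplied by `2^marker_log2fc` in tumor
#' cells; each redundant block copies the realized per-cell latent rate
#' of its parent marker under multiplicative lognormal noise, so block
#' members are class-informative but carry almost no information beyond
#' their parent - the situation the min-redundancy term of mRMR exists
#' for.
#'
#' @param n_patients number of patients, each contributing paired tumor
#'   and normal cells.
#' @param cells_per_patient_per_class cells per patient per tissue class.
#' @param n_genes total genes.
#' @param n_markers truly discriminative genes.
#' @param marker_log2fc log2 fold change of markers in tumor cells.
#' @param n_redundant_blocks number of redundant blocks; block `b` is
#'   seeded from the marker with the `b`-th largest baseline mean (the
#'   "strongest" markers by expected detectability).
#' @param block_size genes per block.
#' @param block_noise_sd sd of the lognormal noise a block gene applies
#'   to its parent's latent rate (natural-log scale).
#' @param nb_mean_range `(low, high)`; per-gene baseline means are drawn
#'   log-uniformly from this interval.
#' @param nb_dispersion negative-binomial dispersion `phi` (> 0), so that
#'   `var = mu + phi * mu^2` for every gene.
#' @param dropout_extra extra Bernoulli dropout rate in `[0, 1)` applied
#'   on top of sampling zeros.
#' @param patient_lib_sd sd of the per-patient lognormal library-size
#'   factor (natural-log scale).
#' @param seed integer seed; the same spec and seed reproduce the dataset
#'   bit for bit.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_patients = 8,
                           cells_per_patient_per_class = 200,
                           n_genes = 500,
                           n_markers = 10,
                           marker_log2fc = 2,
                           n_redundant_blocks = 1,
                           block_size = 10,
                           block_noise_sd = 0.1,
                           nb_mean_range = c(2, 20),
                           nb_dispersion = 0.2,
                           dropout_extra = 0.01,
                           patient_lib_sd = 0.3,
                           seed = 0) {
  spec <- structure(as.list(environment()), class = "SyntheticSpec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    stopifnot(n_patients >= 1, cells_per_patient_per_class >= 1,
              n_genes >= 1, n_markers >= 0, n_redundant_blocks >= 0,
              block_size >= 1 || n_redundant_blocks == 0)
    if (n_redundant_blocks > n_markers) {
      stop("invalid spec: n_redundant_blocks (", n_redundant_blocks,
           ") exceeds n_markers (", n_markers, "); each block needs a parent marker")
    }
    if (n_markers + n_redundant_blocks * block_size > n_genes) {
      stop("invalid spec: n_markers + n_redundant_blocks * block_size = ",
           n_markers + n_redundant_blocks * block_size,
           " exceeds n_genes = ", n_genes)
    }
    if (nb_dispersion <= 0) stop("invalid spec: nb_dispersion must be > 0")
    if (dropout_extra < 0 || dropout_extra >= 1) {
      stop("invalid spec: dropout_extra must lie in [0, 1)")
    }
    if (length(nb_mean_range) != 2 || any(nb_mean_range <= 0) ||
        nb_mean_range[1] > nb_mean_range[2]) {
      stop("invalid spec: nb_mean_range must be (low, high) with 0 < low <= high")
    }
    if (block_noise_sd < 0 || patient_lib_sd < 0) {
      stop("invalid spec: noise sds must be >= 0")
    }
  })
  invisible(spec)
}

## run `code` under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws counts under the Gamma-Poisson model described in
#' [synthetic_spec()]. Baseline rates are
#' `mu_g * lib(patient) * G` with `G ~ Gamma(1/phi, 1/phi)` (so counts
#' are marginally NB with dispersion `phi`); marker genes multiply the
#' mean by `2^marker_log2fc` in tumor cells; block genes Poisson-sample
#' from their parent marker's realized latent rate times
#' `exp(N(0, block_noise_sd))`; finally every count is zeroed with
#' probability `dropout_extra`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `dataset` (an [ExpressionDataset()], sparse
#'   counts) and `truth` (class `GroundTruth`): `marker_gene_ids`,
#'   `block_membership` (named integer vector gene -> block),
#'   `block_parent` (named character vector block gene -> parent marker),
#'   `labels` (1 = tumor per cell), `baseline_mean` (per gene) and
#'   `cells_per_patient` (table for split bookkeeping).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  validate_synthetic_spec(spec)
  with_local_seed(spec$seed, {
    n_cells <- spec$n_patients * 2 * spec$cells_per_patient_per_class
    gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
    patient_ids <- sprintf("P%d", seq_len(spec$n_patients))
    ann <- data.frame(
      cell_id = sprintf("C%05d", seq_len(n_cells)),
      patient_id = rep(patient_ids, each = 2 * spec$cells_per_patient_per_class),
      tissue = rep(rep(c("tumor", "normal"), each = spec$cells_per_patient_per_class),
                   times = spec$n_patients),
      stringsAsFactors = FALSE
    )
    tumor <- ann$tissue == "tumor"

    ## gene roles: markers first, then block genes, then baseline noise;
    ## positions shuffled so role is not encoded in gene order
    n_block_genes <- spec$n_redundant_blocks * spec$block_size
    perm <- sample.int(spec$n_genes)
    marker_idx <- perm[seq_len(spec$n_markers)]
    block_idx <- if (n_block_genes > 0) {
      matrix(perm[spec$n_markers + seq_len(n_block_genes)],
             nrow = spec$n_redundant_blocks, byrow = TRUE)
    } else {
      matrix(integer(0), nrow = 0, ncol = 0)
    }

    mu <- exp(stats::runif(spec$n_genes,
                           log(spec$nb_mean_range[1]),
                           log(spec$nb_mean_range[2])))
    lib_patient <- stats::rlnorm(spec$n_patients, 0, spec$patient_lib_sd)
    lib <- lib_patient[match(ann$patient_id, patient_ids)]

    ## blocks are parented by the markers with the largest baseline mean
    parent_of_block <- integer(0)
    if (spec$n_redundant_blocks > 0) {
      strongest <- marker_idx[order(mu[marker_idx], decreasing = TRUE)]
      parent_of_block <- strongest[seq_len(spec$n_redundant_blocks)]
    }

    shape <- 1 / spec$nb_dispersion
    fc <- 2^spec$marker_log2fc
    counts <- matrix(0L, spec$n_genes, n_cells)
    latent_parent <- vector("list", spec$n_redundant_blocks)
    for (g in seq_len(spec$n_genes)) {
      if (g %in% block_idx) next  # filled from parent below
      m <- mu[g] * lib
      if (g %in% marker_idx) m[tumor] <- m[tumor] * fc
      lam <- m * stats::rgamma(n_cells, shape = shape, rate = shape)
      counts[g, ] <- stats::rpois(n_cells, lam)
      b <- which(parent_of_block == g)
      if (length(b) == 1) latent_parent[[b]] <- lam
    }
    if (spec$n_redundant_blocks > 0) {
      for (b in seq_len(spec$n_redundant_blocks)) {
        for (g in block_idx[b, ]) {
          lam <- latent_parent[[b]] *
            exp(stats::rnorm(n_cells, 0, spec$block_noise_sd))
          counts[g, ] <- stats::rpois(n_cells, lam)
        }
      }
    }
    if (spec$dropout_extra > 0) {
      drop <- matrix(stats::runif(length(counts)) < spec$dropout_extra,
                     nrow = nrow(counts))
      counts[drop] <- 0L
    }
    dimnames(counts) <- list(gene_ids, ann$cell_id)

    block_membership <- integer(0)
    block_parent <- character(0)
    if (n_block_genes > 0) {
      block_membership <- rep(seq_len(spec$n_redundant_blocks),
                              each = spec$block_size)
      names(block_membership) <- gene_ids[as.vector(t(block_idx))]
      block_parent <- rep(gene_ids[parent_of_block], each = spec$block_size)
      names(block_parent) <- names(block_membership)
    }
    truth <- structure(
      list(marker_gene_ids = gene_ids[sort(marker_idx)],
           block_membership = block_membership,
           block_parent = block_parent,
           labels = as.integer(tumor),
           baseline_mean = stats::setNames(mu, gene_ids),
           cells_per_patient = table(ann$patient_id)),
      class = "GroundTruth"
    )
    ds <- ExpressionDataset(Matrix::Matrix(counts, sparse = TRUE), ann,
                            normalized = FALSE)
    list(dataset = ds, truth = truth)
  })
}
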