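#' Validate a gene panel on held-out patient cohorts
#'
#' Fits one linear SVM on the full training cohort restricted to the
#' panel, then applies it unchanged to every validation patient.
#' Reports training-resubstitution counts, per-patient confusion counts
#' and MCCs, and the pooled counts over all validation patients (the
#' element-wise sum of the per-patient counts). A validation patient
#' whose cells carry a single tissue label gets MCC 0 by convention,
#' with a warning.
#'
#' @param train normalized training [ExpressionDataset()].
#' @param validation named list of normalized [ExpressionDataset()]s,
#'   one per held-out patient (may be empty).
#' @param panel character vector of panel gene IDs; must be present in
#'   every dataset.
#' @param cost SVM cost parameter.
#' @param config optional list snapshot of the run configuration to
#'   embed in the report.
#' @param seed optional seed to record.
#' @return Object of class `CohortReport`: `panel`, `train`
#'   (counts + mcc), `per_patient` (data.frame), `pooled`
#'   (counts + mcc), `model`, `config`, `seed`.
#' @export
validate_panel <- function(train, validation = list(), panel,
                           cost = 1, config = NULL, seed = NULL) {
  stopifnot(inherits(train, "ExpressionDataset"))
  for (nm in names(validation)) {
    missing <- setdiff(panel, validation[[nm]]$gene_ids)
    if (length(missing) > 0) {
      stop("panel gene(s) absent from validation patient ", nm, ": ",
           paste(missing, collapse = ", "))
    }
  }
  y_train <- tissue_labels(train)
  model <- fit_classifier(cells_by_genes(train, panel), y_train, cost = cost)
  resub <- tally_confusion(predict(model, cells_by_genes(train, panel)),
                           y_train)
  per_patient <- lapply(names(validation), function(p) {
    vds <- validation[[p]]
    actual <- tissue_labels(vds)
    cc <- tally_confusion(predict(model, cells_by_genes(vds, panel)), actual)
    m <- if (length(unique(actual)) < 2) {
      warning("validation patient ", p,
              " has a single tissue class; MCC reported as 0 by convention")
      0
    } else {
      mcc(cc)
    }
    data.frame(patient_id = p, TP = cc$TP, TN = cc$TN, FP = cc$FP,
               FN = cc$FN, mcc = m, stringsAsFactors = FALSE)
  })
  per_patient <- if (length(per_patient) > 0) {
    do.call(rbind, per_patient)
  } else {
    data.frame(patient_id = character(0), TP = integer(0), TN = integer(0),
               FP = integer(0), FN = integer(0), mcc = numeric(0))
  }
  pooled <- confusion_counts(TP = sum(per_patient$TP),
                             TN = sum(per_patient$TN),
                             FP = sum(per_patient$FP),
                             FN = sum(per_patient$FN))
  pooled_mcc <- if (sum(unlist(pooled[c("TP", "TN", "FP", "FN")])) > 0) {
    mcc(pooled)
  } else {
    NA_real_
  }
  structure(
    list(panel = panel,
         train = list(counts = resub, mcc = mcc(resub)),
         per_patient = per_patient,
         pooled = list(counts = pooled, mcc = pooled_mcc),
         model = model, config = config, seed = seed),
    class = "CohortReport"
  )
}

#' @export
print.CohortReport <- function(x, ...) {
  cat(sprintf("CohortReport: %d-gene panel; training MCC %.4f; %d validation patient(s)",
              length(x$panel), x$train$mcc, nrow(x$per_patient)))
  if (nrow(x$per_patient) > 0) {
    cat(sprintf("; pooled validation MCC %.4f", x$pooled$mcc))
  }
  cat("\n")
  invisible(x)
}

#' Write / read a cohort report as JSON
#'
#' The JSON carries the panel, the training, per-patient and pooled
#' confusion counts and MCCs, the configuration snapshot and the seed;
#' counts survive a write/read round trip exactly.
#'
#' @param report a [validate_panel()] report.
#' @param path JSON file.
#' @return `write_report()`: invisibly, `path`. `read_report()`: the
#'   report as a list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "CohortReport"))
  out <- list(
    panel = report$panel,
    train = list(counts = unclass(report$train$counts),
                 mcc = report$train$mcc),
    per_patient = report$per_patient,
    pooled = list(counts = unclass(report$pooled$counts),
                  mcc = report$pooled$mcc),
    config = report$config,
    seed = report$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
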