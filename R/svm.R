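#' Fit a maximum-margin linear classifier
#'
#' Trains a soft-margin linear SVM (L2-regularized hinge loss, solved by
#' dual coordinate descent; the intercept is carried as an augmented
#' constant feature). Features are standardized to zero mean and unit
#' sd using statistics of `X` only; the model stores them so held-out
#' cells are scaled with training statistics. Constant features are
#' dropped from the decision (scaled to zero). If every feature is
#' constant the model falls back to predicting the majority class of
#' `y` (ties go to the positive class).
#'
#' @param X cells x features numeric matrix (continuous normalized
#'   expression of the current gene set).
#' @param y binary labels, one per row of `X` (1 = tumor).
#' @param cost soft-margin cost parameter C (default 1).
#' @param bias value of the augmented intercept feature (default 1).
#' @param tol,max_epochs optimizer stopping rule.
#' @return Object of class `linear_svm`: weights `w`, intercept `b`,
#'   `feature_means`, `feature_sds`, `majority`.
#' @export
fit_classifier <- function(X, y, cost = 1, bias = 1,
                           tol = 0.01, max_epochs = 200) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (length(y) != nrow(X)) stop("labels length does not match rows of X")
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; cannot fit a classifier")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  majority <- if (sum(y == 1) >= sum(y == 0)) 1L else 0L
  live <- sdv > 0
  if (!any(live)) {
    w <- numeric(ncol(X))
    b <- if (majority == 1L) 1 else -1
  } else {
    Z <- sweep(sweep(X, 2, mu, `-`), 2, ifelse(live, sdv, 1), `/`)
    Z[, !live] <- 0
    Z <- cbind(Z, bias)
    ysign <- ifelse(y == 1L, 1L, -1L)
    wfull <- cpp_linear_svm_fit(Z, as.integer(ysign), cost, tol, max_epochs)
    w <- wfull[seq_len(ncol(X))]
    b <- wfull[ncol(X) + 1] * bias
  }
  structure(
    list(w = w, b = b, feature_means = mu, feature_sds = sdv,
         majority = majority, cost = cost, bias = bias),
    class = "linear_svm"
  )
}

#' Decision values of a linear SVM
#'
#' @param model a [fit_classifier()] model.
#' @param X cells x features matrix on the same features, raw scale.
#' @return Numeric decision values; `>= 0` is called tumor.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "linear_svm"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) stop("feature count mismatch")
  live <- model$feature_sds > 0
  Z <- sweep(sweep(X, 2, model$feature_means, `-`), 2,
             ifelse(live, model$feature_sds, 1), `/`)
  Z[, !live] <- 0
  as.numeric(Z %*% model$w) + model$b
}

#' @param object a [fit_classifier()] model.
#' @param newdata cells x features matrix.
#' @param ... unused.
#' @return Integer labels (1 = tumor, 0 = normal).
#' @rdname fit_classifier
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  as.integer(decision_values(object, newdata) >= 0)
}
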