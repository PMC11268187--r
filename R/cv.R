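#' Stratified k-fold assignments
#'
#' Splits rows into k disjoint, covering folds while keeping each class's
#' representation in every fold within one sample of its global proportion.
#' Deterministic under the seed.
#'
#' @param y Class labels (each class must have at least `k` members).
#' @param k Number of folds, default 5.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
stratified_kfold <- function(y, k = 5L, seed = 1L) {
  classes <- unique(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        pt_stop("pt_input_error",
                "class '%s' has %d members, fewer than k = %d",
                cl, length(idx), k)
      }
      idx <- idx[sample.int(length(idx))]
      sizes <- diff(round(seq(0, length(idx), length.out = k + 1)))
      folds[idx] <- rep(sample.int(k), times = sizes)
    }
  })
  folds
}

#' Cross-validated binary classification of a feature matrix
#'
#' Stratified k-fold cross-validation: for each fold, the classifier is
#' fitted on the other k-1 folds and its accuracy (unweighted fraction
#' correct) measured on the held-out fold. Alongside accuracy, a
#' separability index is extracted from every trained model -- the distance
#' between class means for LDA ([lda_distance()]), the geometric margin
#' width for the SVM ([svm_margin_width()]) -- and averaged across folds.
#'
#' @param fm A `feature_matrix`.
#' @param classifier List: `type` (`"lda"` or `"svm"`) plus `lambda`
#'   (LDA shrinkage, default 0.5) or `C` (SVM box constraint, default 1).
#' @param k Number of folds, default 5.
#' @param seed Fold-assignment seed.
#' @return A `cv_result`: `fold_accuracies`, `mean_accuracy`,
#'   `separability_index` (mean across folds), `sep_values` (per fold),
#'   `fold_assignments`, `seed`, `classifier`.
#' @export
cross_validate <- function(fm, classifier = list(type = "lda"),
                           k = 5L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  type <- match.arg(classifier$type %||% "lda", c("lda", "svm"))
  folds <- stratified_kfold(fm$y, k = k, seed = seed)
  acc <- numeric(k)
  sepv <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (type == "lda") {
      model <- fit_lda(fm$x[tr, , drop = FALSE], fm$y[tr],
                       lambda = classifier$lambda %||% 0.5)
      pred <- predict_lda(model, fm$x[!tr, , drop = FALSE])$class
      sepv[f] <- lda_distance(model)
    } else {
      model <- fit_linear_svm(fm$x[tr, , drop = FALSE], fm$y[tr],
                              C = classifier$C %||% 1)
      pred <- predict_svm(model, fm$x[!tr, , drop = FALSE])$class
      sepv[f] <- svm_margin_width(model)
    }
    acc[f] <- mean(pred == fm$y[!tr])
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 separability_index = mean(sepv), sep_values = sepv,
                 fold_assignments = folds, seed = seed,
                 classifier = c(list(type = type),
                                classifier[setdiff(names(classifier),
                                                   "type")])),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s, %d folds: mean accuracy %.3f (folds: %s), separability %.3f\n",
    x$classifier$type, length(x$fold_accuracies), x$mean_accuracy,
    paste(sprintf("%.2f", x$fold_accuracies), collapse = " "),
    x$separability_index))
  invisible(x)
}
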