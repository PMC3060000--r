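#' Train a random forest companion classifier
#'
#' A standard random forest (via the randomForest package) trained on the
#' same balanced, scaled descriptor matrix as the kNN ensembles. Its class-1
#' vote fraction is mapped onto the same 0--1 consensus-score scale used by
#' the kNN consensus, so downstream thresholding and evaluation are shared.
#'
#' @param matrix Scaled `descriptor_matrix` of the training compounds.
#' @param labels Named 0/1 vector (1 = toxic) covering the rows.
#' @param n_trees Number of trees.
#' @param seed Integer seed; forests are reproducible given it.
#' @return An `rf_model` wrapping the fit; `importance(model)` style scores
#'   are available via `$fit` and [rf_importance()].
#' @export
train_random_forest <- function(matrix, labels, n_trees = 500, seed = 1) {
  y <- labels[rownames(matrix)]
  if (anyNA(y)) stopf("labels missing for some compounds")
  if (length(unique(y)) < 2L)
    stopf("degenerate single-class input; two classes required")
  fit <- with_seed(seed, randomForest::randomForest(
    x = unclass(matrix), y = factor(y, levels = c(0, 1)),
    ntree = n_trees, importance = TRUE))
  structure(list(fit = fit, n_trees = n_trees, seed = seed),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("random forest: %d trees, %d descriptors\n",
              x$n_trees, nrow(x$fit$importance)))
  invisible(x)
}

#' Consensus-scale scores from a random forest
#'
#' @param model An `rf_model`.
#' @param newdata Descriptor matrix of query compounds.
#' @return Numeric vector in `[0, 1]`: fraction of trees voting "toxic".
#' @export
rf_score <- function(model, newdata) {
  p <- stats::predict(model$fit, unclass(newdata), type = "prob")
  unname(p[, "1"])
}

#' Per-descriptor importance from a random forest
#'
#' @param model An `rf_model`.
#' @return Named numeric vector (mean decrease in accuracy), descending.
#' @export
rf_importance <- function(model) {
  imp <- randomForest::importance(model$fit, type = 1)[, 1L]
  sort(imp, decreasing = TRUE)
}
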