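#' Consensus prediction from a kNN ensemble
#'
#' Each model in the ensemble casts a binary vote (0 = nontoxic,
#' 1 = toxic) for every query compound that falls inside its applicability
#' domain. The consensus score is the mean vote over covering models; a
#' compound covered by no model has an undefined score and the call
#' `not_covered`.
#'
#' @param ensemble A `knn_ensemble` (or plain list of `knn_model`s).
#' @param newdata Scaled descriptor matrix of query compounds (rows named
#'   by compound id), covering every model's descriptor subset.
#' @return Data frame with `compound_id`, `score` (`NA` when uncovered) and
#'   `n_models_covering`.
#' @export
consensus_predict <- function(ensemble, newdata) {
  models <- if (inherits(ensemble, "knn_ensemble")) ensemble$models else ensemble
  if (!length(models)) stopf("ensemble contains no models")
  n <- nrow(newdata)
  votes <- matrix(0, n, length(models))
  cover <- matrix(FALSE, n, length(models))
  for (j in seq_along(models)) {
    pr <- knn_predict_matrix(models[[j]], unclass(newdata))
    votes[, j] <- pr$class
    cover[, j] <- pr$in_ad
  }
  n_cov <- rowSums(cover)
  score <- ifelse(n_cov > 0, rowSums(votes * cover) / n_cov, NA_real_)
  data.frame(compound_id = rownames(newdata) %||% as.character(seq_len(n)),
             score = score, n_models_covering = n_cov,
             stringsAsFactors = FALSE)
}

#' Pool consensus scores from several model families
#'
#' Averages aligned score vectors (e.g. the kNN consensus score and the
#' random-forest vote fraction) compound-wise, propagating coverage: a
#' compound's pooled score averages the families that cover it and is `NA`
#' only if none do. Per-method reporting remains the default elsewhere;
#' pooling is provided for combined-classification summaries.
#'
#' @param ... Numeric score vectors of equal length (`NA` = not covered).
#' @return Numeric vector of pooled scores.
#' @export
pool_consensus_scores <- function(...) {
  scores <- list(...)
  if (!length(scores)) stopf("no score vectors supplied")
  n <- unique(lengths(scores))
  if (length(n) != 1L) stopf("score vectors must align")
  m <- do.call(cbind, scores)
  out <- rowMeans(m, na.rm = TRUE)
  out[!rowSums(!is.na(m))] <- NA_real_
  out
}

#' Classify consensus scores with dual thresholds
#'
#' Scores at or below `t1` are called `nontoxic`, at or above `t2` `toxic`,
#' and anything strictly between is `inconclusive`. With the default single
#' threshold (`t1 == t2 == 0.5`) scores strictly above 0.5 are toxic,
#' strictly below nontoxic, and exactly 0.5 inconclusive. Undefined scores
#' (`NA`) are `not_covered`.
#'
#' @param score Numeric vector of consensus scores (`NA` = uncovered).
#' @param t1,t2 Classification thresholds, `0 <= t1 <= t2 <= 1`.
#' @return Character vector of calls.
#' @export
classify_with_thresholds <- function(score, t1 = 0.5, t2 = 0.5) {
  if (!is.numeric(t1) || !is.numeric(t2) || t1 > t2 || t1 < 0 || t2 > 1)
    stopf("parameter error: need 0 <= t1 <= t2 <= 1")
  call <- rep("inconclusive", length(score))
  if (t1 == t2) {
    call[score < t1] <- "nontoxic"
    call[score > t2] <- "toxic"
  } else {
    call[score <= t1] <- "nontoxic"
    call[score >= t2] <- "toxic"
  }
  call[is.na(score)] <- "not_covered"
  call
}

#' Evaluate classification calls against known classes
#'
#' Sensitivity (specificity) is the correctly predicted fraction of toxic
#' (nontoxic) compounds among those with a conclusive, in-domain call;
#' CCR = 0.5 (sensitivity + specificity). Coverage is the fraction of all
#' evaluated compounds that received a conclusive, covered call. A class
#' absent from the conclusive calls leaves its component (and the CCR)
#' undefined (`NA`).
#'
#' @param calls Character vector from [classify_with_thresholds()].
#' @param truth 0/1 vector (1 = toxic) or class labels.
#' @return An `evaluation_report`: list with `ccr`, `sensitivity`,
#'   `specificity`, `coverage`, `n_evaluated`, `n_conclusive`.
#' @export
evaluate_classification <- function(calls, truth) {
  if (length(calls) != length(truth)) stopf("calls and truth must align")
  y <- if (is.numeric(truth)) as.integer(truth) else
    as.integer(truth %in% c("toxic", "1"))
  conclusive <- calls %in% c("toxic", "nontoxic")
  sens <- if (any(conclusive & y == 1))
    mean(calls[conclusive & y == 1] == "toxic") else NA_real_
  spec <- if (any(conclusive & y == 0))
    mean(calls[conclusive & y == 0] == "nontoxic") else NA_real_
  structure(list(ccr = 0.5 * (sens + spec), sensitivity = sens,
                 specificity = spec, coverage = mean(conclusive),
                 n_evaluated = length(calls),
                 n_conclusive = sum(conclusive)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("CCR %.3f | sensitivity %.3f | specificity %.3f | coverage %.3f (%d/%d conclusive)\n",
              x$ccr, x$sensitivity, x$specificity, x$coverage,
              x$n_conclusive, x$n_evaluated))
  invisible(x)
}

#' CCR and coverage over a grid of classification thresholds
#'
#' Evaluates [classify_with_thresholds()] at every pair `t1 <= t2` on a
#' regular lattice, producing the CCR and coverage heat-map grids. The
#' diagonal (`t1 == t2`) reproduces single-threshold classification.
#'
#' @param scores Consensus scores (`NA` = uncovered).
#' @param truth 0/1 vector (1 = toxic).
#' @param grid_step Lattice spacing (default 0.05).
#' @return List with `thresholds` (lattice values) and matrices `ccr` and
#'   `coverage` (rows = t1, cols = t2; `NA` where t1 > t2).
#' @export
threshold_heatmap <- function(scores, truth, grid_step = 0.05) {
  ts <- seq(0, 1, by = grid_step)
  nt <- length(ts)
  ccr <- cov <- matrix(NA_real_, nt, nt, dimnames = list(t1 = ts, t2 = ts))
  for (i in seq_len(nt)) for (j in i:nt) {
    rep <- evaluate_classification(
      classify_with_thresholds(scores, ts[i], ts[j]), truth)
    ccr[i, j] <- rep$ccr
    cov[i, j] <- rep$coverage
  }
  list(thresholds = ts, ccr = ccr, coverage = cov)
}

#' Write a heat-map grid as TSV
#'
#' @param grid A matrix from [threshold_heatmap()].
#' @param path Output path.
#' @export
write_heatmap_tsv <- function(grid, path) {
  df <- data.frame(t1 = rownames(grid), grid, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
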