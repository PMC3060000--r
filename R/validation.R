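#' Five-fold external validation of the modeling pipeline
#'
#' Runs the complete modeling procedure with strict external holdout: the
#' compound set is partitioned into `n_folds` nearly equal external test
#' sets; for each fold, the remaining modeling pool is class-balanced by
#' structural down-sampling, subdivided into internal training/test splits
#' by sphere exclusion, used to train a kNN ensemble (and optionally a
#' random forest), and the untouched external compounds are scored and
#' evaluated at the single 0.5 consensus threshold. External compounds take
#' no part in balancing, splitting or training.
#'
#' @param matrix Scaled `descriptor_matrix` used for modeling (chemical,
#'   hybrid, ...).
#' @param labels Named 0/1 vector (1 = toxic) over the rows of `matrix`.
#' @param chem_matrix Scaled chemical `descriptor_matrix` used for the
#'   balancing distance (defaults to `matrix`; pass the chemical-only
#'   matrix when modeling with hybrid descriptors so that balancing is
#'   identical across descriptor configurations).
#' @param n_folds Number of external folds.
#' @param n_internal_splits Sphere-exclusion subdivisions per fold.
#' @param config A [knn_config()].
#' @param methods Any of `"knn"`, `"rf"`.
#' @param n_trees Random-forest size.
#' @param seed Integer seed for fold assignment (model seeds derive from
#'   the config seed and fold index).
#' @return A `validation_summary`: per-fold reports and predictions, mean
#'   CCR per method, and the split bookkeeping needed for a leakage audit.
#' @export
run_external_validation <- function(matrix, labels,
                                    chem_matrix = matrix,
                                    n_folds = 5, n_internal_splits = 20,
                                    config = knn_config(),
                                    methods = c("knn", "rf"),
                                    n_trees = 500, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  ids <- rownames(matrix)
  if (is.null(ids) || anyNA(labels[ids])) stopf("labels must cover all rows")
  folds <- make_external_folds(ids, n_folds, seed)
  fold_results <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    fold <- folds[[f]]
    pool <- fold$modeling_pool
    if (length(unique(labels[pool])) < 2L || length(unique(labels[fold$external_test])) < 2L) {
      warnf("fold %d has a single class; skipped", f)
      next
    }
    balanced <- balance_modeling_set(pool, labels, chem_matrix)
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, 100 + f)
    res <- list(fold_index = f, external_test = fold$external_test,
                balanced_modeling = as.character(balanced))
    Xext <- dm_subset(matrix, rows = fold$external_test)
    yext <- labels[fold$external_test]
    if ("knn" %in% methods) {
      splits <- sphere_exclusion_split(
        as.character(balanced), labels, matrix, n_internal_splits,
        seed = derive_seed(seed, 200 + f))
      ens <- train_knn_ensemble(splits, dm_subset(matrix, rows = as.character(balanced)),
                                labels, fold_cfg)
      res$internal_splits <- lapply(splits, function(s) s[c("train", "test")])
      res$n_models <- length(ens$models)
      res$ensemble <- ens
      if (length(ens$models)) {
        pred <- consensus_predict(ens, Xext)
        calls <- classify_with_thresholds(pred$score)
        res$knn_scores <- stats::setNames(pred$score, pred$compound_id)
        res$knn_report <- evaluate_classification(calls, yext)
      } else {
        res$knn_report <- NULL
      }
    }
    if ("rf" %in% methods) {
      rf <- train_random_forest(dm_subset(matrix, rows = as.character(balanced)),
                                labels, n_trees = n_trees,
                                seed = derive_seed(config$seed, 300 + f))
      sc <- rf_score(rf, Xext)
      res$rf_scores <- stats::setNames(sc, fold$external_test)
      res$rf_report <- evaluate_classification(
        classify_with_thresholds(sc), yext)
    }
    fold_results[[f]] <- res
  }
  fold_results <- Filter(Negate(is.null), fold_results)
  mean_ccr <- vapply(c(knn = "knn_report", rf = "rf_report")[methods],
                     function(field) {
    v <- vapply(fold_results,
                function(r) if (is.null(r[[field]])) NA_real_ else r[[field]]$ccr, 0)
    mean(v, na.rm = TRUE)
  }, 0)
  structure(list(folds = fold_results, mean_ccr = mean_ccr,
                 methods = methods, seed = seed, config = config),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("external validation: %d folds\n", length(x$folds)))
  for (m in x$methods) {
    field <- paste0(m, "_report")
    ccrs <- vapply(x$folds, function(r)
      if (is.null(r[[field]])) NA_real_ else r[[field]]$ccr, 0)
    cat(sprintf("  %-4s fold CCRs: %s | mean %.3f\n", m,
                paste(sprintf("%.2f", ccrs), collapse = " "),
                x$mean_ccr[[m]]))
  }
  invisible(x)
}

#' y-randomization robustness test
#'
#' Retrains the full pipeline on label-permuted data and compares the
#' resulting external CCRs with the real model's mean CCR. Per repeat, an
#' external set is held out with true labels untouched; the modeling pool's
#' labels are permuted (a shuffle, so class counts are preserved), the pool
#' is balanced and modelled exactly as in the real run, and the external
#' CCR recorded. The one-tailed one-sample t-test asks whether the
#' randomized CCR distribution reaches the real mean CCR; models pass when
#' `p < 0.05` (a randomized model is very unlikely to match them).
#'
#' @param matrix,labels,chem_matrix,n_internal_splits,config,seed As in
#'   [run_external_validation()].
#' @param real_mean_ccr Mean external CCR of the real-label run.
#' @param n_repeats Number of randomized retrainings (default 5).
#' @param external_fraction Fraction of compounds held out per repeat.
#' @param method `"knn"` or `"rf"`.
#' @param n_trees Random-forest size when `method = "rf"`.
#' @return List with `ccrs` (randomized external CCRs), `max_ccr`,
#'   `p_value`, and `pass` (`p < 0.05`).
#' @export
y_randomization_test <- function(matrix, labels, real_mean_ccr,
                                 chem_matrix = matrix, n_repeats = 5,
                                 external_fraction = 0.2,
                                 n_internal_splits = 20,
                                 config = knn_config(), method = "knn",
                                 n_trees = 500, seed = 1) {
  method <- match.arg(method, c("knn", "rf"))
  ids <- rownames(matrix)
  ccrs <- rep(NA_real_, n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    rs <- derive_seed(seed, rep_i)
    ext <- with_seed(rs, sample(ids, round(external_fraction * length(ids))))
    pool <- setdiff(ids, ext)
    perm <- labels
    perm[pool] <- with_seed(derive_seed(rs, 1), sample(labels[pool]))
    balanced <- balance_modeling_set(pool, perm, chem_matrix)
    Xext <- dm_subset(matrix, rows = ext)
    score <- NULL
    if (method == "knn") {
      splits <- sphere_exclusion_split(as.character(balanced), perm, matrix,
                                       n_internal_splits,
                                       seed = derive_seed(rs, 2))
      cfg <- config; cfg$seed <- derive_seed(rs, 3)
      ens <- train_knn_ensemble(splits, dm_subset(matrix, rows = as.character(balanced)),
                                perm, cfg)
      if (!length(ens$models)) next
      score <- consensus_predict(ens, Xext)$score
    } else {
      rf <- train_random_forest(dm_subset(matrix, rows = as.character(balanced)),
                                perm, n_trees = n_trees,
                                seed = derive_seed(rs, 3))
      score <- rf_score(rf, Xext)
    }
    rep_eval <- evaluate_classification(classify_with_thresholds(score),
                                        labels[ext])
    ccrs[rep_i] <- rep_eval$ccr
  }
  obs <- ccrs[!is.na(ccrs)]
  p <- y_rand_pvalue(obs, real_mean_ccr)
  list(ccrs = ccrs, max_ccr = if (length(obs)) max(obs) else NA_real_,
       p_value = p, pass = isTRUE(p < 0.05))
}

# One-tailed one-sample t-test: probability that the randomized CCR
# distribution reaches the real mean CCR. Zero-variance distributions fall
# back to exact comparison (0.5 when equal).
y_rand_pvalue <- function(obs, real_mean_ccr) {
  if (!length(obs)) return(NA_real_)
  if (length(obs) == 1L || stats::sd(obs) == 0) {
    return(if (mean(obs) == real_mean_ccr) 0.5
           else if (mean(obs) < real_mean_ccr) 0 else 1)
  }
  tstat <- (real_mean_ccr - mean(obs)) / (stats::sd(obs) / sqrt(length(obs)))
  stats::pt(tstat, df = length(obs) - 1L, lower.tail = FALSE)
}

#' Descriptor occurrence frequencies across an ensemble
#'
#' The frequency of a descriptor is the fraction of retained models whose
#' subset contains it. Descriptors above the mean frequency are flagged as
#' the informative set; biological descriptors (named
#' `<cell_line>@<concentration>`) are additionally pivoted to a
#' cell-line-by-concentration grid.
#'
#' @param ensemble A `knn_ensemble` with at least one model.
#' @return List with `frequencies` (named, full descriptor universe),
#'   `mean_frequency`, `above_mean` (descriptor names) and `bio_grid`
#'   (matrix or `NULL`).
#' @export
descriptor_frequency <- function(ensemble) {
  models <- if (inherits(ensemble, "knn_ensemble")) ensemble$models else ensemble
  if (!length(models)) stopf("need at least one retained model")
  universe <- if (inherits(ensemble, "knn_ensemble"))
    ensemble$descriptor_universe
  else unique(unlist(lapply(models, `[[`, "descriptor_subset")))
  counts <- stats::setNames(numeric(length(universe)), universe)
  for (mod in models) {
    s <- mod$descriptor_subset
    counts[s] <- counts[s] + 1
  }
  freq <- counts / length(models)
  above <- names(freq)[freq > mean(freq)]
  bio <- grep("@", names(freq), value = TRUE)
  bio_grid <- NULL
  if (length(bio)) {
    parts <- strsplit(bio, "@", fixed = TRUE)
    cells <- unique(vapply(parts, `[[`, "", 1L))
    concs <- unique(vapply(parts, `[[`, "", 2L))
    bio_grid <- matrix(0, length(cells), length(concs),
                       dimnames = list(cells, concs))
    for (i in seq_along(bio))
      bio_grid[parts[[i]][1L], parts[[i]][2L]] <- freq[bio[i]]
  }
  list(frequencies = freq, mean_frequency = mean(freq),
       above_mean = above, bio_grid = bio_grid)
}

#' Audit serialized splits for external-test leakage
#'
#' Asserts, from a `validation_summary`, that no external-test compound of
#' any fold appears in that fold's balanced modeling set or internal
#' training/test splits.
#'
#' @param summary A `validation_summary`.
#' @return `TRUE` invisibly; errors on any leak.
#' @export
audit_leakage <- function(summary) {
  for (r in summary$folds) {
    ext <- r$external_test
    if (length(intersect(ext, r$balanced_modeling)))
      stopf("fold %d: external compounds in modeling set", r$fold_index)
    for (sp in r$internal_splits %||% list())
      if (length(intersect(ext, c(sp$train, sp$test))))
        stopf("fold %d: external compounds in internal splits", r$fold_index)
  }
  invisible(TRUE)
}
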