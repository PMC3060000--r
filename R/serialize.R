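#' Serialize a kNN ensemble to JSON
#'
#' The entire ensemble -- descriptor subsets, training reference vectors
#' and labels, applicability-domain cutoffs, and the training configuration
#' with its seed -- is written to a single JSON document, sufficient to
#' reproduce predictions exactly.
#'
#' @param ensemble A `knn_ensemble`.
#' @param path Output path.
#' @return `read_ensemble_json` returns a `knn_ensemble`.
#' @export
write_ensemble_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "knn_ensemble"))
  doc <- list(
    descriptor_universe = ensemble$descriptor_universe,
    config = unclass(ensemble$config),
    models = lapply(ensemble$models, function(m) list(
      descriptor_subset = m$descriptor_subset, k = m$k,
      train_ids = m$train_ids, X = unclass(m$X), y = m$y,
      ad_cutoff = m$ad_cutoff, training_ccr = m$training_ccr,
      test_ccr = m$test_ccr)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_len(if (is.data.frame(doc$models)) nrow(doc$models)
                           else length(doc$models)), function(i) {
    m <- if (is.data.frame(doc$models)) lapply(doc$models, `[[`, i)
         else doc$models[[i]]
    X <- as.matrix(m$X)
    rownames(X) <- m$train_ids
    colnames(X) <- m$descriptor_subset
    structure(list(descriptor_subset = m$descriptor_subset, k = m$k,
                   train_ids = m$train_ids, X = X, y = as.integer(m$y),
                   ad_cutoff = m$ad_cutoff, training_ccr = m$training_ccr,
                   test_ccr = m$test_ccr), class = "knn_model")
  })
  cfg <- doc$config
  config <- knn_config(k_range = cfg$k_range,
                       subset_size = cfg$subset_size, t0 = cfg$t0,
                       cooling = cfg$cooling,
                       proposals_per_temp = cfg$proposals_per_temp,
                       min_acceptance = cfg$min_acceptance,
                       max_temps = cfg$max_temps,
                       accept_ccr = cfg$accept_ccr, z_ad = cfg$z_ad,
                       max_models_per_split = cfg$max_models_per_split,
                       exhaustive_limit = cfg$exhaustive_limit,
                       seed = cfg$seed)
  structure(list(models = models, config = config,
                 descriptor_universe = doc$descriptor_universe),
            class = "knn_ensemble")
}
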