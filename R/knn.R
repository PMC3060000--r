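#' Configuration for kNN ensemble training
#'
#' Hyperparameters of the descriptor-subset search. Models are sought by
#' simulated annealing over descriptor subsets: each proposal swaps, adds or
#' drops one descriptor, is scored by leave-one-out (LOO) training CCR at
#' the best `k`, and is accepted by the Metropolis rule under geometric
#' cooling. Accepted states whose LOO CCR reaches `accept_ccr` are evaluated
#' on the split's test compounds; those that also reach `accept_ccr` there
#' are retained, each with an applicability-domain cutoff
#' `D = mean + z_ad * sd` of the training nearest-neighbour distances in the
#' model's own descriptor subspace.
#'
#' @param k_range Candidate neighbour counts.
#' @param subset_size Length-2 integer range of descriptor-subset sizes.
#' @param t0 Initial annealing temperature, in CCR units (0.05 accepts a
#'   0.035 CCR worsening about half the time).
#' @param cooling Geometric cooling factor per temperature step.
#' @param proposals_per_temp Proposals evaluated at each temperature.
#' @param min_acceptance Stop when the acceptance rate at a temperature
#'   drops below this.
#' @param max_temps Maximum number of temperature steps.
#' @param accept_ccr Minimum LOO and test CCR for a model to be retained.
#' @param z_ad Applicability-domain multiplier Z.
#' @param max_models_per_split Cap on retained models per internal split
#'   (best test CCR kept).
#' @param exhaustive_limit If the total number of admissible subsets is at
#'   most this, enumerate them all instead of annealing.
#' @param seed Integer seed; all randomness in training derives from it.
#' @return A `knn_config` list.
#' @export
knn_config <- function(k_range = 1:5, subset_size = c(5, 40), t0 = 0.05,
                       cooling = 0.9, proposals_per_temp = 100,
                       min_acceptance = 0.01, max_temps = 30,
                       accept_ccr = 0.70, z_ad = 0.5,
                       max_models_per_split = 25, exhaustive_limit = 64,
                       seed = 1) {
  stopifnot(all(k_range >= 1), length(subset_size) == 2L,
            subset_size[1L] >= 1L, subset_size[2L] >= subset_size[1L])
  structure(list(k_range = as.integer(k_range),
                 subset_size = as.integer(subset_size), t0 = t0,
                 cooling = cooling,
                 proposals_per_temp = as.integer(proposals_per_temp),
                 min_acceptance = min_acceptance,
                 max_temps = as.integer(max_temps), accept_ccr = accept_ccr,
                 z_ad = z_ad,
                 max_models_per_split = as.integer(max_models_per_split),
                 exhaustive_limit = exhaustive_limit, seed = seed),
            class = "knn_config")
}

# Single kNN vote. Odd k: simple majority. Even k: inverse-distance
# weighted, ties broken toward nontoxic (0).
knn_vote <- function(labels, dists) {
  k <- length(labels)
  if (k %% 2L == 1L) return(as.integer(sum(labels) * 2L > k))
  w <- 1 / (dists + 1e-12)
  s1 <- sum(w[labels == 1]); s0 <- sum(w[labels == 0])
  as.integer(s1 > s0)
}

ccr_binary <- function(pred, truth) {
  sens <- mean(pred[truth == 1] == 1)
  spec <- mean(pred[truth == 0] == 0)
  0.5 * (sens + spec)
}

# LOO predictions over a squared-distance matrix for each k in k_range.
# Returns the best CCR and the k achieving it (first on ties).
loo_best_ccr <- function(D2, y, k_range) {
  n <- nrow(D2)
  kmax <- min(max(k_range), n - 1L)
  ks <- k_range[k_range <= kmax]
  preds <- matrix(NA_integer_, n, length(ks))
  for (i in seq_len(n)) {
    o <- order(D2[, i])
    o <- o[o != i][seq_len(kmax)]
    di <- sqrt(pmax(D2[o, i], 0))
    for (j in seq_along(ks))
      preds[i, j] <- knn_vote(y[o[seq_len(ks[j])]], di[seq_len(ks[j])])
  }
  ccrs <- vapply(seq_along(ks), function(j) ccr_binary(preds[, j], y), 0)
  best <- which.max(ccrs)
  list(ccr = ccrs[best], k = ks[best])
}

# Squared cross-distances between rows of A (queries) and B (references).
cross_dist2 <- function(A, B) {
  out <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(out, 0)
}

# Build a retained model from a subset (column indices into Xtr).
make_knn_model <- function(subset, k, Xtr, ytr, train_ids, training_ccr,
                           test_ccr, z_ad) {
  Xs <- Xtr[, subset, drop = FALSE]
  D2 <- cross_dist2(Xs, Xs)
  diag(D2) <- Inf
  nn <- sqrt(apply(D2, 1L, min))
  cutoff <- mean(nn) + z_ad * stats::sd(nn)
  if (!is.finite(cutoff) || cutoff <= 0) cutoff <- max(mean(nn), 1e-8)
  structure(list(descriptor_subset = colnames(Xtr)[subset], k = k,
                 train_ids = train_ids, X = Xs, y = ytr,
                 ad_cutoff = cutoff, training_ccr = training_ccr,
                 test_ccr = test_ccr),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("kNN model: %d descriptors, k=%d, %d training compounds, AD cutoff %.4f, LOO CCR %.3f, test CCR %.3f\n",
              length(x$descriptor_subset), x$k, length(x$y), x$ad_cutoff,
              x$training_ccr, x$test_ccr))
  invisible(x)
}

# Test CCR of a subset/k on an internal test split.
subset_test_ccr <- function(subset, k, Xtr, ytr, Xte, yte) {
  D2 <- cross_dist2(Xte[, subset, drop = FALSE], Xtr[, subset, drop = FALSE])
  pred <- vapply(seq_len(nrow(Xte)), function(i) {
    o <- order(D2[i, ])[seq_len(k)]
    knn_vote(ytr[o], sqrt(D2[i, o]))
  }, integer(1))
  ccr_binary(pred, yte)
}

# Anneal one internal split; returns a list of knn_model objects.
anneal_split <- function(Xtr, ytr, Xte, yte, train_ids, config, seed) {
  p <- ncol(Xtr)
  smin <- min(config$subset_size[1L], p)
  smax <- min(config$subset_size[2L], p)
  sizes <- smin:smax
  n_subsets <- sum(choose(p, sizes))
  retained <- list()
  seen <- character(0)

  consider <- function(subset, loo) {
    key <- paste(c(sort(subset), loo$k), collapse = ",")
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    if (!is.na(loo$ccr) && loo$ccr >= config$accept_ccr) {
      tccr <- subset_test_ccr(subset, loo$k, Xtr, ytr, Xte, yte)
      if (!is.na(tccr) && tccr >= config$accept_ccr)
        retained[[length(retained) + 1L]] <<- make_knn_model(
          subset, loo$k, Xtr, ytr, train_ids, loo$ccr, tccr, config$z_ad)
    }
    invisible(NULL)
  }

  score_subset <- function(subset) {
    Xs <- Xtr[, subset, drop = FALSE]
    D2 <- cross_dist2(Xs, Xs)
    loo_best_ccr(D2, ytr, config$k_range)
  }

  with_seed(seed, {
    if (n_subsets <= config$exhaustive_limit) {
      for (size in sizes)
        utils::combn(p, size, function(subset) {
          consider(subset, score_subset(subset)); 0
        })
    } else {
      cur <- sort(sample(p, sample(sizes, 1L)))
      D2 <- cross_dist2(Xtr[, cur, drop = FALSE], Xtr[, cur, drop = FALSE])
      cur_loo <- loo_best_ccr(D2, ytr, config$k_range)
      consider(cur, cur_loo)
      temp <- config$t0
      for (step in seq_len(config$max_temps)) {
        accepted <- 0L
        for (prop in seq_len(config$proposals_per_temp)) {
          size <- length(cur)
          moves <- c(if (size < smax && size < p) "add",
                     if (size > smin) "drop",
                     if (size < p) "swap")
          move <- if (length(moves) == 1L) moves else
            sample(moves, 1L, prob = c(0.2, 0.2, 0.6)[match(moves, c("add", "drop", "swap"))])
          out_j <- in_j <- NULL
          if (move %in% c("drop", "swap"))
            out_j <- cur[sample.int(size, 1L)]
          if (move %in% c("add", "swap"))
            in_j <- sample(setdiff(seq_len(p), cur), 1L)
          D2_new <- D2
          if (!is.null(in_j)) {
            x <- Xtr[, in_j]
            D2_new <- D2_new + outer(x, x, "-")^2
          }
          if (!is.null(out_j)) {
            x <- Xtr[, out_j]
            D2_new <- D2_new - outer(x, x, "-")^2
          }
          new <- sort(c(setdiff(cur, out_j), in_j))
          new_loo <- loo_best_ccr(D2_new, ytr, config$k_range)
          delta <- new_loo$ccr - cur_loo$ccr
          if (delta >= 0 || stats::runif(1) < exp(delta / temp)) {
            cur <- new; D2 <- D2_new; cur_loo <- new_loo
            accepted <- accepted + 1L
            consider(cur, cur_loo)
          }
        }
        if (accepted / config$proposals_per_temp < config$min_acceptance)
          break
        temp <- temp * config$cooling
      }
    }
  })
  if (length(retained) > config$max_models_per_split) {
    ord <- order(-vapply(retained, `[[`, 0, "test_ccr"))
    retained <- retained[ord[seq_len(config$max_models_per_split)]]
  }
  retained
}

#' Train a kNN model ensemble over internal splits
#'
#' For every internal training/test split, runs the simulated-annealing
#' descriptor-subset search (see [knn_config()]) and collects every model
#' whose leave-one-out training CCR and internal-test CCR both reach
#' `accept_ccr`. A split in which no model qualifies contributes nothing
#' (with a warning).
#'
#' @param splits List of splits with `train` and `test` id vectors, e.g.
#'   from [sphere_exclusion_split()].
#' @param matrix Scaled `descriptor_matrix` covering all split compounds.
#' @param labels Named 0/1 vector (1 = toxic).
#' @param config A [knn_config()].
#' @return A `knn_ensemble`: list with `models`, `config` and
#'   `descriptor_universe` (colnames of `matrix`).
#' @export
train_knn_ensemble <- function(splits, matrix, labels, config = knn_config()) {
  stopifnot(inherits(config, "knn_config"))
  m <- unclass(matrix)
  models <- list()
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    ytr <- unname(labels[sp$train]); yte <- unname(labels[sp$test])
    if (length(unique(ytr)) < 2L)
      stopf("internal split %d has a single class in training", s)
    got <- anneal_split(m[sp$train, , drop = FALSE], ytr,
                        m[sp$test, , drop = FALSE], yte,
                        sp$train, config, derive_seed(config$seed, s))
    if (!length(got))
      warnf("internal split %d: no model reached accept_ccr = %.2f",
            s, config$accept_ccr)
    models <- c(models, got)
  }
  structure(list(models = models, config = config,
                 descriptor_universe = colnames(m)),
            class = "knn_ensemble")
}

#' @export
print.knn_ensemble <- function(x, ...) {
  cat(sprintf("kNN ensemble: %d models over %d descriptors\n",
              length(x$models), length(x$descriptor_universe)))
  invisible(x)
}

#' Predict a single compound with one kNN model
#'
#' Distance is Euclidean in the model's descriptor subspace. The compound is
#' inside the applicability domain when its mean distance to the `k` nearest
#' training compounds does not exceed the model's cutoff; the class is the
#' (distance-weighted for even `k`) majority label of those neighbours.
#'
#' @param model A `knn_model`.
#' @param x Named numeric vector covering the model's `descriptor_subset`
#'   (extra entries ignored), or an unnamed vector in subset order.
#' @return List with `class` (0/1), `in_ad` (logical) and `mean_dist`.
#' @export
knn_predict <- function(model, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(model$descriptor_subset, names(x))
    if (length(miss))
      stopf("missing descriptor value(s): %s", paste(miss, collapse = ", "))
    x <- x[model$descriptor_subset]
  } else if (length(x) != length(model$descriptor_subset)) {
    stopf("unnamed vector must match the descriptor subset length")
  }
  if (anyNA(x)) stopf("missing descriptor value(s)")
  d <- sqrt(colSums((t(model$X) - as.numeric(x))^2))
  o <- order(d)[seq_len(min(model$k, length(d)))]
  list(class = knn_vote(model$y[o], d[o]),
       in_ad = mean(d[o]) <= model$ad_cutoff,
       mean_dist = mean(d[o]))
}

# Vectorized per-model prediction over a query matrix (rows = compounds).
knn_predict_matrix <- function(model, X) {
  D2 <- cross_dist2(X[, model$descriptor_subset, drop = FALSE], model$X)
  k <- min(model$k, ncol(D2))
  n <- nrow(X)
  cls <- integer(n); ind <- logical(n)
  for (i in seq_len(n)) {
    o <- order(D2[i, ])[seq_len(k)]
    di <- sqrt(D2[i, o])
    cls[i] <- knn_vote(model$y[o], di)
    ind[i] <- mean(di) <= model$ad_cutoff
  }
  list(class = cls, in_ad = ind)
}
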