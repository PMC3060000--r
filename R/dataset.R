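#' Assign acute-toxicity categories from -log10 LD50
#'
#' Rat acute oral toxicity on the negative log molar-per-kilogram scale is
#' categorised per the acute-toxicity guidelines: values above 3 are
#' `toxic`, below 2 `nontoxic`, and the band in between `marginal`.
#'
#' @param neg_log_ld50 Numeric vector of -log10 LD50 (mol/kg) values.
#' @return Character vector in `{"toxic", "nontoxic", "marginal"}`.
#' @export
assign_toxicity_class <- function(neg_log_ld50) {
  x <- as.numeric(neg_log_ld50)
  if (any(!is.finite(x)))
    stopf("neg_log_ld50 must be finite; offending index: %s",
          paste(which(!is.finite(x)), collapse = ", "))
  ifelse(x > 3, "toxic", ifelse(x < 2, "nontoxic", "marginal"))
}

#' Read a rat LD50 table
#'
#' Two-column TSV/CSV: `compound_id` and `neg_log_ld50` (-log10 mol/kg).
#'
#' @param path File path.
#' @param sep Delimiter; inferred from the extension when `NULL`.
#' @return Data frame with `compound_id`, `neg_log_ld50` and derived
#'   `tox_class`.
#' @export
read_ld50_table <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("compound_id", "neg_log_ld50")
  if (!all(need %in% names(df)))
    stopf("format error: missing required column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  df$neg_log_ld50 <- as.numeric(df$neg_log_ld50)
  df$tox_class <- assign_toxicity_class(df$neg_log_ld50)
  df[, c("compound_id", "neg_log_ld50", "tox_class")]
}

#' Build the binary modeling dataset
#'
#' Marginal compounds (the 2--3 band of -log10 LD50) are excluded from
#' modeling; toxic and nontoxic compounds receive binary labels (toxic = 1,
#' nontoxic = 0). Every modeled compound must have descriptors.
#'
#' @param tox_records Data frame with `compound_id` and `neg_log_ld50`
#'   (class recomputed if absent).
#' @param descriptors A `descriptor_matrix` covering all labelled compounds.
#' @return List with `modeling` (data frame `compound_id`, `neg_log_ld50`,
#'   `tox_class`, `label`), `excluded` (the marginal records), `matrix`
#'   (descriptor rows of the modeling compounds) and `labels` (named 0/1
#'   vector).
#' @export
build_modeling_dataset <- function(tox_records, descriptors) {
  rec <- as.data.frame(tox_records, stringsAsFactors = FALSE)
  if (is.null(rec$tox_class))
    rec$tox_class <- assign_toxicity_class(rec$neg_log_ld50)
  missing <- setdiff(rec$compound_id, rownames(descriptors))
  if (length(missing))
    stopf("labelled compound(s) without descriptors: %s",
          paste(missing, collapse = ", "))
  keep <- rec$tox_class != "marginal"
  modeling <- rec[keep, , drop = FALSE]
  if (!nrow(modeling))
    warnf("all compounds are marginal; modeling set is empty")
  modeling$label <- as.integer(modeling$tox_class == "toxic")
  labels <- stats::setNames(modeling$label, modeling$compound_id)
  list(modeling = modeling,
       excluded = rec[!keep, , drop = FALSE],
       matrix = if (nrow(modeling)) dm_subset(descriptors, rows = modeling$compound_id) else NULL,
       labels = labels)
}

#' Partition compounds into external-validation folds
#'
#' Seeded random partition into `n_folds` nearly equal subsets (sizes differ
#' by at most one). Fold i's subset is the untouched external test set; the
#' remaining compounds form that fold's modeling pool.
#'
#' @param ids Compound identifiers.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of length `n_folds`; each element has `fold_index`,
#'   `external_test` and `modeling_pool` id vectors.
#' @export
make_external_folds <- function(ids, n_folds = 5, seed = 1) {
  if (n_folds < 2) stopf("parameter error: n_folds must be >= 2")
  if (length(ids) < n_folds) stopf("need at least n_folds compounds")
  shuffled <- with_seed(seed, sample(ids))
  assignment <- rep(seq_len(n_folds), length.out = length(ids))
  lapply(seq_len(n_folds), function(i) {
    ext <- shuffled[assignment == i]
    list(fold_index = i, external_test = ext,
         modeling_pool = setdiff(ids, ext))
  })
}

#' Balance a modeling pool by structural down-sampling
#'
#' Toxic compounds are typically outnumbered roughly 3:1 by nontoxic ones.
#' For each nontoxic compound the Euclidean distance (in scaled
#' chemical-descriptor space) to its nearest toxic compound is computed, and
#' nontoxic compounds are removed in descending order of that distance --
#' i.e. the ones most structurally dissimilar from any toxic compound go
#' first -- until the nontoxic count is at most `target_ratio` times the
#' toxic count. Toxic compounds are never removed. Deterministic (distance
#' ties broken by compound id).
#'
#' @param ids Compound ids of the pool.
#' @param labels Named 0/1 vector (1 = toxic) covering `ids`.
#' @param chem_matrix Scaled chemical `descriptor_matrix` covering `ids`.
#'   Balancing always uses chemical structure space, whatever descriptors
#'   the downstream model uses.
#' @param target_ratio Maximum nontoxic:toxic ratio to keep (default 1).
#' @return Character vector of retained ids (original order); attribute
#'   `"removed"` lists the discarded nontoxic ids.
#' @export
balance_modeling_set <- function(ids, labels, chem_matrix, target_ratio = 1) {
  lab <- labels[ids]
  if (anyNA(lab)) stopf("labels missing for some ids")
  tox <- ids[lab == 1]; non <- ids[lab == 0]
  if (!length(tox)) stopf("no toxic compounds in the pool")
  n_keep <- floor(target_ratio * length(tox))
  if (length(non) <= n_keep)
    return(structure(ids, removed = character(0)))
  m <- unclass(chem_matrix)
  xt <- m[tox, , drop = FALSE]; xn <- m[non, , drop = FALSE]
  # nearest-toxic distance per nontoxic compound
  cross <- outer(rowSums(xn^2), rowSums(xt^2), "+") - 2 * tcrossprod(xn, xt)
  nearest <- sqrt(pmax(apply(cross, 1L, min), 0))
  ord <- order(-nearest, non)  # farthest first, ties by id
  drop_ids <- non[ord][seq_len(length(non) - n_keep)]
  structure(setdiff(ids, drop_ids), removed = drop_ids)
}

#' Sphere-exclusion training/test splitting
#'
#' Diversity-driven splitting: for each of `n_splits` probe radii (evenly
#' spaced quantiles of the nearest-neighbour-distance distribution), the
#' algorithm repeatedly selects the unassigned compound farthest from the
#' already-selected sphere centres (the first centre is the compound
#' farthest from the data centroid), places it in the training set, and
#' assigns the unassigned compounds inside its sphere alternately to test
#' and training (nearest first, starting with test). Every test compound
#' therefore lies within the probe radius of a training compound, which is
#' what makes kNN interpolation from the training set legitimate. A radius
#' whose split leaves the test fraction outside `[0.10, 0.40]` (or a class
#' missing from training) is inflated stepwise and the adjustment logged.
#'
#' @param ids Compound ids.
#' @param labels Named 0/1 vector covering `ids`.
#' @param matrix `descriptor_matrix` covering `ids` (the modeling space).
#' @param n_splits Number of train/test subdivisions (default 20).
#' @param seed Integer seed (recorded; the construction itself is
#'   deterministic).
#' @param test_bounds Acceptable test-set fraction range.
#' @return List of `n_splits` splits, each with `train`, `test`, `radius`
#'   and `adjusted` (number of radius inflations applied).
#' @export
sphere_exclusion_split <- function(ids, labels, matrix, n_splits = 20,
                                   seed = 1, test_bounds = c(0.10, 0.40)) {
  n <- length(ids)
  if (n < 10L) stopf("need at least 10 compounds")
  lab <- labels[ids]
  m <- unclass(matrix)[ids, , drop = FALSE]
  d <- as.matrix(stats::dist(m))
  nn <- apply(d + diag(Inf, n), 1L, min)
  radii <- stats::quantile(nn, probs = seq_len(n_splits) / (n_splits + 1),
                           names = FALSE, type = 7)
  radii[radii <= 0] <- min(nn[nn > 0], max(d) / n)

  one_split <- function(r) {
    r_eff <- r * (1 + 1e-9) + 1e-12  # tolerate ulp noise at the sphere boundary
    role <- rep(NA_character_, n)  # "train"/"test"
    centers <- integer(0)
    centroid_d <- sqrt(colSums((t(m) - colMeans(m))^2))
    while (anyNA(role)) {
      un <- which(is.na(role))
      cand <- if (!length(centers)) {
        un[order(-centroid_d[un], ids[un])][1L]
      } else {
        md <- apply(d[un, centers, drop = FALSE], 1L, min)
        un[order(-md, ids[un])][1L]
      }
      role[cand] <- "train"
      centers <- c(centers, cand)
      un <- setdiff(which(is.na(role)), cand)
      inside <- un[d[un, cand] <= r_eff]
      if (length(inside)) {
        inside <- inside[order(d[inside, cand], ids[inside])]
        role[inside] <- rep(c("test", "train"), length.out = length(inside))
      }
    }
    # guarantee both classes in training
    for (cl in c(0, 1)) {
      if (!any(lab[role == "train"] == cl)) {
        cand <- which(role == "test" & lab == cl)
        if (!length(cand)) return(NULL)
        role[cand[order(ids[cand])][1L]] <- "train"
      }
    }
    list(train = ids[role == "train"], test = ids[role == "test"])
  }

  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    r <- radii[s]; adjusted <- 0L; sp <- NULL
    repeat {
      sp <- one_split(r)
      frac <- if (is.null(sp)) 0 else length(sp$test) / n
      if (!is.null(sp) && frac >= test_bounds[1L] && frac <= test_bounds[2L])
        break
      if (adjusted >= 25L) break
      r <- r * if (frac < test_bounds[1L]) 1.3 else 0.75
      adjusted <- adjusted + 1L
    }
    if (is.null(sp) || !length(sp$test))
      stopf("sphere exclusion could not produce a usable split at radius %g", radii[s])
    splits[[s]] <- list(train = sp$train, test = sp$test, radius = r,
                        adjusted = adjusted)
  }
  attr(splits, "seed") <- seed
  splits
}

#' Serialize / read modeling splits
#'
#' Splits are written as TSV (`compound_id`, `fold`, `split`, `role`) with
#' the seed recorded in a `# seed=` header so an experiment is replayable
#' and auditable for training/test leakage.
#'
#' @param splits Output of [sphere_exclusion_split()] or a list of folds.
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @param fold Fold index recorded with every row.
#' @return `read_splits` returns a data frame plus `"seed"` attribute.
#' @export
write_splits <- function(splits, path, seed = attr(splits, "seed") %||% NA,
                         fold = 1L) {
  rows <- do.call(rbind, lapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    rbind(data.frame(compound_id = sp$train, fold = fold, split = s,
                     role = "train", stringsAsFactors = FALSE),
          data.frame(compound_id = sp$test, fold = fold, split = s,
                     role = "test", stringsAsFactors = FALSE))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", seed), con)
  utils::write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  seed <- if (grepl("^# seed=", first)) sub("^# seed=", "", first) else NA
  attr(df, "seed") <- seed
  df
}
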