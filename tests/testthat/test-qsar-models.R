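test_that("kNN prediction matches a hand-computed neighbour vote", {
  toy <- toy_points()
  # 5-point training set, hand distance table for query (0.15, 0.05)
  train_ids <- rownames(toy$matrix)[1:5]
  model <- qhtsqsar:::make_knn_model(
    subset = 1:2, k = 3, Xtr = unclass(toy$matrix)[1:5, ],
    ytr = unname(toy$labels[1:5]), train_ids = train_ids,
    training_ccr = 1, test_ccr = 1, z_ad = 0.5)
  q <- c(d1 = 0.15, d2 = 0.05)
  d <- sqrt(rowSums(sweep(unclass(toy$matrix)[1:5, ], 2, q)^2))
  o <- order(d)[1:3]
  expect_identical(sort(train_ids[o]), sort(c("c01", "c02", "c03")))
  pred <- knn_predict(model, q)
  expect_identical(pred$class, 0L)  # all 3 nearest are nontoxic
  expect_equal(pred$mean_dist, mean(d[o]))

  # a training compound predicts its own label at k=1 and is in-domain
  m1 <- qhtsqsar:::make_knn_model(
    subset = 1:2, k = 1, Xtr = unclass(toy$matrix),
    ytr = unname(toy$labels), train_ids = rownames(toy$matrix),
    training_ccr = 1, test_ccr = 1, z_ad = 0.5)
  for (i in seq_len(nrow(toy$matrix))) {
    p <- knn_predict(m1, unclass(toy$matrix)[i, ])
    expect_identical(p$class, as.integer(toy$labels[i]))
    expect_true(p$in_ad)
  }
  # far-away query is out of domain
  far <- knn_predict(m1, c(d1 = 50, d2 = 50))
  expect_false(far$in_ad)
  expect_error(knn_predict(m1, c(d1 = 0.5)), "missing descriptor")
})

test_that("ensemble training recovers planted informative descriptors", {
  sd <- separable_data(n_per_class = 25, p_informative = 2, p_noise = 48,
                       seed = 7, noise = 0.15)
  splits <- sphere_exclusion_split(rownames(sd$matrix), sd$labels, sd$matrix,
                                   n_splits = 4, seed = 3)
  cfg <- knn_config(subset_size = c(2, 6), proposals_per_temp = 40,
                    max_temps = 6, accept_ccr = 0.75, seed = 5)
  ens <- train_knn_ensemble(splits, sd$matrix, sd$labels, cfg)
  expect_gt(length(ens$models), 0)
  has_inf <- vapply(ens$models, function(m)
    any(grepl("^inf_", m$descriptor_subset)), TRUE)
  expect_gte(mean(has_inf), 0.9)
  # every retained model clears the acceptance bar on both criteria
  for (m in ens$models) {
    expect_gte(m$training_ccr, cfg$accept_ccr)
    expect_gte(m$test_ccr, cfg$accept_ccr)
    expect_gt(m$ad_cutoff, 0)
    expect_gte(m$k, 1)
  }
})

test_that("an unreachable acceptance threshold retains nothing, with warnings", {
  sd <- separable_data(n_per_class = 10, seed = 8)
  splits <- sphere_exclusion_split(rownames(sd$matrix), sd$labels, sd$matrix,
                                   n_splits = 2, seed = 1)
  cfg <- knn_config(subset_size = c(2, 4), proposals_per_temp = 10,
                    max_temps = 2, accept_ccr = 1.01, seed = 1)
  w <- capture_warnings(ens <- train_knn_ensemble(splits, sd$matrix,
                                                  sd$labels, cfg))
  expect_length(w, 2)
  expect_true(all(grepl("no model reached", w)))
  expect_length(ens$models, 0)
})

test_that("tiny search spaces are enumerated exhaustively", {
  sd <- separable_data(n_per_class = 12, p_informative = 1, p_noise = 4,
                       seed = 9, noise = 0.1)
  splits <- sphere_exclusion_split(rownames(sd$matrix), sd$labels, sd$matrix,
                                   n_splits = 1, seed = 2)
  cfg <- knn_config(subset_size = c(1, 1), k_range = 1:3,
                    accept_ccr = 0.75, exhaustive_limit = 64, seed = 3)
  ens <- train_knn_ensemble(splits, sd$matrix, sd$labels, cfg)
  # exhaustive oracle over all 5 single-descriptor subsets
  sp <- splits[[1]]
  Xtr <- unclass(sd$matrix)[sp$train, , drop = FALSE]
  Xte <- unclass(sd$matrix)[sp$test, , drop = FALSE]
  expected <- character(0)
  for (j in seq_len(ncol(Xtr))) {
    D2 <- qhtsqsar:::cross_dist2(Xtr[, j, drop = FALSE], Xtr[, j, drop = FALSE])
    loo <- qhtsqsar:::loo_best_ccr(D2, unname(sd$labels[sp$train]), 1:3)
    if (!is.na(loo$ccr) && loo$ccr >= 0.75) {
      tc <- qhtsqsar:::subset_test_ccr(j, loo$k, Xtr,
                                       unname(sd$labels[sp$train]), Xte,
                                       unname(sd$labels[sp$test]))
      if (!is.na(tc) && tc >= 0.75)
        expected <- c(expected, colnames(Xtr)[j])
    }
  }
  got <- sort(vapply(ens$models, function(m) m$descriptor_subset, ""))
  expect_identical(got, sort(expected))
})

test_that("random forest separates clean classes and is seed-deterministic", {
  sd <- separable_data(n_per_class = 20, seed = 10)
  rf <- train_random_forest(sd$matrix, sd$labels, n_trees = 100, seed = 4)
  sc <- rf_score(rf, sd$matrix)
  expect_equal(as.integer(sc > 0.5), unname(sd$labels))
  rf2 <- train_random_forest(sd$matrix, sd$labels, n_trees = 100, seed = 4)
  expect_identical(rf_score(rf2, sd$matrix), sc)
  # planted informative descriptors rank at the top of the importances
  imp <- rf_importance(rf)
  expect_true(all(grepl("^inf_", names(imp)[1:3])))
  one_class <- stats::setNames(rep(1, nrow(sd$matrix)), rownames(sd$matrix))
  expect_error(train_random_forest(sd$matrix, one_class), "single-class")
})

test_that("consensus scores average in-domain votes and flag uncovered compounds", {
  toy <- toy_points()
  base <- function(k) qhtsqsar:::make_knn_model(
    subset = 1:2, k = k, Xtr = unclass(toy$matrix),
    ytr = unname(toy$labels), train_ids = rownames(toy$matrix),
    training_ccr = 1, test_ccr = 1, z_ad = 0.5)
  ens <- structure(list(models = list(base(1), base(1), base(3), base(3)),
                        config = knn_config(),
                        descriptor_universe = colnames(toy$matrix)),
                   class = "knn_ensemble")
  pred <- consensus_predict(ens, toy$matrix)
  # identical models: consensus equals any single model's prediction
  expect_true(all(pred$score %in% c(0, 1)))
  expect_equal(as.integer(pred$score), unname(toy$labels))
  expect_true(all(pred$n_models_covering == 4))
  # a faraway compound is outside every applicability domain
  far <- descriptor_matrix(
    matrix(c(9, 9), 1, 2, dimnames = list("far", c("d1", "d2"))),
    scaled = FALSE)
  pf <- consensus_predict(ens, far)
  expect_identical(pf$n_models_covering, 0)
  expect_true(is.na(pf$score))
  expect_identical(classify_with_thresholds(pf$score), "not_covered")
})

test_that("pooled family scores average coverage-aware", {
  knn <- c(0.8, NA, 0.4, NA)
  rf <- c(0.6, 0.2, NA, NA)
  pooled <- pool_consensus_scores(knn, rf)
  expect_equal(pooled, c(0.7, 0.2, 0.4, NA))
  expect_error(pool_consensus_scores(knn, c(0.1)), "align")
})

test_that("dual-threshold calls follow the documented conventions", {
  expect_identical(classify_with_thresholds(0.75, 0.3, 0.7), "toxic")
  expect_identical(classify_with_thresholds(0.3, 0.3, 0.7), "nontoxic")
  expect_identical(classify_with_thresholds(0.5, 0.3, 0.7), "inconclusive")
  expect_identical(classify_with_thresholds(0.5, 0.5, 0.5), "inconclusive")
  expect_identical(classify_with_thresholds(0.51, 0.5, 0.5), "toxic")
  expect_identical(classify_with_thresholds(0.49, 0.5, 0.5), "nontoxic")
  expect_error(classify_with_thresholds(0.5, 0.8, 0.2), "parameter")
  # grid of scores vs thresholds matches the elementwise comparison oracle
  scores <- seq(0, 1, by = 0.1)
  for (t1 in c(0, 0.25, 0.5)) for (t2 in c(0.5, 0.7, 1)) {
    if (t1 > t2) next
    got <- classify_with_thresholds(scores, t1, t2)
    oracle <- vapply(scores, function(s) {
      if (t1 == t2) {
        if (s < t1) "nontoxic" else if (s > t2) "toxic" else "inconclusive"
      } else if (s <= t1) "nontoxic" else if (s >= t2) "toxic"
      else "inconclusive"
    }, "")
    expect_identical(got, oracle)
  }
})

test_that("evaluation reports satisfy the CCR identity and coverage accounting", {
  calls <- c("toxic", "toxic", "nontoxic", "inconclusive", "not_covered",
             "nontoxic", "toxic", "nontoxic")
  truth <- c(1, 0, 0, 1, 1, 0, 1, 1)
  rep <- evaluate_classification(calls, truth)
  # conclusive: idx 1,2,3,6,7,8 -> toxic truths 1,7,8: predicted toxic 1,7
  expect_equal(rep$sensitivity, 2 / 3)
  expect_equal(rep$specificity, 2 / 3)
  expect_equal(rep$ccr, 0.5 * (rep$sensitivity + rep$specificity),
               tolerance = 1e-12)
  expect_equal(rep$coverage, 6 / 8)
  # perfect predictions
  perfect <- evaluate_classification(c("toxic", "nontoxic"), c(1, 0))
  expect_equal(perfect$ccr, 1)
  expect_equal(perfect$coverage, 1)
  # random calls on balanced truth hover near CCR 0.5 (binomial bound)
  n <- 1000
  truth_big <- rep(c(0, 1), n / 2)
  calls_big <- with_seed(11, sample(c("toxic", "nontoxic"), n, replace = TRUE))
  expect_lt(abs(evaluate_classification(calls_big, truth_big)$ccr - 0.5), 0.05)
})

test_that("threshold heat maps agree with per-cell recomputation and shrink coverage", {
  scores <- with_seed(12, round(runif(40), 2))
  truth <- with_seed(13, sample(c(0, 1), 40, replace = TRUE))
  hm <- threshold_heatmap(scores, truth, grid_step = 0.25)
  ts <- hm$thresholds
  for (i in seq_along(ts)) for (j in i:length(ts)) {
    rep <- evaluate_classification(
      classify_with_thresholds(scores, ts[i], ts[j]), truth)
    expect_equal(hm$ccr[i, j], rep$ccr)
    expect_equal(hm$coverage[i, j], rep$coverage)
  }
  # diagonal equals single-threshold evaluation
  mid <- which(ts == 0.5)
  expect_equal(hm$coverage[mid, mid],
               evaluate_classification(
                 classify_with_thresholds(scores, 0.5, 0.5), truth)$coverage)
  # widening the band never increases coverage (fixed midpoint 0.5)
  covs <- c(hm$coverage[mid, mid],
            hm$coverage[which(ts == 0.25), which(ts == 0.75)],
            hm$coverage[which(ts == 0), which(ts == 1)])
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("ensembles round-trip through JSON with identical predictions", {
  sd <- separable_data(n_per_class = 12, seed = 14)
  splits <- sphere_exclusion_split(rownames(sd$matrix), sd$labels, sd$matrix,
                                   n_splits = 2, seed = 5)
  cfg <- knn_config(subset_size = c(2, 4), proposals_per_temp = 15,
                    max_temps = 3, accept_ccr = 0.8, seed = 6)
  ens <- train_knn_ensemble(splits, sd$matrix, sd$labels, cfg)
  expect_gt(length(ens$models), 0)
  tf <- withr::local_tempfile(fileext = ".json")
  write_ensemble_json(ens, tf)
  back <- read_ensemble_json(tf)
  expect_equal(length(back$models), length(ens$models))
  p1 <- consensus_predict(ens, sd$matrix)
  p2 <- consensus_predict(back, sd$matrix)
  expect_equal(p2$score, p1$score)
})
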