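test_that("biological descriptor layout is panel x grid with zero-fill for missing lines", {
  grid <- default_concentration_grid()
  profs <- tiny_profiles()
  panel2 <- c("BJ", "Jurkat")
  bio <- build_bio_descriptors(profs, panel = panel2, grid = grid)
  expect_equal(ncol(bio), 2 * 14)
  expect_equal(nrow(bio), 2)
  expect_true(all(attr(bio, "origin") == "biological"))

  # hand-laid-out oracle for one compound/line block
  expect_equal(unname(unclass(bio)["cpdA", 1:14]),
               as.numeric(profs[profs$compound_id == "cpdA" &
                                profs$cell_line == "BJ", -(1:2)]))
  # full 13-line panel: 182 columns, absent lines zero-filled and flagged
  bio13 <- build_bio_descriptors(profs, panel = qhts_cell_lines(), grid = grid)
  expect_equal(ncol(bio13), 182)
  expect_true(all(unclass(bio13)[, grep("^HepG2@", colnames(bio13))] == 0))
  expect_setequal(attr(bio13, "missing_lines"), c("cpdA", "cpdB"))
  # one cell line -> 14 columns
  expect_equal(ncol(build_bio_descriptors(
    profs[profs$cell_line == "BJ", ], panel = "BJ", grid = grid)), 14)

  # unknown cell line is an error naming it
  expect_error(build_bio_descriptors(profs, panel = "BJ", grid = grid),
               "Jurkat")
})

test_that("curve fingerprints encode quartile bins with the documented boundaries", {
  # the canonical worked curve: ten low, one in [25,50), three > 75 -> 127
  fp <- encode_fingerprint(generate_worked_examples()$fingerprint127)
  expect_identical(fp$bits, paste0(strrep("00", 10), "01", "111111"))
  expect_equal(fp$int_value, 127)

  expect_equal(encode_fingerprint(rep(0, 14))$int_value, 0)
  expect_equal(encode_fingerprint(rep(80, 14))$int_value, 2^28 - 1)

  # boundary convention: closed-left bins
  expect_identical(encode_fingerprint(c(24.999, 25, 50, 75), 100)$bits,
                   "00011011")

  # monotone: raising any response never decreases the integer value
  for (seed in 1:10) {
    x <- with_seed(seed, runif(14, 0, 100))
    base <- encode_fingerprint(x)$int_value
    i <- with_seed(seed + 50, sample(14, 1))
    x[i] <- min(100, x[i] + 30)
    expect_gte(encode_fingerprint(x)$int_value, base)
  }
})

test_that("chemical descriptor curation matches a greedy brute-force oracle", {
  # constant and all-but-one-constant columns are removed
  m <- with_seed(1, matrix(rnorm(40), 8, 5,
                           dimnames = list(sprintf("c%d", 1:8),
                                           sprintf("d%d", 1:5))))
  m[, 2] <- 3
  m[, 4] <- c(7, rep(1, 7))
  dm <- descriptor_matrix(m)
  out <- filter_chemical_descriptors(dm, seed = 1)
  expect_false(any(c("d2", "d4") %in% colnames(out)))

  # duplicated column: exactly one member survives
  m2 <- with_seed(2, matrix(rnorm(30), 10, 3,
                            dimnames = list(sprintf("c%d", 1:10),
                                            c("a", "b", "dup"))))
  m2[, "dup"] <- m2[, "a"]
  out2 <- filter_chemical_descriptors(descriptor_matrix(m2), seed = 5)
  expect_equal(sum(c("a", "dup") %in% colnames(out2)), 1L)

  # greedy oracle replayed with the same seed on 10 random columns
  greedy_oracle <- function(m, cutoff, seed) {
    lowvar <- vapply(seq_len(ncol(m)), function(j)
      nrow(m) - max(table(m[, j])) <= 1L, TRUE)
    m <- m[, !lowvar, drop = FALSE]
    with_seed(seed, {
      repeat {
        r2 <- suppressWarnings(stats::cor(m))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 1
        if (max(r2) <= cutoff) break
        w <- which(r2 == max(r2), arr.ind = TRUE)
        w <- w[w[, 1] < w[, 2], , drop = FALSE]
        nm <- cbind(colnames(m)[w[, 1]], colnames(m)[w[, 2]])
        pick <- w[order(nm[, 1], nm[, 2])[1], ]
        drop_j <- if (stats::runif(1) < 0.5) pick[[1]] else pick[[2]]
        m <- m[, -drop_j, drop = FALSE]
      }
      m
    })
  }
  base <- with_seed(7, matrix(rnorm(200), 20, 10))
  m3 <- cbind(base, base[, 1:3] + with_seed(8, matrix(rnorm(60, sd = 0.01), 20, 3)))
  dimnames(m3) <- list(sprintf("c%d", 1:20), sprintf("d%02d", 1:13))
  expected <- greedy_oracle(m3, 0.95, seed = 11)
  got <- filter_chemical_descriptors(descriptor_matrix(m3), 0.95, seed = 11)
  expect_identical(colnames(got), colnames(expected))
  # no surviving pair exceeds the cutoff (exhaustive check)
  r2 <- stats::cor(unclass(got))^2; diag(r2) <- 0
  expect_lt(max(r2), 0.95 + 1e-12)
  # every column spans [0,1] exactly
  expect_equal(unname(apply(unclass(got), 2, min)), rep(0, ncol(got)))
  expect_equal(unname(apply(unclass(got), 2, max)), rep(1, ncol(got)))
})

test_that("external compounds are scaled with training limits only, clipped to [0,1]", {
  train <- descriptor_matrix(
    matrix(c(0, 5, 10, 2, 4, 6), 3, 2,
           dimnames = list(c("a", "b", "c"), c("x", "y"))))
  sc <- range_scale(train)
  ext <- descriptor_matrix(
    matrix(c(-5, 20, 3, 5), 2, 2,
           dimnames = list(c("q1", "q2"), c("x", "y"))))
  out <- apply_scaling(ext, sc)
  expect_equal(unname(unclass(out)[, "x"]), c(0, 1))   # clipped
  expect_equal(unname(unclass(out)[, "y"]), c(0.25, 0.75))
})

test_that("hybrid combination concatenates scaled spaces and rejects mismatches", {
  chem <- range_scale(descriptor_matrix(
    matrix(with_seed(3, rnorm(20)), 5, 4,
           dimnames = list(sprintf("c%d", 1:5), sprintf("chem%d", 1:4)))))
  bio <- descriptor_matrix(
    matrix(with_seed(4, runif(15, 0, 100)), 5, 3,
           dimnames = list(sprintf("c%d", 1:5), sprintf("BJ@%d", 1:3))),
    origin = "biological")
  hy <- combine_hybrid(chem, bio)
  expect_equal(ncol(hy), 7)
  expect_identical(attr(hy, "origin"),
                   c(rep("chemical", 4), rep("biological", 3)))
  # bio responses divided by 100
  expect_equal(unclass(hy)[, 5:7], unclass(bio) / 100,
               ignore_attr = TRUE)
  # shuffled compound order is an error
  bio_shuffled <- qhtsqsar:::dm_subset(bio, rows = c(2, 1, 3, 4, 5))
  expect_error(combine_hybrid(chem, bio_shuffled), "order|mismatch")
  # empty biological matrix: output equals the chemical matrix
  bio0 <- qhtsqsar:::dm_subset(bio, cols = integer(0))
  expect_equal(unclass(combine_hybrid(chem, bio0)), unclass(chem),
               ignore_attr = TRUE)
})

test_that("pairwise distance comparison matches a double-loop oracle", {
  n <- 20
  chem <- descriptor_matrix(
    matrix(with_seed(5, runif(n * 3)), n, 3,
           dimnames = list(sprintf("c%02d", 1:n), c("a", "b", "c"))),
    scaled = TRUE)
  bio <- descriptor_matrix(
    matrix(with_seed(6, runif(n * 4)), n, 4,
           dimnames = list(sprintf("c%02d", 1:n), sprintf("L@%d", 1:4))),
    origin = "biological", scaled = TRUE)
  labels <- stats::setNames(rep(c(1, 0), each = n / 2), rownames(chem))
  out <- pairwise_distance_comparison(chem, bio, labels)
  expect_equal(nrow(out$pairs), choose(n, 2))

  # brute-force double loop
  cd <- bd <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cd <- c(cd, sqrt(sum((unclass(chem)[i, ] - unclass(chem)[j, ])^2)))
    bd <- c(bd, sqrt(sum((unclass(bio)[i, ] - unclass(bio)[j, ])^2)))
  }
  expect_equal(out$pairs$chem_distance, cd)
  expect_equal(out$pairs$bio_distance, bd)
  expect_equal(out$correlation, stats::cor(cd, bd))
  # identical rows give zero distance; 3 compounds -> 3 pairs
  tri <- qhtsqsar:::dm_subset(chem, rows = c(1, 1, 2))
  rownames_fix <- unclass(tri); rownames(rownames_fix) <- c("p", "q", "r")
  tri <- descriptor_matrix(rownames_fix, scaled = TRUE)
  out3 <- pairwise_distance_comparison(tri, tri)
  expect_equal(nrow(out3$pairs), 3)
  expect_equal(out3$pairs$chem_distance[1], 0)
})

test_that("descriptor matrices round-trip through TSV", {
  m <- descriptor_matrix(
    matrix(with_seed(9, rnorm(12)), 4, 3,
           dimnames = list(sprintf("c%d", 1:4), c("d1", "d2", "d3"))))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_matrix(m, tf)
  back <- read_descriptor_matrix(tf)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(m))
})
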