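#' Construct a descriptor matrix
#'
#' A thin wrapper around a dense numeric matrix (rows = compounds, columns =
#' named descriptors) carrying per-column origin tags (`"chemical"` or
#' `"biological"`), a `scaled` flag and, once scaled, the per-column
#' min/max used so that external compounds can be transformed with the
#' training parameters only.
#'
#' @param values Numeric matrix with rownames (compound ids) and unique
#'   colnames (descriptor names); no missing values.
#' @param origin `"chemical"`, `"biological"`, or a per-column vector.
#' @param scaled Logical: are all columns already in `[0, 1]`?
#' @param scale_limits Optional 2-row matrix (`min`, `max`) per column.
#' @return A `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, origin = "chemical", scaled = FALSE,
                              scale_limits = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) && nrow(values) > 0L)
    stopf("descriptor matrix needs compound rownames")
  if (is.null(colnames(values))) {
    if (ncol(values) > 0L)
      stopf("descriptor matrix needs descriptor colnames")
    dimnames(values) <- list(rownames(values), character(0))
  }
  if (anyDuplicated(colnames(values)))
    stopf("descriptor names must be unique")
  if (anyNA(values))
    stopf("descriptor matrix must not contain missing values")
  origin <- rep_len(origin, ncol(values))
  if (!all(origin %in% c("chemical", "biological")))
    stopf("origin must be 'chemical' or 'biological'")
  structure(values, origin = origin, scaled = isTRUE(scaled),
            scale_limits = scale_limits,
            class = c("descriptor_matrix", "matrix", "array"))
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  o <- table(attr(x, "origin"))
  cat(sprintf("descriptor matrix: %d compounds x %d descriptors (%s)%s\n",
              nrow(x), ncol(x),
              paste(sprintf("%d %s", o, names(o)), collapse = ", "),
              if (isTRUE(attr(x, "scaled"))) ", range-scaled" else ""))
  invisible(x)
}

#' Subset a descriptor matrix, keeping its metadata in sync
#'
#' Plain `[` subsetting drops the origin tags and scaling metadata; this
#' keeps them aligned with the retained columns.
#'
#' @param x A `descriptor_matrix`.
#' @param rows,cols Row/column selector (names or indices), or `NULL` to
#'   keep all.
#' @return A `descriptor_matrix`.
#' @export
subset_descriptors <- function(x, rows = NULL, cols = NULL) {
  dm_subset(x, rows = rows, cols = cols)
}

# internal alias used throughout
dm_subset <- function(x, rows = NULL, cols = NULL) {
  origin <- attr(x, "origin"); lim <- attr(x, "scale_limits")
  sc <- attr(x, "scaled")
  m <- unclass(x)
  if (!is.null(cols)) {
    ci <- if (is.character(cols)) match(cols, colnames(m)) else cols
    m <- m[, ci, drop = FALSE]
    origin <- origin[ci]
    if (!is.null(lim)) lim <- lim[, ci, drop = FALSE]
  }
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  descriptor_matrix(m, origin = origin, scaled = sc, scale_limits = lim)
}

#' Assemble biological descriptors from filtered qHTS profiles
#'
#' Each (cell line, concentration) pair defines one biological descriptor;
#' its value is the (noise-filtered) percent-viability-loss response. With
#' the default 13-line panel and 14-point grid this yields the canonical
#' 14 x 13 = 182 biological descriptors per compound. Compounds missing a
#' cell line receive all-zero (baseline) values in that line's columns and
#' are flagged.
#'
#' @param profiles A [qhts_profiles()] object (already filtered, or raw if
#'   `params` is supplied, in which case [filter_profiles()] is applied).
#' @param params Optional [filter_params()]; `NULL` uses profiles as-is.
#' @param panel Cell-line labels defining the column blocks.
#' @param grid Concentration grid; defaults to the profiles' own grid.
#' @return A `descriptor_matrix` with `length(panel) * length(grid)`
#'   biological columns named `<cell_line>@<concentration>`; attribute
#'   `"missing_lines"` names compounds lacking one or more cell lines.
#' @export
build_bio_descriptors <- function(profiles, params = NULL,
                                  panel = qhts_cell_lines(),
                                  grid = attr(profiles, "concentrations")) {
  stopifnot(inherits(profiles, "qhts_profiles"))
  if (!is.null(params)) profiles <- filter_profiles(profiles, params)
  conc <- attr(profiles, "concentrations")
  if (length(conc) != length(grid) || any(abs(conc - grid) > 1e-9))
    stopf("profiles are on a different concentration grid than requested")
  unknown <- setdiff(unique(profiles$cell_line), panel)
  if (length(unknown))
    stopf("profiles contain cell line(s) outside the panel: %s",
          paste(unknown, collapse = ", "))
  ids <- unique(profiles$compound_id)
  resp <- response_matrix(profiles)
  ncol_per_line <- length(grid)
  out <- matrix(0, nrow = length(ids), ncol = length(panel) * ncol_per_line,
                dimnames = list(ids, paste0(
                  rep(panel, each = ncol_per_line), "@",
                  rep(vapply(grid, format_conc, ""), length(panel)))))
  for (j in seq_along(panel)) {
    sel <- profiles$cell_line == panel[j]
    if (!any(sel)) next
    rows <- match(profiles$compound_id[sel], ids)
    out[rows, (j - 1L) * ncol_per_line + seq_len(ncol_per_line)] <-
      resp[sel, , drop = FALSE]
  }
  have <- table(factor(profiles$compound_id, levels = ids))
  missing_lines <- ids[have < length(panel)]
  structure(descriptor_matrix(out, origin = "biological"),
            missing_lines = missing_lines)
}

#' Encode a filtered response curve as a binary fingerprint
#'
#' Each concentration contributes two bits determined by which quarter of
#' the response scale the (filtered) response falls in: `00` below 25% of
#' `scale_max`, `01` in `[25, 50)`%, `10` in `[50, 75)`%, `11` at or above
#' 75%. Bits are concatenated from the lowest to the highest concentration,
#' and the integer value reads the bit string most-significant-bit first, so
#' the highest-concentration pair occupies the least significant bits.
#' Fingerprints summarise curve shape for reporting; they are not model
#' inputs.
#'
#' @param responses Filtered response vector in `[0, scale_max]`.
#' @param scale_max Full response scale (percent); the quartile bins are
#'   quarters of this value, not of the per-curve maximum.
#' @return A `curve_fingerprint`: list with `bits` (character, 2 bits per
#'   concentration) and `int_value` (numeric integer value).
#' @export
encode_fingerprint <- function(responses, scale_max = 100) {
  r <- as.numeric(responses)
  if (!length(r)) stopf("responses must be non-empty")
  if (anyNA(r)) stopf("responses must not contain missing values")
  bin <- pmin(pmax(floor(r / (scale_max / 4)), 0), 3)
  bits <- paste(c("00", "01", "10", "11")[bin + 1L], collapse = "")
  int_value <- sum(bin * 4^(rev(seq_along(bin)) - 1L))
  structure(list(bits = bits, int_value = int_value),
            class = "curve_fingerprint")
}

#' @export
print.curve_fingerprint <- function(x, ...) {
  cat(sprintf("curve fingerprint: %s = %.0f\n", x$bits, x$int_value))
  invisible(x)
}

#' Range-scale a descriptor matrix to the unit interval
#'
#' @param mat A `descriptor_matrix` (unscaled).
#' @return The matrix scaled column-wise to `[0, 1]`, with the per-column
#'   min/max retained in `attr(, "scale_limits")`.
#' @export
range_scale <- function(mat) {
  stopifnot(inherits(mat, "descriptor_matrix"))
  m <- unclass(mat)
  lo <- apply(m, 2L, min); hi <- apply(m, 2L, max)
  if (any(hi - lo <= 0))
    stopf("zero-range column(s) at scaling time: %s",
          paste(colnames(m)[hi - lo <= 0], collapse = ", "))
  scaled <- sweep(sweep(m, 2L, lo, "-"), 2L, hi - lo, "/")
  descriptor_matrix(scaled, origin = attr(mat, "origin"), scaled = TRUE,
                    scale_limits = rbind(min = lo, max = hi))
}

#' Scale external compounds with training scaling parameters
#'
#' @param mat A `descriptor_matrix` of new compounds (same columns).
#' @param limits The `scale_limits` attribute from a training
#'   [range_scale()] call (or a scaled training matrix).
#' @param clip Clip transformed values into `[0, 1]` (default) so external
#'   compounds cannot leave the training descriptor range.
#' @return Scaled `descriptor_matrix`.
#' @export
apply_scaling <- function(mat, limits, clip = TRUE) {
  stopifnot(inherits(mat, "descriptor_matrix"))
  if (inherits(limits, "descriptor_matrix"))
    limits <- attr(limits, "scale_limits")
  if (is.null(limits)) stopf("no scaling limits supplied")
  if (!all(colnames(mat) %in% colnames(limits)))
    stopf("scaling limits missing for: %s",
          paste(setdiff(colnames(mat), colnames(limits)), collapse = ", "))
  lim <- limits[, colnames(mat), drop = FALSE]
  m <- sweep(sweep(unclass(mat), 2L, lim["min", ], "-"),
             2L, lim["max", ] - lim["min", ], "/")
  if (clip) m <- pmin(pmax(m, 0), 1)
  descriptor_matrix(m, origin = attr(mat, "origin"), scaled = TRUE,
                    scale_limits = lim)
}

#' Curate a chemical descriptor matrix
#'
#' Reproduces the standard chemical-descriptor preparation: (1) remove
#' low-variance columns (all values, or all but one, identical); (2) while
#' any pair of surviving columns has squared Pearson correlation above
#' `r2_cutoff`, take the worst pair (ties broken by descriptor name) and
#' remove one member chosen at random; (3) range-scale survivors to
#' `[0, 1]`, retaining the min/max per column for transforming external
#' compounds. The removal sequence is reproducible given `seed`.
#'
#' @param mat A chemical-origin `descriptor_matrix`, at least two compounds.
#' @param r2_cutoff Squared-correlation cutoff (default 0.95).
#' @param seed Integer seed driving the random member choice.
#' @return A scaled `descriptor_matrix`; attribute `"removed"` is a data
#'   frame (`descriptor`, `reason`) of dropped columns.
#' @export
filter_chemical_descriptors <- function(mat, r2_cutoff = 0.95, seed = 1) {
  stopifnot(inherits(mat, "descriptor_matrix"))
  if (nrow(mat) < 2L) stopf("need at least 2 compounds")
  m <- unclass(mat)
  removed <- data.frame(descriptor = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  # low variance: at most one value differs from the modal value
  lowvar <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    nrow(m) - max(tab) <= 1L
  }, TRUE)
  if (any(lowvar)) {
    removed <- rbind(removed, data.frame(
      descriptor = colnames(m)[lowvar], reason = "low_variance",
      stringsAsFactors = FALSE))
    m <- m[, !lowvar, drop = FALSE]
  }
  if (!ncol(m)) stopf("no descriptors survive the variance filter")
  m <- with_seed(seed, {
    repeat {
      r2 <- suppressWarnings(stats::cor(m))^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 1  # post-filter degenerate correlation: treat as violation
      if (max(r2) <= r2_cutoff) break
      w <- which(r2 == max(r2), arr.ind = TRUE)
      w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
      pair_names <- cbind(colnames(m)[w[, 1L]], colnames(m)[w[, 2L]])
      ord <- order(pair_names[, 1L], pair_names[, 2L])
      pair <- w[ord[1L], ]
      drop_j <- if (stats::runif(1) < 0.5) pair[[1L]] else pair[[2L]]
      removed <- rbind(removed, data.frame(
        descriptor = colnames(m)[drop_j], reason = "high_correlation",
        stringsAsFactors = FALSE))
      m <- m[, -drop_j, drop = FALSE]
    }
    m
  })
  out <- range_scale(descriptor_matrix(m, origin = "chemical"))
  attr(out, "removed") <- removed
  out
}

#' Combine chemical and biological descriptors into a hybrid matrix
#'
#' Column-wise concatenation over an identical, identically ordered compound
#' set. Chemical descriptors must already be range-scaled; biological
#' descriptors (percent responses) are divided by 100 if not yet scaled, so
#' that all descriptors share the `[0, 1]` range used by Euclidean
#' distances in kNN.
#'
#' @param chem Scaled chemical `descriptor_matrix`.
#' @param bio Biological `descriptor_matrix` (percent scale or `[0, 1]`).
#' @return Hybrid `descriptor_matrix` with origin tags preserved.
#' @export
combine_hybrid <- function(chem, bio) {
  stopifnot(inherits(chem, "descriptor_matrix"),
            inherits(bio, "descriptor_matrix"))
  if (!identical(rownames(chem), rownames(bio))) {
    sym <- c(setdiff(rownames(chem), rownames(bio)),
             setdiff(rownames(bio), rownames(chem)))
    if (length(sym))
      stopf("compound set mismatch; symmetric difference: %s",
            paste(sym, collapse = ", "))
    stopf("compound order differs between the chemical and biological matrices")
  }
  if (!isTRUE(attr(chem, "scaled")))
    stopf("chemical matrix must be range-scaled before combining")
  b <- unclass(bio)
  if (!isTRUE(attr(bio, "scaled"))) b <- b / 100
  descriptor_matrix(cbind(unclass(chem), b),
                    origin = c(attr(chem, "origin"), attr(bio, "origin")),
                    scaled = TRUE)
}

#' Compare pairwise compound distances in chemical vs biological space
#'
#' Computes Euclidean distances between all unordered compound pairs in each
#' descriptor space, labels each pair by the toxicity classes of its
#' members, and reports the Pearson correlation between the two distance
#' vectors -- the standard check of whether chemical and biological
#' similarity agree.
#'
#' @param chem,bio `descriptor_matrix` objects over the same compounds.
#' @param labels Named vector of class labels (`1`/`"toxic"` vs
#'   `0`/`"nontoxic"`), or `NULL` to skip pair classing.
#' @return List with `pairs` (data frame: `id1`, `id2`, `chem_distance`,
#'   `bio_distance`, `pair_class` in `both_toxic` / `both_nontoxic` /
#'   `mixed`) and `correlation` (Pearson r between the distance vectors).
#' @export
pairwise_distance_comparison <- function(chem, bio, labels = NULL) {
  if (!identical(rownames(chem), rownames(bio)))
    stopf("matched compound sets required")
  n <- nrow(chem)
  if (n < 2L) stopf("need at least 2 compounds")
  dc <- stats::dist(unclass(chem))
  db <- stats::dist(unclass(bio))
  idx <- utils::combn(n, 2L)
  ids <- rownames(chem)
  pair_class <- NA_character_
  if (!is.null(labels)) {
    lab <- labels[ids]
    tox <- lab %in% c(1, "toxic", "1")
    t1 <- tox[idx[1L, ]]; t2 <- tox[idx[2L, ]]
    pair_class <- ifelse(t1 & t2, "both_toxic",
                         ifelse(!t1 & !t2, "both_nontoxic", "mixed"))
  }
  pairs <- data.frame(id1 = ids[idx[1L, ]], id2 = ids[idx[2L, ]],
                      chem_distance = as.vector(dc),
                      bio_distance = as.vector(db),
                      pair_class = pair_class, stringsAsFactors = FALSE)
  list(pairs = pairs,
       correlation = stats::cor(pairs$chem_distance, pairs$bio_distance))
}

#' Read / write descriptor matrices as TSV
#'
#' First column `compound_id`, remaining columns named descriptors. Origin
#' and scaled status are not stored in the file; supply them on read.
#'
#' @param mat A `descriptor_matrix`.
#' @param path File path.
#' @param origin,scaled Metadata to attach on read.
#' @param sep Field delimiter.
#' @return `read_descriptor_matrix` returns a `descriptor_matrix`.
#' @export
write_descriptor_matrix <- function(mat, path, sep = "\t") {
  df <- data.frame(compound_id = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(path, origin = "chemical",
                                   scaled = FALSE, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "compound_id")
    stopf("format error: first column must be compound_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$compound_id
  descriptor_matrix(m, origin = origin, scaled = scaled)
}

#' Write curve fingerprints for a profile table
#'
#' @param profiles Filtered [qhts_profiles()].
#' @param path Output TSV path.
#' @param scale_max Response scale passed to [encode_fingerprint()].
#' @return Invisibly, the data frame written (`compound_id`, `cell_line`,
#'   `bits`, `int_value`).
#' @export
write_fingerprints <- function(profiles, path, scale_max = 100) {
  resp <- response_matrix(profiles)
  fp <- lapply(seq_len(nrow(resp)),
               function(i) encode_fingerprint(resp[i, ], scale_max))
  df <- data.frame(compound_id = profiles$compound_id,
                   cell_line = profiles$cell_line,
                   bits = vapply(fp, `[[`, "", "bits"),
                   int_value = vapply(fp, `[[`, 0, "int_value"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
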