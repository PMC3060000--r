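#' Noise-filter parameters
#'
#' The two user-set parameters of the concentration-response noise filter,
#' both in percent-response units. `thr` (baseline threshold, THR) is the
#' largest deviation from baseline still treated as "no response"; `mxdv`
#' (maximum curve deviation, MXDV) is the largest drop between adjacent
#' concentrations still considered unchanged, i.e. not a monotonicity
#' violation.
#'
#' @param thr Baseline threshold, in `[0, 100]` percent.
#' @param mxdv Maximum curve deviation, in `[0, 100]` percent.
#' @return A `filter_params` list.
#' @export
filter_params <- function(thr = 15, mxdv = 5) {
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) ||
      thr < 0 || thr > 100)
    stopf("parameter error: thr must be a single value in [0, 100]")
  if (!is.numeric(mxdv) || length(mxdv) != 1L || is.na(mxdv) ||
      mxdv < 0 || mxdv > 100)
    stopf("parameter error: mxdv must be a single value in [0, 100]")
  structure(list(thr = thr, mxdv = mxdv), class = "filter_params")
}

#' Zero out baseline-level responses
#'
#' Any response whose absolute value is below `thr` is treated as baseline
#' noise and set to 0. Negative responses (apparent viability increase) that
#' survive the threshold are clipped to 0, since all downstream descriptors
#' live on the 0-100 percent-toxicity scale.
#'
#' @param responses Numeric vector of percent-viability-loss responses.
#' @param thr Baseline threshold in `[0, 100]`.
#' @return Numeric vector of the same length.
#' @export
apply_baseline_threshold <- function(responses, thr) {
  filter_params(thr = thr)  # validates
  r <- as.numeric(responses)
  r[abs(r) < thr] <- 0
  r[r < 0] <- 0
  r
}

#' Repair monotonicity violations in a response curve
#'
#' Scans the curve from the lowest to the highest concentration keeping a
#' running maximum of the responses accepted so far. A point that falls more
#' than `mxdv` below that running maximum violates the expected monotone
#' (non-decreasing, within tolerance) toxic response pattern and is flagged.
#' Each maximal run of flagged points is replaced by linear interpolation
#' between its nearest unflagged neighbours; a flagged run ending the curve
#' is replaced by the last unflagged value (constant extension). The output
#' satisfies `r[i+1] >= r[i] - mxdv` everywhere.
#'
#' @param responses Numeric vector (typically baseline-thresholded first).
#' @param mxdv Maximum curve deviation in `[0, 100]`.
#' @return Numeric vector of the same length; attribute `"replaced"` lists
#'   the indices of repaired points (integer(0) when the curve was clean).
#' @export
enforce_monotonicity <- function(responses, mxdv) {
  filter_params(mxdv = mxdv)  # validates
  r <- as.numeric(responses)
  n <- length(r)
  flagged <- logical(n)
  run_max <- -Inf
  for (i in seq_len(n)) {
    if (r[i] < run_max - mxdv) flagged[i] <- TRUE
    else run_max <- max(run_max, r[i])
  }
  if (any(flagged)) {
    idx <- which(flagged)
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (run in runs) {
      a <- run[1L]; b <- run[length(run)]
      left <- r[a - 1L]  # first point can never be flagged
      if (b < n) {
        right <- r[b + 1L]
        r[run] <- left + (seq_along(run) / (length(run) + 1L)) * (right - left)
      } else {
        r[run] <- left
      }
    }
  }
  structure(r, replaced = which(flagged))
}

#' Apply the full noise filter to a response curve
#'
#' Composition of [apply_baseline_threshold()] (THR) followed by
#' [enforce_monotonicity()] (MXDV) -- baseline flattening first so that
#' baseline jitter cannot seed a spurious running maximum. Deterministic and
#' idempotent.
#'
#' @param responses Numeric response vector.
#' @param params A [filter_params()] object.
#' @return Filtered numeric vector with attribute `"replaced"` (indices
#'   repaired by the monotonicity step).
#' @export
filter_profile <- function(responses, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  enforce_monotonicity(apply_baseline_threshold(responses, params$thr),
                       params$mxdv)
}

#' Filter every curve in a profile table
#'
#' @param profiles A [qhts_profiles()] object.
#' @param params A [filter_params()] object.
#' @return A `qhts_profiles` object with filtered responses; attribute
#'   `"filter_log"` is a data frame (`compound_id`, `cell_line`,
#'   `replaced`) listing, per curve, the comma-separated indices of points
#'   repaired by the monotonicity step (empty string when none).
#' @export
filter_profiles <- function(profiles, params = filter_params()) {
  stopifnot(inherits(profiles, "qhts_profiles"))
  resp <- response_matrix(profiles)
  replaced <- character(nrow(resp))
  for (i in seq_len(nrow(resp))) {
    f <- filter_profile(resp[i, ], params)
    replaced[i] <- paste(attr(f, "replaced"), collapse = ",")
    resp[i, ] <- f
  }
  out <- qhts_profiles(profiles$compound_id, profiles$cell_line, resp,
                       concentrations = attr(profiles, "concentrations"),
                       panel = unique(profiles$cell_line))
  attr(out, "filter_log") <- data.frame(
    compound_id = profiles$compound_id, cell_line = profiles$cell_line,
    replaced = replaced, stringsAsFactors = FALSE)
  attr(out, "filter_params") <- params
  out
}
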