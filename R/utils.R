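#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so library functions do not disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG state alone.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; stays well below 2^31.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + as.numeric(offset) * 7919) %% 2147483629 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Format a concentration for use in a column header; stable round trip.
format_conc <- function(x) format(signif(x, 6), trim = TRUE, scientific = FALSE)
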