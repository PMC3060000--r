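#' The default cytotoxicity assay panel
#'
#' Thirteen cell lines screened for cell-viability loss in the qHTS campaign
#' the package models: human and rodent lines covering fibroblast, immune,
#' kidney, liver, neuronal, endothelial and mesenchymal lineages.
#'
#' @return A data frame with columns `cell_line` (the label used throughout
#'   the package), `aid` (PubChem BioAssay identifier of the source screen)
#'   and `description`.
#' @export
qhts_assay_panel <- function() {
  data.frame(
    cell_line = c("BJ", "Jurkat", "HEK293", "HepG2", "MRC-5", "SK-N-SH",
                  "N2a", "NIH3T3", "HUV-EC-C", "H-4-II-E", "SH-SY-5Y",
                  "RPTC", "MSC"),
    aid = c(421L, 426L, 427L, 433L, 434L, 435L, 540L, 541L, 542L, 543L,
            544L, 545L, 546L),
    description = c(
      "human foreskin fibroblast", "human acute T-cell leukemia",
      "human embryonic kidney", "human hepatoma", "human lung fibroblast",
      "human neuroblastoma", "mouse neuroblastoma",
      "mouse embryonic fibroblast", "human vascular endothelium",
      "rat hepatoma", "human neuroblastoma", "rat renal proximal tubule",
      "human renal glomeruli (mesenchymal)"),
    stringsAsFactors = FALSE
  )
}

#' @rdname qhts_assay_panel
#' @export
qhts_cell_lines <- function() qhts_assay_panel()$cell_line

#' Default 14-point concentration grid
#'
#' Geometric series of assay concentrations in micromolar, spanning the
#' screened range 0.006--92 uM.
#'
#' @param n Number of concentrations.
#' @param cmin,cmax Lowest and highest concentration (uM).
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
default_concentration_grid <- function(n = 14, cmin = 0.006, cmax = 92) {
  exp(seq(log(cmin), log(cmax), length.out = n))
}

#' Construct a table of concentration-response profiles
#'
#' A `qhts_profiles` object is a data frame with one row per
#' (compound, cell line) pair and one numeric response column per assay
#' concentration. Responses are percent loss of cell viability: 0 means no
#' effect, 100 complete loss. The shared concentration grid (uM, strictly
#' increasing) is carried in the `"concentrations"` attribute.
#'
#' @param compound_id Character vector of compound identifiers.
#' @param cell_line Character vector of cell-line labels, same length.
#' @param responses Numeric matrix, one row per profile, one column per
#'   concentration.
#' @param concentrations Strictly increasing numeric vector of assay
#'   concentrations (uM), one per response column.
#' @param panel Allowed cell-line labels.
#' @return A `qhts_profiles` data frame.
#' @export
qhts_profiles <- function(compound_id, cell_line, responses,
                          concentrations = default_concentration_grid(),
                          panel = qhts_cell_lines()) {
  responses <- as.matrix(responses)
  if (length(compound_id) != length(cell_line) ||
      nrow(responses) != length(compound_id))
    stopf("compound_id, cell_line and rows of responses must align")
  if (ncol(responses) != length(concentrations))
    stopf("responses has %d columns but %d concentrations were given",
          ncol(responses), length(concentrations))
  if (any(diff(concentrations) <= 0))
    stopf("concentrations must be strictly increasing")
  bad <- setdiff(unique(cell_line), panel)
  if (length(bad))
    stopf("unknown cell line(s): %s", paste(bad, collapse = ", "))
  key <- paste(compound_id, cell_line, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (compound, cell line) pairs: %s",
          paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  df <- data.frame(compound_id = as.character(compound_id),
                   cell_line = as.character(cell_line),
                   responses, stringsAsFactors = FALSE)
  names(df) <- c("compound_id", "cell_line",
                 paste0("c_", vapply(concentrations, format_conc, "")))
  attr(df, "concentrations") <- as.numeric(concentrations)
  class(df) <- c("qhts_profiles", "data.frame")
  df
}

#' @export
print.qhts_profiles <- function(x, ...) {
  conc <- attr(x, "concentrations")
  cat(sprintf("qHTS profiles: %d curves (%d compounds, %d cell lines), %d concentrations (%.3g-%.3g uM)\n",
              nrow(x), length(unique(x$compound_id)),
              length(unique(x$cell_line)), length(conc),
              min(conc), max(conc)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Extract the response block of a profiles table as a plain matrix.
response_matrix <- function(profiles) {
  as.matrix(profiles[, grep("^c_", names(profiles)), drop = FALSE])
}

#' Read a qHTS concentration-response table
#'
#' Reads a CSV/TSV file with columns `compound_id`, `cell_line` and one
#' response column per assay concentration, named `c_<concentration-in-uM>`
#' (e.g. `c_0.006` ... `c_92`). Response columns may appear in any order; the
#' concentrations are parsed from the headers and sorted ascending. Rows with
#' unparseable (non-numeric) responses are dropped and reported via the
#' `"rejected"` attribute.
#'
#' @param path File path.
#' @param panel Allowed cell-line labels.
#' @param sep Field delimiter; default is inferred from the file extension
#'   (`","` for `.csv`, tab otherwise).
#' @param negate If `TRUE`, responses in the file are signed percent change
#'   in viability relative to vehicle (negative = cell death) and are negated
#'   on read so that positive always means loss of viability.
#' @param encoding File encoding passed to the reader.
#' @return A [qhts_profiles()] object; attribute `"rejected"` holds a data
#'   frame of dropped rows with reasons.
#' @export
read_qhts_table <- function(path, panel = qhts_cell_lines(), sep = NULL,
                            negate = FALSE, encoding = "UTF-8") {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = encoding,
                           colClasses = "character")
  need <- c("compound_id", "cell_line")
  if (!all(need %in% names(raw)))
    stopf("format error: missing required column(s): %s",
          paste(setdiff(need, names(raw)), collapse = ", "))
  rcols <- grep("^c_", names(raw), value = TRUE)
  if (length(rcols) < 2L)
    stopf("format error: no response columns named 'c_<concentration>' found")
  conc <- suppressWarnings(as.numeric(sub("^c_", "", rcols)))
  if (anyNA(conc))
    stopf("format error: unparseable concentration header(s): %s",
          paste(rcols[is.na(conc)], collapse = ", "))
  ord <- order(conc)
  rcols <- rcols[ord]; conc <- conc[ord]

  key <- paste(raw$compound_id, raw$cell_line, sep = "/")
  if (anyDuplicated(key))
    stopf("curation error: duplicate (compound, cell line) rows: %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))

  resp <- suppressWarnings(
    vapply(raw[rcols], as.numeric, numeric(nrow(raw))))
  resp <- matrix(resp, nrow = nrow(raw),
                 dimnames = list(NULL, rcols))
  bad <- apply(resp, 1L, anyNA)
  rejected <- data.frame(compound_id = raw$compound_id[bad],
                         cell_line = raw$cell_line[bad],
                         reason = rep("unparseable response", sum(bad)),
                         stringsAsFactors = FALSE)
  if (any(bad)) {
    raw <- raw[!bad, , drop = FALSE]
    resp <- resp[!bad, , drop = FALSE]
  }
  if (negate) resp <- -resp
  out <- qhts_profiles(raw$compound_id, raw$cell_line, resp,
                       concentrations = conc, panel = panel)
  attr(out, "rejected") <- rejected
  out
}

#' Write a qHTS profile table
#'
#' Inverse of [read_qhts_table()]: writes a delimited text file that reads
#' back to an identical `qhts_profiles` object.
#'
#' @param profiles A [qhts_profiles()] object.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_qhts_table <- function(profiles, path, sep = "\t") {
  df <- as.data.frame(profiles)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
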