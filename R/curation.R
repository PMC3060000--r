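#' Metal elements used to flag organometallic compounds
#'
#' Alkali, alkaline-earth, transition, post-transition metals and
#' metalloids commonly encountered in screening libraries as counter-ions or
#' organometallics. Configurable so the curation policy can be tightened or
#' relaxed.
#'
#' @return Character vector of element symbols.
#' @export
default_metal_elements <- function() {
  c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
    "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
    "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
    "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
    "Al", "Ga", "In", "Sn", "Tl", "Pb", "Bi", "Sb", "As", "Ge",
    "Se", "Te", "Po")
}

# Tokenize a SMILES string into element symbols, or NA if unparseable.
# Bracket atoms ([13CH4], [Na+], [Fe++]) yield the bracket element; outside
# brackets only the organic subset (B C N O P S F Cl Br I and aromatic
# b c n o p s) is legal.
smiles_elements <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(NA_character_)
  s <- smiles
  elems <- character(0)
  i <- 1L; n <- nchar(s)
  depth <- 0L
  two_letter <- c("Cl", "Br")
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) return(NA_character_)  # unbalanced bracket
      inner <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(inner, regexpr("^[0-9]*([A-Z][a-z]?|[a-z])", inner))
      if (!length(m)) return(NA_character_)
      el <- sub("^[0-9]*", "", m)
      if (el %in% c("b", "c", "n", "o", "p", "s", "se", "as"))
        el <- paste0(toupper(substr(el, 1, 1)), substr(el, 2, 10))
      elems <- c(elems, el)
      i <- i + j
    } else if (i < n && substr(s, i, i + 1L) %in% two_letter) {
      elems <- c(elems, substr(s, i, i + 1L))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      elems <- c(elems, ch)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elems <- c(elems, toupper(ch))
      i <- i + 1L
    } else if (grepl("[0-9()=#$:/\\\\.@+%-]", ch)) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) return(NA_character_)
      }
      i <- i + 1L  # ring closures, bonds, branches, charges, dots
    } else {
      return(NA_character_)  # illegal character -> undefined structure
    }
  }
  if (depth != 0L || !length(elems)) return(NA_character_)
  elems
}

#' Curate a compound list for QSAR modeling
#'
#' Applies the standard library-curation rules: exact-duplicate identifiers
#' are collapsed, and, where structures (SMILES) are supplied, entries that
#' are inorganic (no carbon atom), organometallic (contain a metal from
#' `metals`), mixtures (multiple disconnected components), or have an
#' unparseable structure are removed. Every removal carries a
#' machine-readable reason.
#'
#' @param records Data frame with columns `compound_id` and optionally
#'   `structure` (SMILES; `NA` or missing column means no structure check).
#' @param metals Element symbols treated as metals.
#' @return List with `kept` (data frame of retained records) and `removed`
#'   (data frame with `compound_id` and `reason`, one of `duplicate`,
#'   `undefined_structure`, `inorganic`, `organometallic`, `mixture`).
#' @export
curate_compounds <- function(records, metals = default_metal_elements()) {
  if (!"compound_id" %in% names(records))
    stopf("records must have a compound_id column")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  has_struct <- "structure" %in% names(records)
  reason <- rep(NA_character_, nrow(records))

  dup <- duplicated(records$compound_id)
  reason[dup] <- "duplicate"

  if (has_struct) {
    for (i in which(!dup & !is.na(records$structure))) {
      smi <- records$structure[i]
      if (grepl(".", smi, fixed = TRUE)) { reason[i] <- "mixture"; next }
      el <- smiles_elements(smi)
      if (length(el) == 1L && is.na(el)) { reason[i] <- "undefined_structure"; next }
      hit <- intersect(el, metals)
      if (length(hit)) { reason[i] <- "organometallic"; next }
      if (!"C" %in% el) reason[i] <- "inorganic"
    }
  }
  keep <- is.na(reason)
  list(kept = records[keep, , drop = FALSE],
       removed = data.frame(compound_id = records$compound_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Read structures from a SMILES or SDF file
#'
#' SMILES files are one record per line, `id<TAB>smiles` (or
#' `smiles<TAB>id`; the column containing a parseable SMILES is detected).
#' SDF (V2000) files contribute the molecule title line as the identifier;
#' only identifiers and (for SMILES) structure strings are retained.
#'
#' @param path File path ending in `.smi`/`.smiles`/`.txt` or `.sdf`.
#' @return Data frame with columns `compound_id` and `structure`
#'   (`NA` structure for SDF input).
#' @export
read_structures <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    starts <- c(1L, which(lines == "$$$$") + 1L)
    starts <- starts[starts <= length(lines)]
    ids <- trimws(lines[starts])
    ids <- ids[nzchar(ids) & ids != "$$$$"]
    return(data.frame(compound_id = ids, structure = NA_character_,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L))
    stopf("SMILES file must be two tab-separated columns (id, smiles)")
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  # column whose entries parse as SMILES is the structure column
  ok_b <- mean(!vapply(b, function(x) all(is.na(smiles_elements(x))), TRUE))
  ok_a <- mean(!vapply(a, function(x) all(is.na(smiles_elements(x))), TRUE))
  if (ok_b >= ok_a)
    data.frame(compound_id = a, structure = b, stringsAsFactors = FALSE)
  else
    data.frame(compound_id = b, structure = a, stringsAsFactors = FALSE)
}
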