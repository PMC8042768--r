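# Nucleotide alphabet: fixed order A, C, G, T (indices 1..4 in R, 0..3 in the
# compiled core).  Gaps and IUPAC ambiguity codes are "missing" (NA) at the
# alignment level; they are never a fifth state.

NUC_STATES <- c("A", "C", "G", "T")

#' Encode nucleotide characters as state indices
#'
#' Maps characters to indices 1-4 in the fixed order A, C, G, T.  Lower case
#' is accepted, U is read as T, and everything else (gaps, N, IUPAC ambiguity
#' codes) becomes `NA` (missing).
#'
#' @param x Character vector of single-letter nucleotide codes.
#' @return Integer vector with values in 1..4 or `NA`.
#' @export
encode_bases <- function(x) {
  x <- toupper(as.character(x))
  x[x == "U"] <- "T"
  match(x, NUC_STATES)
}

#' Decode state indices back to nucleotide characters
#'
#' @param idx Integer vector with values 1..4 or `NA`.
#' @param missing_char Character used for missing states (default `"N"`).
#' @return Character vector of bases.
#' @export
decode_bases <- function(idx, missing_char = "N") {
  out <- NUC_STATES[idx]
  out[is.na(out)] <- missing_char
  out
}

# internal: coerce a base given as "A".."T" or 1..4 to an index, with checks
.base_index <- function(base) {
  if (is.character(base)) {
    i <- encode_bases(base)
  } else {
    i <- as.integer(base)
  }
  if (any(is.na(i)) || any(i < 1L) || any(i > 4L))
    stop("base must be one of A, C, G, T (or an index 1..4)")
  i
}
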