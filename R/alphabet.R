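# Amino-acid alphabet handling.
#
# The 20 standard residues plus a 21st "unknown" symbol X. Ambiguity codes
# are collapsed onto their most common parent residue; stops and gaps are
# stripped. X matches no motif position and is excluded from CKSAAP pair
# counts.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_UNKNOWN <- "X"
AA21 <- c(AA20, AA_UNKNOWN)

#' Sanitize amino-acid sequences
#'
#' Upper-cases, strips stops (`*`) and gap characters (`-`, `.`), maps the
#' ambiguity codes B->D, Z->E, J->L, U->C, O->K, and keeps `X` as an
#' explicit unknown residue. Any other character is an error.
#'
#' @param x Character vector of raw sequences.
#' @return Character vector of sanitized sequences over the 21-letter
#'   alphabet (20 standard residues plus `X`).
#' @export
#' @examples
#' sanitize_sequence("mks*kip-a")
sanitize_sequence <- function(x) {
  stopifnot(is.character(x))
  out <- toupper(x)
  out <- gsub("[*. \t-]", "", out)
  out <- chartr("BZJUO", "DELCK", out)
  bad <- grepl(paste0("[^", paste(AA21, collapse = ""), "]"), out)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub(paste0("[", paste(AA21, collapse = ""), "]"), "", out[bad]), "")))
    abort(sprintf("invalid sequence character(s): %s", paste(ch, collapse = ", ")))
  }
  out
}
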