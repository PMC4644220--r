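# Feature encodings: CKSAAP (composition of k-spaced amino-acid pairs) and
# binary degenerate-motif presence.
#
# A motif is written as a string over the 20 residues plus the wildcard
# "x": e.g. "SxIP" matches Ser, anything, Ile, Pro. First and last motif
# positions must be fixed residues; the unknown residue X matches no motif
# position.

#' Validate a degenerate motif pattern
#'
#' @param motif Motif string, e.g. `"SxIP"`; lowercase `x` marks a wildcard
#'   position.
#' @return The motif, invisibly; errors when invalid.
#' @export
validate_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1)
  if (nchar(motif) < 2) abort(sprintf("motif '%s' is shorter than 2 positions", motif))
  ch <- strsplit(motif, "")[[1]]
  if (!all(ch %in% c(AA20, "x"))) {
    abort(sprintf("motif '%s' contains characters outside the 20 residues and 'x'", motif))
  }
  if (ch[1] == "x" || ch[length(ch)] == "x") {
    abort(sprintf("motif '%s' must start and end with a fixed residue", motif))
  }
  if (all(ch == "x")) abort("motif must have at least one fixed position")
  invisible(motif)
}

#' Find all matches of a degenerate motif in a sequence
#'
#' Scans every window of the sequence; a window matches when each fixed
#' motif position equals the corresponding residue. Overlapping matches are
#' all reported. The unknown residue `X` never matches a fixed position.
#'
#' @param seq Amino-acid sequence (character scalar).
#' @param motif Motif string (see [validate_motif()]).
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
#' @examples
#' match_motif("MKSKIPAA", "SxIP")
match_motif <- function(seq, motif) {
  validate_motif(motif)
  stopifnot(is.character(seq), length(seq) == 1)
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  L <- length(m)
  n <- length(s)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1)
  for (j in which(m != "x")) {
    ok <- ok & (s[seq_len(n - L + 1) + j - 1] == m[j])
  }
  which(ok)
}

cksaap_pair_names <- function(k_max) {
  pairs <- as.vector(t(outer(AA20, AA20, paste0)))
  unlist(lapply(0:k_max, function(k) paste0("k", k, ":", pairs)))
}

#' CKSAAP encoding of one sequence
#'
#' For each spacing k in `0..k_max` and each ordered residue pair (a, b),
#' counts positions i with `seq[i] == a` and `seq[i + k + 1] == b`, and
#' divides by the number of k-spaced windows. Pairs touching the unknown
#' residue `X` are excluded from both the count and the denominator, so
#' each k-block of 400 features sums to 1 whenever at least one valid pair
#' exists.
#'
#' @param seq Amino-acid sequence of length at least `k_max + 2`.
#' @param k_max Largest spacing considered (default 1, i.e. pairs with 0 or
#'   1 residue in between).
#' @return Named numeric vector of length `400 * (k_max + 1)`; names are
#'   `"k0:AA"`, `"k0:AC"`, ... with k ascending and pairs alphabetical.
#' @export
#' @examples
#' encode_cksaap("ACAC", k_max = 1)[c("k0:AC", "k0:CA", "k1:AA", "k1:CC")]
encode_cksaap <- function(seq, k_max = 1) {
  stopifnot(is.character(seq), length(seq) == 1, k_max >= 0)
  n <- nchar(seq)
  if (n < k_max + 2) {
    abort(sprintf("sequence of length %d is too short for CKSAAP with k_max = %d", n, k_max))
  }
  codes <- match(strsplit(seq, "")[[1]], AA20)  # NA for unknown residue
  out <- numeric(400 * (k_max + 1))
  for (k in 0:k_max) {
    a <- codes[seq_len(n - k - 1)]
    b <- codes[seq_len(n - k - 1) + k + 1]
    valid <- !is.na(a) & !is.na(b)
    counts <- tabulate((a[valid] - 1) * 20 + b[valid], nbins = 400)
    denom <- sum(valid)
    if (denom > 0) out[k * 400 + seq_len(400)] <- counts / denom
  }
  names(out) <- cksaap_pair_names(k_max)
  out
}

#' Binary motif-presence encoding of one sequence
#'
#' @param seq Amino-acid sequence.
#' @param motifs Character vector of motif strings.
#' @return Named binary vector: 1 when [match_motif()] finds at least one
#'   occurrence, else 0. Presence, not count.
#' @export
encode_motifs <- function(seq, motifs) {
  stopifnot(length(motifs) >= 1)
  setNames(vapply(motifs, function(m) as.numeric(length(match_motif(seq, m)) > 0),
                  numeric(1)), motifs)
}

# Fast presence matrix for many (sequence, motif) pairs. Motifs are grouped
# by (length, wildcard-position set); for each group every sequence window
# is masked to that wildcard pattern and looked up in the group's motif
# set. Equivalent to match_motif() per pair but linear in total windows.
motif_presence_matrix <- function(sequences, motifs) {
  vapply(motifs, validate_motif, character(1))
  n <- length(sequences)
  out <- matrix(0, nrow = n, ncol = length(motifs), dimnames = list(NULL, motifs))
  key <- vapply(motifs, function(m) gsub("[^x]", ".", m), character(1))
  groups <- split(seq_along(motifs), key)
  for (g in groups) {
    patt <- motifs[g]
    L <- nchar(patt[1])
    wc <- which(strsplit(patt[1], "")[[1]] == "x")
    for (i in seq_len(n)) {
      ni <- nchar(sequences[i])
      if (ni < L) next
      w <- substring(sequences[i], seq_len(ni - L + 1), L:ni)
      for (p in wc) substr(w, p, p) <- "x"
      out[i, g] <- as.numeric(patt %in% w)
    }
  }
  out
}

#' Encode a whole dataset as a feature tibble
#'
#' @param ds Dataset tibble (columns `id`, `sequence`, `label`).
#' @param encoder `"cksaap"` or `"motifs"`.
#' @param k_max CKSAAP spacing limit (used when `encoder = "cksaap"`).
#' @param motifs Character vector of motifs (used when `encoder = "motifs"`).
#' @return Tibble with `id`, `label`, then one numeric column per feature;
#'   row order equals dataset order.
#' @export
encode_dataset <- function(ds, encoder = c("cksaap", "motifs"), k_max = 1, motifs = NULL) {
  validate_dataset(ds)
  encoder <- arg_match(encoder)
  if (encoder == "cksaap") {
    too_short <- nchar(ds$sequence) < k_max + 2
    if (any(too_short)) {
      abort(sprintf("sequence(s) too short for CKSAAP (k_max = %d): %s", k_max,
                    paste(head(ds$id[too_short], 5), collapse = ", ")))
    }
    mat <- t(vapply(ds$sequence, encode_cksaap, numeric(400 * (k_max + 1)),
                    k_max = k_max, USE.NAMES = FALSE))
    colnames(mat) <- cksaap_pair_names(k_max)
  } else {
    if (is.null(motifs) || length(motifs) == 0) abort("`motifs` must be a non-empty character vector")
    mat <- motif_presence_matrix(ds$sequence, motifs)
  }
  bind_cols_features(ds, mat)
}

bind_cols_features <- function(ds, mat) {
  out <- tibble(id = ds$id, label = ds$label)
  dplyr::bind_cols(out, as_tibble(mat, .name_repair = "minimal"))
}

# split a feature tibble into matrix + metadata
feature_matrix <- function(x) {
  meta <- intersect(c("id", "label"), names(x))
  m <- as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
  storage.mode(m) <- "double"
  attr(m, "id") <- if ("id" %in% meta) x$id else NULL
  attr(m, "label") <- if ("label" %in% meta) x$label else NULL
  m
}
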