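# Dataset assembly: FASTA I/O, validation, redundancy filtering, and
# class-ratio sampling. A dataset is a plain tibble with columns
# id / sequence / label (and optionally desc and other metadata), so it
# composes with dplyr verbs.

MAP_LABELS <- c("positive", "negative", "unlabeled", "unknown")

validate_dataset <- function(ds, arg = "ds") {
  if (!is.data.frame(ds)) abort(sprintf("`%s` must be a data frame", arg))
  need <- c("id", "sequence", "label")
  miss <- setdiff(need, names(ds))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(ds$id)) {
    dup <- unique(ds$id[duplicated(ds$id)])
    abort(sprintf("duplicate record id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(ds$label %in% MAP_LABELS)) {
    abort(sprintf("labels must be one of: %s", paste(MAP_LABELS, collapse = ", ")))
  }
  invisible(as_tibble(ds))
}

#' Read a FASTA file into a dataset tibble
#'
#' Each FASTA entry becomes one record. The identifier is the header token
#' before the first whitespace; the remainder of the header line is kept in
#' a `desc` column. Sequences are sanitized with [sanitize_sequence()];
#' records whose sequence is empty after sanitization are a parse error.
#'
#' @param path Path to a FASTA file.
#' @param label Class label assigned to every record: one of `"positive"`,
#'   `"negative"`, `"unlabeled"`, `"unknown"`.
#' @return A tibble with columns `id`, `desc`, `sequence`, `label`, in file
#'   order.
#' @export
read_fasta <- function(path, label = "unknown") {
  label <- arg_match(label, MAP_LABELS)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- sanitize_sequence(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    abort(sprintf("record %d ('%s') has an empty sequence after sanitization",
                  empty[1], ids[empty[1]]))
  }
  ds <- tibble(id = unname(ids), desc = unname(desc),
               sequence = unname(seqs), label = label)
  validate_dataset(ds)
  ds
}

#' Write a dataset tibble to FASTA
#'
#' @param ds Dataset tibble with `id` and `sequence` columns (an optional
#'   `desc` column is appended to the header).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  stopifnot(is.data.frame(ds), all(c("id", "sequence") %in% names(ds)))
  set <- Biostrings::AAStringSet(ds$sequence)
  hdr <- ds$id
  if ("desc" %in% names(ds)) {
    hdr <- ifelse(nchar(ds$desc) > 0, paste(ds$id, ds$desc), ds$id)
  }
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column id/label table
#'
#' @param path Tab-separated file with columns `id` and `label` (no header
#'   required; if the first line parses as `id<TAB>label` it is treated as a
#'   header).
#' @return Tibble with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("id", "label"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(tab) > 0 && identical(tolower(unlist(tab[1, ])), c(id = "id", label = "label"))) {
    tab <- tab[-1, ]
  }
  tab$label <- tolower(tab$label)
  if (!all(tab$label %in% MAP_LABELS)) {
    abort(sprintf("labels must be one of: %s", paste(MAP_LABELS, collapse = ", ")))
  }
  tab
}

#' Attach labels from a label table to a dataset
#'
#' @param ds Dataset tibble.
#' @param labels Tibble from [read_labels()] (columns `id`, `label`).
#' @return `ds` with its `label` column replaced for ids present in
#'   `labels`; ids absent from `labels` keep their current label.
#' @export
apply_labels <- function(ds, labels) {
  validate_dataset(ds)
  idx <- match(ds$id, labels$id)
  ds$label <- ifelse(is.na(idx), ds$label, labels$label[idx])
  ds
}

#' Count records per class label
#'
#' @param ds Dataset tibble.
#' @return Tibble with columns `label`, `n` (zero rows for absent labels are
#'   omitted).
#' @export
dataset_counts <- function(ds) {
  validate_dataset(ds)
  count(ds, label)
}

# identity-scoring substitution matrix over the 21-letter alphabet
identity_submat <- local({
  m <- diag(1, length(AA21))
  dimnames(m) <- list(AA21, AA21)
  m
})

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and a
#' linear gap penalty of -1; identity is the number of identical aligned
#' positions divided by the alignment length (gap columns included).
#' Symmetric in its arguments.
#'
#' @param a,b Non-empty amino-acid sequences (character scalars).
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACDEF", "ACDEF")
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = identity_submat,
    gapOpening = 0, gapExtension = 1, type = "global"
  )
  # alignment columns = n + m - aligned (diagonal) steps; end gaps included
  diag_steps <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  Biostrings::nmatch(aln) / (nchar(a) + nchar(b) - diag_steps)
}

#' Remove redundant sequences at class-aware identity cutoffs
#'
#' Greedy clustering: records are visited positives first, then by
#' decreasing sequence length (ties by id), and a record is kept only if its
#' identity to every already-kept record does not exceed the applicable
#' cutoff — `intraclass_cutoff` against kept records of the same class,
#' `interclass_cutoff` against kept records of a different class. Because
#' positives are visited first they are never removed by a cross-class
#' conflict; the negative or unlabeled member is dropped instead.
#'
#' @param ds Dataset tibble.
#' @param intraclass_cutoff,interclass_cutoff Identity fractions in
#'   `(0, 1]`; a pair exceeding (strictly) the cutoff is a conflict.
#' @return The filtered dataset, in the original record order.
#' @export
filter_redundancy <- function(ds, intraclass_cutoff = 0.25, interclass_cutoff = 0.80) {
  validate_dataset(ds)
  stopifnot(intraclass_cutoff > 0, intraclass_cutoff <= 1,
            interclass_cutoff > 0, interclass_cutoff <= 1)
  if (nrow(ds) <= 1) return(ds)
  ord <- order(ds$label != "positive", -nchar(ds$sequence), ds$id, method = "radix")
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      cutoff <- if (ds$label[i] == ds$label[j]) intraclass_cutoff else interclass_cutoff
      if (pairwise_identity(ds$sequence[i], ds$sequence[j]) > cutoff) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  ds[sort(kept), ]
}

#' Assemble a dataset at a fixed positive-to-negative ratio
#'
#' Takes every positive record and samples `ratio` negatives per positive
#' from the pool, without replacement, deterministically for a given seed.
#' Records shorter than 3 residues are dropped first (the CKSAAP encoding
#' with one allowed space is undefined for them).
#'
#' @param pos Dataset tibble of positive records.
#' @param neg_pool Dataset tibble of candidate negative records.
#' @param ratio Integer negatives-per-positive (e.g. 10 for training, 50
#'   for testing).
#' @param seed Integer seed controlling the negative sample.
#' @return Dataset tibble: all positives followed by the sampled negatives.
#' @export
assemble_at_ratio <- function(pos, neg_pool, ratio, seed = 1) {
  validate_dataset(pos, "pos")
  validate_dataset(neg_pool, "neg_pool")
  stopifnot(is.numeric(ratio), ratio >= 1)
  short_p <- nchar(pos$sequence) < 3
  short_n <- nchar(neg_pool$sequence) < 3
  if (any(short_p) || any(short_n)) {
    warn(sprintf("dropping %d record(s) shorter than 3 residues",
                 sum(short_p) + sum(short_n)))
    pos <- pos[!short_p, ]
    neg_pool <- neg_pool[!short_n, ]
  }
  pos <- mutate(pos, label = "positive")
  neg_pool <- mutate(neg_pool, label = "negative")
  need <- as.integer(ratio) * nrow(pos)
  if (nrow(neg_pool) < need) {
    abort(sprintf("insufficient negatives: need %d, have %d", need, nrow(neg_pool)))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  take <- sort(sample.int(nrow(neg_pool), need))
  bind_rows(pos, neg_pool[take, ])
}
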