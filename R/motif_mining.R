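# Discriminative degenerate-motif discovery and mRMR feature selection.
#
# Discovery exhaustively enumerates every degenerate pattern (fixed first
# and last residues, up to max_wildcards internal wildcards) that occurs in
# the positive set, counts per-class support, and keeps patterns that are
# frequent in positives and rare in negatives. Enumeration is data-driven:
# any pattern occurring in a sequence arises from one of its windows under
# one wildcard mask, so masked windows enumerate the full candidate space.

# wildcard masks (subsets of internal positions) for a pattern length
wildcard_masks <- function(L, max_wildcards) {
  internal <- if (L > 2) 2:(L - 1) else integer(0)
  masks <- list(integer(0))
  if (length(internal) > 0 && max_wildcards > 0) {
    for (w in seq_len(min(max_wildcards, length(internal)))) {
      # index-based combn: a length-1 `internal` must not be read as 1:n
      cmb <- utils::combn(seq_along(internal), w, simplify = FALSE)
      masks <- c(masks, lapply(cmb, function(ix) internal[ix]))
    }
  }
  masks
}

# data.table of unique (pattern, seq_id) occurrences across sequences
pattern_occurrences <- function(sequences, lengths, max_wildcards) {
  pats <- list()
  ids <- list()
  for (L in lengths) {
    masks <- wildcard_masks(L, max_wildcards)
    for (i in seq_along(sequences)) {
      n <- nchar(sequences[i])
      if (n < L) next
      w <- substring(sequences[i], seq_len(n - L + 1), L:n)
      w <- unique(w[!grepl("X", w, fixed = TRUE)])
      if (length(w) == 0) next
      all_p <- unlist(lapply(masks, function(m) {
        p <- w
        for (pos in m) substr(p, pos, pos) <- "x"
        p
      }), use.names = FALSE)
      all_p <- unique(all_p)
      pats[[length(pats) + 1]] <- all_p
      ids[[length(ids) + 1]] <- rep.int(i, length(all_p))
    }
  }
  if (length(pats) == 0) {
    return(data.table::data.table(pattern = character(0), seq_id = integer(0)))
  }
  data.table::data.table(pattern = unlist(pats, use.names = FALSE),
                         seq_id = unlist(ids, use.names = FALSE))
}

#' Discover discriminative degenerate motifs
#'
#' Enumerates all degenerate patterns with lengths in `length_range`, fixed
#' first/last residues and at most `max_wildcards` internal wildcard
#' positions that occur in at least `min_pos_support` of the positive
#' sequences, drops those matched by more than `max_neg_support` of the
#' negatives, and scores each survivor by the support difference
#' `pos_support - neg_support`. Output is deterministic and invariant to
#' record order: sorted by score descending, ties by pattern.
#'
#' @param pos,neg Dataset tibbles of positive and negative records.
#' @param length_range Two integers in `[2, 8]`: smallest and largest
#'   pattern length.
#' @param max_wildcards Maximum internal wildcard positions per pattern.
#' @param min_pos_support Minimum fraction of positives matched.
#' @param max_neg_support Maximum fraction of negatives matched.
#' @param top_n Cap on the number of returned candidates (best first).
#' @return Tibble with columns `motif`, `pos_hits`, `neg_hits`,
#'   `pos_support`, `neg_support`, `score`; possibly zero rows.
#' @export
discover_motifs <- function(pos, neg, length_range = c(2, 6), max_wildcards = 2,
                            min_pos_support = 0.05, max_neg_support = 0.02,
                            top_n = 5000) {
  validate_dataset(pos, "pos")
  validate_dataset(neg, "neg")
  stopifnot(length(length_range) == 2, length_range[1] >= 2, length_range[2] <= 8,
            length_range[1] <= length_range[2], max_wildcards >= 0)
  if (nrow(pos) == 0 || nrow(neg) == 0) abort("datasets must be non-empty")
  lengths <- length_range[1]:length_range[2]
  n_pos <- nrow(pos)
  n_neg <- nrow(neg)

  occ_pos <- pattern_occurrences(pos$sequence, lengths, max_wildcards)
  if (nrow(occ_pos) == 0) return(empty_candidates())
  pos_tab <- occ_pos[, list(pos_hits = .N), by = pattern]
  pos_tab <- pos_tab[pos_tab$pos_hits / n_pos >= min_pos_support]
  if (nrow(pos_tab) == 0) return(empty_candidates())

  occ_neg <- pattern_occurrences(neg$sequence, lengths, max_wildcards)
  neg_tab <- occ_neg[, list(neg_hits = .N), by = pattern]
  cand <- merge(pos_tab, neg_tab, by = "pattern", all.x = TRUE)
  cand$neg_hits[is.na(cand$neg_hits)] <- 0L
  cand <- cand[cand$neg_hits / n_neg <= max_neg_support]
  if (nrow(cand) == 0) return(empty_candidates())

  out <- as_tibble(cand)
  out <- mutate(out,
                pos_support = pos_hits / n_pos,
                neg_support = neg_hits / n_neg,
                score = pos_support - neg_support)
  out <- rename(out, motif = pattern)
  out <- out[order(-out$score, out$motif, method = "radix"), ]
  head(out, top_n)
}

empty_candidates <- function() {
  tibble(motif = character(0), pos_hits = integer(0), neg_hits = integer(0),
         pos_support = numeric(0), neg_support = numeric(0), score = numeric(0))
}

#' Mutual information between two binary vectors
#'
#' Plug-in estimate over the 2x2 joint distribution, in bits, with the
#' convention `0 * log(0) = 0`. Zero when the vectors are independent by
#' counts.
#'
#' @param feature,labels Binary (0/1 or logical) vectors of equal length.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information_binary <- function(feature, labels) {
  f <- as.numeric(feature)
  y <- as.numeric(labels)
  if (length(f) != length(y)) {
    abort(sprintf("length mismatch: feature has %d, labels has %d", length(f), length(y)))
  }
  if (length(f) == 0) abort("vectors must have length >= 1")
  stopifnot(all(f %in% c(0, 1)), all(y %in% c(0, 1)))
  n <- length(f)
  n11 <- sum(f * y)
  n10 <- sum(f) - n11
  n01 <- sum(y) - n11
  n00 <- n - n11 - n10 - n01
  joint <- c(n00, n01, n10, n11) / n
  pf <- c(n00 + n01, n10 + n11) / n
  py <- c(n00 + n10, n01 + n11) / n
  prod_marg <- c(pf[1] * py[1], pf[1] * py[2], pf[2] * py[1], pf[2] * py[2])
  terms <- ifelse(joint > 0, joint * log2(joint / prod_marg), 0)
  max(sum(terms), 0)
}

# MI of every column of binary matrix X against binary vector s, vectorized
mi_columns <- function(X, s) {
  n <- length(s)
  c1 <- colSums(X)
  s1 <- sum(s)
  n11 <- as.vector(crossprod(X, s))
  n10 <- c1 - n11
  n01 <- s1 - n11
  n00 <- n - c1 - s1 + n11
  mi_from_counts <- function(nn, pf, py) {
    p <- nn / n
    ifelse(p > 0, p * log2(p / (pf * py)), 0)
  }
  pf1 <- c1 / n; pf0 <- 1 - pf1
  py1 <- s1 / n; py0 <- 1 - py1
  mi <- mi_from_counts(n00, pf0, py0) + mi_from_counts(n01, pf0, py1) +
    mi_from_counts(n10, pf1, py0) + mi_from_counts(n11, pf1, py1)
  pmax(mi, 0)
}

#' Greedy mRMR feature selection (MID criterion)
#'
#' The first feature maximizes mutual information with the label; each
#' subsequent feature maximizes relevance minus mean redundancy,
#' `MI(f; label) - mean over selected s of MI(f; s)`. Ties are broken by
#' column order, so the result is deterministic.
#'
#' @param X Binary feature tibble (from [encode_dataset()]) or matrix.
#' @param labels Binary vector (1 = positive) or character labels; when `X`
#'   is a feature tibble with a `label` column, may be omitted.
#' @param m Number of features to select.
#' @return An object of class `mrmr_selection`: a tibble with columns
#'   `rank`, `feature`, `relevance` (MI with the label, bits) and `score`
#'   (the MID objective at selection time).
#' @export
mrmr_select <- function(X, labels = NULL, m) {
  if (is.data.frame(X)) {
    if (is.null(labels) && "label" %in% names(X)) labels <- X$label
    X <- feature_matrix(X)
  }
  stopifnot(m >= 1)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.numeric(as.character(labels) == "positive")
  }
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), all(X %in% c(0, 1)))
  p <- ncol(X)
  if (m > p) {
    warn(sprintf("m = %d exceeds the %d available features; selecting all", m, p))
    m <- p
  }
  relevance <- mi_columns(X, y)
  selected <- integer(m)
  sel_score <- numeric(m)
  red_sum <- numeric(p)
  active <- rep(TRUE, p)
  for (step in seq_len(m)) {
    score <- if (step == 1) relevance else relevance - red_sum / (step - 1)
    score[!active] <- -Inf
    pick <- which.max(score)
    selected[step] <- pick
    sel_score[step] <- score[pick]
    active[pick] <- FALSE
    if (step < m) red_sum <- red_sum + mi_columns(X, X[, pick])
  }
  out <- tibble(rank = seq_len(m),
                feature = colnames(X)[selected],
                relevance = relevance[selected],
                score = sel_score)
  class(out) <- c("mrmr_selection", class(out))
  out
}
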