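# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package code paths it checks.

# random amino-acid sequence (uniform over the 20 standard residues)
rand_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

make_dataset <- function(sequences, label = "unknown", prefix = "S") {
  tibble::tibble(id = sprintf("%s%03d", prefix, seq_along(sequences)),
                 sequence = sequences, label = label)
}

# brute-force global alignment oracle: exhaustively enumerates EVERY global
# alignment of two short sequences (match 1, mismatch 0, linear gap -1),
# returning the optimal score and the set of identity fractions
# (matches / alignment columns) realized by optimal-score alignments.
# Identity can differ between co-optimal alignments, so agreement means
# membership in this set.
nw_enumerate_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  results <- list()
  recurse <- function(i, j, score, matches, cols) {
    if (i > length(x) && j > length(y)) {
      results[[length(results) + 1]] <<- c(score, matches, cols)
      return(invisible())
    }
    if (i <= length(x) && j <= length(y)) {
      recurse(i + 1, j + 1, score + (x[i] == y[j]), matches + (x[i] == y[j]), cols + 1)
    }
    if (i <= length(x)) recurse(i + 1, j, score - 1, matches, cols + 1)
    if (j <= length(y)) recurse(i, j + 1, score - 1, matches, cols + 1)
  }
  recurse(1, 1, 0, 0, 0)
  res <- do.call(rbind, results)
  best <- max(res[, 1])
  list(score = best,
       identities = unique(res[res[, 1] == best, 2] / res[res[, 1] == best, 3]))
}

# regex oracle for degenerate motif matching (overlaps via lookahead)
match_motif_regex_oracle <- function(seq, motif) {
  rx <- paste0("(?=", gsub("x", ".", motif, fixed = TRUE), ")")
  hits <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

# joint-histogram mutual information oracle (bits)
mi_oracle <- function(f, y) {
  tab <- table(factor(f, levels = 0:1), factor(y, levels = 0:1)) / length(f)
  pf <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (pf[i] * py[j]))
  }
  as.numeric(s)
}

# pairwise-comparison AUC oracle: P(random positive outscores random
# negative), ties counted one half
auc_oracle <- function(scores, labels) {
  y <- if (is.character(labels)) labels == "positive" else labels > 0
  ps <- scores[y]; ns <- scores[!y]
  wins <- 0
  for (p in ps) for (q in ns) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(ps) * length(ns))
}

# greedy mRMR (MID) oracle using mi_oracle directly
mrmr_oracle <- function(X, y, m) {
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) mi_oracle(X[, j], y), numeric(1))
  sel <- integer(0)
  for (step in seq_len(m)) {
    score <- vapply(seq_len(p), function(j) {
      if (j %in% sel) return(-Inf)
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(s) mi_oracle(X[, j], X[, s]), numeric(1)))
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, which.max(score))
  }
  colnames(X)[sel]
}

# exact probability that a wildcard-free 2-residue motif "ab" occurs in an
# i.i.d. uniform sequence of length n, by transfer-matrix recursion over
# prefix states (0: no progress, 1: last residue was 'a')
dimer_occurrence_prob <- function(n, a_eq_b = FALSE) {
  # state probabilities for "no match yet"
  p <- 1 / 20
  s0 <- 1; s1 <- 0
  for (i in seq_len(n)) {
    if (a_eq_b) {
      # pattern "aa": from s1, emitting 'a' is a match
      new_s1 <- s0 * p
      new_s0 <- (s0 + s1) * (1 - p) # any non-'a' resets both states
    } else {
      # pattern "ab", a != b: from s1, 'b' matches, 'a' stays in s1
      new_s1 <- (s0 + s1) * p
      new_s0 <- s0 * (1 - p) + s1 * (1 - 2 * p)
    }
    s0 <- new_s0; s1 <- new_s1
  }
  1 - (s0 + s1)
}
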