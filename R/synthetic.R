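# Synthetic data with the statistical structure the predictor assumes:
# positives carry planted degenerate motifs and a mild enrichment of
# positively charged residues (K/R); negatives are i.i.d. background;
# unlabeled sequences sit in between (half the charge boost, half the
# plant rate). Everything is a deterministic function of the seed.

#' Synthetic dataset configuration
#'
#' @param n_pos Number of positive sequences.
#' @param neg_ratio Negatives per positive (10 emulates the training
#'   ratio, 50 the curated-test ratio).
#' @param n_unlabeled Number of unlabeled sequences.
#' @param seq_len_range Two integers: uniform range of sequence lengths.
#' @param planted_motifs Character vector of degenerate motifs planted in
#'   positives.
#' @param plant_rate Probability, per motif per positive, that the motif is
#'   planted.
#' @param pos_charge_boost Multiplier (>= 1) on the K and R background
#'   frequencies in positives, renormalized.
#' @param background `"uniform"` (1/20 each; default, makes analytic match
#'   rates exact) or `"natural"` (SwissProt-like frequencies).
#' @param seed Integer seed; the generated dataset is a pure function of
#'   the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pos = 250, neg_ratio = 10, n_unlabeled = 50,
                         seq_len_range = c(80, 200),
                         planted_motifs = c("SxIP", "KRxKP"),
                         plant_rate = 0.8, pos_charge_boost = 1.5,
                         background = c("uniform", "natural"), seed = 1) {
  background <- arg_match(background)
  stopifnot(n_pos >= 0, neg_ratio >= 0, n_unlabeled >= 0,
            length(seq_len_range) == 2, seq_len_range[1] <= seq_len_range[2],
            plant_rate >= 0, plant_rate <= 1, pos_charge_boost >= 1)
  for (m in planted_motifs) validate_motif(m)
  if (length(planted_motifs) > 0 && max(nchar(planted_motifs)) > seq_len_range[1]) {
    abort("planted motif longer than the minimum sequence length")
  }
  structure(list(n_pos = as.integer(n_pos), neg_ratio = as.integer(neg_ratio),
                 n_unlabeled = as.integer(n_unlabeled),
                 seq_len_range = as.integer(seq_len_range),
                 planted_motifs = planted_motifs, plant_rate = plant_rate,
                 pos_charge_boost = pos_charge_boost, background = background,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# SwissProt-like residue frequencies, order AA20
natural_freqs <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0663, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)

background_freqs <- function(background, charge_boost = 1) {
  p <- if (background == "uniform") setNames(rep(1 / 20, 20), AA20) else natural_freqs / sum(natural_freqs)
  p[c("K", "R")] <- p[c("K", "R")] * charge_boost
  p / sum(p)
}

random_seqs <- function(n, len_range, freqs) {
  if (n == 0) return(character(0))
  lens <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1, n,
                                    replace = TRUE) - 1L
  vapply(lens, function(len) {
    paste(sample(AA20, len, replace = TRUE, prob = freqs), collapse = "")
  }, character(1))
}

plant_motifs_in <- function(seqs, motifs, rate, freqs) {
  planted <- rep(FALSE, length(seqs))
  if (length(motifs) == 0 || rate == 0) return(list(seqs = seqs, planted = planted))
  for (i in seq_along(seqs)) {
    for (m in motifs) {
      if (runif(1) >= rate) next
      ch <- strsplit(m, "")[[1]]
      ch[ch == "x"] <- sample(AA20, sum(ch == "x"), replace = TRUE, prob = freqs)
      inst <- paste(ch, collapse = "")
      L <- nchar(inst)
      start <- sample.int(nchar(seqs[i]) - L + 1, 1)
      substr(seqs[i], start, start + L - 1) <- inst
      planted[i] <- TRUE
    }
  }
  list(seqs = seqs, planted = planted)
}

#' Generate a labeled synthetic dataset
#'
#' Negatives are i.i.d. residues from the background frequencies.
#' Positives use the background with K/R frequencies multiplied by
#' `pos_charge_boost` (renormalized), then each planted motif is written
#' over a uniformly random window with probability `plant_rate` (wildcard
#' positions instantiated at random). Unlabeled sequences get half the
#' charge boost and half the plant rate.
#'
#' @param cfg A [synth_config()].
#' @return Dataset tibble with columns `id`, `sequence`, `label` and
#'   `planted` (whether any motif was actually planted in the record).
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  n_neg <- cfg$n_pos * cfg$neg_ratio

  p_pos <- background_freqs(cfg$background, cfg$pos_charge_boost)
  p_neg <- background_freqs(cfg$background, 1)
  p_unl <- background_freqs(cfg$background, 1 + (cfg$pos_charge_boost - 1) / 2)

  pos <- plant_motifs_in(random_seqs(cfg$n_pos, cfg$seq_len_range, p_pos),
                         cfg$planted_motifs, cfg$plant_rate, p_pos)
  neg <- random_seqs(n_neg, cfg$seq_len_range, p_neg)
  unl <- plant_motifs_in(random_seqs(cfg$n_unlabeled, cfg$seq_len_range, p_unl),
                         cfg$planted_motifs, cfg$plant_rate / 2, p_unl)

  fmt <- function(prefix, n) sprintf("%s_%0*d", prefix, max(4, nchar(n)), seq_len(n))
  ds <- bind_rows(
    tibble(id = fmt("POS", cfg$n_pos), sequence = pos$seqs,
           label = "positive", planted = pos$planted),
    tibble(id = fmt("NEG", n_neg), sequence = neg,
           label = "negative", planted = FALSE),
    tibble(id = fmt("UNL", cfg$n_unlabeled), sequence = unl$seqs,
           label = "unlabeled", planted = unl$planted)
  )
  validate_dataset(ds)
  ds
}

#' Generate a synthetic precomputed homology hit table
#'
#' Emulates a BLAST search of `ds` against `db`: records that actually
#' carry a planted motif get a best hit against a planted `db` member
#' (E-value log-uniform between 1e-50 and 1e-5); records without planted
#' signal get no row, so their transformed score falls to the no-hit value
#' of -3. Members of `db` queried against themselves additionally get a
#' near-zero self-hit row (E = 1e-180), which best-hit extraction ignores.
#'
#' @param ds Query dataset tibble (needs the generator's `planted`
#'   column; records lacking it are treated as unplanted).
#' @param db Database dataset tibble (the positive training set).
#' @param seed Integer seed.
#' @return Tibble with columns `query`, `subject`, `evalue`, consumable by
#'   [homology_backend_tsv()].
#' @export
synth_homology_tsv <- function(ds, db, seed = 1) {
  validate_dataset(ds, "ds")
  validate_dataset(db, "db")
  if (nrow(ds) == 0 || nrow(db) == 0) abort("datasets must be non-empty")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  q_planted <- if ("planted" %in% names(ds)) ds$planted else rep(FALSE, nrow(ds))
  db_planted <- if ("planted" %in% names(db)) db$planted else rep(TRUE, nrow(db))
  rows <- list()
  for (i in seq_len(nrow(ds))) {
    qid <- ds$id[i]
    if (qid %in% db$id) {
      rows[[length(rows) + 1]] <- tibble(query = qid, subject = qid, evalue = 1e-180)
    }
    if (!q_planted[i]) next
    partners <- db$id[db_planted & db$id != qid]
    if (length(partners) == 0) next
    subj <- partners[sample.int(length(partners), 1)]
    ev <- 10^runif(1, min = -50, max = -5)
    rows[[length(rows) + 1]] <- tibble(query = qid, subject = subj, evalue = ev)
  }
  if (length(rows) == 0) {
    return(tibble(query = character(0), subject = character(0), evalue = numeric(0)))
  }
  bind_rows(rows)
}
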