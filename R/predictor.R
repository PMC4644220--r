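# The combined MAP predictor: motif lapSVM + CKSAAP lapSVM + homology,
# fused by weighted averaging and cut at stringency thresholds.

#' Train the combined MAP predictor
#'
#' Runs the full training pipeline: degenerate-motif discovery on the
#' labeled records, mRMR reduction of the motif feature set, one Laplacian
#' SVM on the selected binary motif features and one on the CKSAAP
#' encoding (both using any unlabeled records), and retention of the
#' positive training set as the homology-search database.
#'
#' @param data Dataset tibble with `positive` and `negative` records;
#'   rows labeled `unlabeled` are used by the semi-supervised classifiers.
#' @param discovery Named list of overrides for [discover_motifs()]
#'   arguments (`length_range`, `max_wildcards`, `min_pos_support`,
#'   `max_neg_support`, `top_n`).
#' @param n_motif_features Motif features to keep after mRMR (capped at the
#'   number of discovered candidates).
#' @param k_max CKSAAP spacing limit.
#' @param motif_config,cksaap_config [lapsvm_config()] for the two
#'   classifiers.
#' @param weights [fusion_weights()] for score fusion.
#' @param thresholds Stringency threshold tibble (`level`, `value`).
#' @return An object of class `map_predictor`.
#' @export
map_train <- function(data,
                      discovery = list(),
                      n_motif_features = 463,
                      k_max = 1,
                      motif_config = lapsvm_config(),
                      cksaap_config = lapsvm_config(),
                      weights = fusion_weights(),
                      thresholds = stringency_thresholds()) {
  validate_dataset(data)
  pos <- filter(data, label == "positive")
  neg <- filter(data, label == "negative")
  unl <- filter(data, label == "unlabeled")
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("training data must contain both positive and negative records")
  }
  labeled <- bind_rows(pos, neg)

  disc_args <- modifyList(
    list(length_range = c(2, 6), max_wildcards = 2,
         min_pos_support = 0.05, max_neg_support = 0.02, top_n = 5000),
    discovery
  )
  candidates <- do.call(discover_motifs, c(list(pos = pos, neg = neg), disc_args))
  if (nrow(candidates) == 0) {
    abort("motif discovery produced no candidates; relax the support thresholds")
  }

  Xm <- encode_dataset(labeled, "motifs", motifs = candidates$motif)
  m <- min(n_motif_features, nrow(candidates))
  selection <- mrmr_select(Xm, m = m)
  motifs <- selection$feature

  Xm_sel <- Xm[, c("id", "label", motifs)]
  Um_sel <- if (nrow(unl) > 0) encode_dataset(unl, "motifs", motifs = motifs) else NULL
  motif_model <- train_lapsvm(Xm_sel, X_unlabeled = Um_sel, config = motif_config)

  Xc <- encode_dataset(labeled, "cksaap", k_max = k_max)
  Uc <- if (nrow(unl) > 0) encode_dataset(unl, "cksaap", k_max = k_max) else NULL
  cksaap_model <- train_lapsvm(Xc, X_unlabeled = Uc, config = cksaap_config)

  structure(list(
    motifs = motifs,
    candidates = candidates,
    selection = selection,
    motif_model = motif_model,
    cksaap_model = cksaap_model,
    k_max = k_max,
    db = pos,
    weights = weights,
    thresholds = thresholds,
    n_train = c(positive = nrow(pos), negative = nrow(neg), unlabeled = nrow(unl))
  ), class = "map_predictor")
}

#' @export
print.map_predictor <- function(x, ...) {
  cat("Combined MAP predictor\n")
  cat(sprintf("  training records: %d positive, %d negative, %d unlabeled\n",
              x$n_train["positive"], x$n_train["negative"], x$n_train["unlabeled"]))
  cat(sprintf("  motif features: %d (of %d discovered candidates)\n",
              length(x$motifs), nrow(x$candidates)))
  cat(sprintf("  CKSAAP features: %d (k_max = %d)\n", 400 * (x$k_max + 1), x$k_max))
  cat(sprintf("  fusion weights: motif %.2f, CKSAAP %.2f, BLAST %.2f\n",
              x$weights$motif, x$weights$cksaap, x$weights$blast))
  invisible(x)
}

#' Predict MAP scores for new sequences
#'
#' @param object A `map_predictor` from [map_train()].
#' @param newdata Dataset tibble of query records.
#' @param backend Homology backend; when `NULL` and `homology_hits` is
#'   also `NULL`, every query is treated as having no homology hit
#'   (`pev = -3`).
#' @param homology_hits Convenience: a precomputed hit tibble/path wrapped
#'   with [homology_backend_tsv()].
#' @param ... Unused.
#' @return Tibble with one row per query in input order: `id`, `ds_motif`,
#'   `ds_cksaap`, `pev`, `s_combined`, and one `call_<level>` column per
#'   stringency threshold.
#' @export
predict.map_predictor <- function(object, newdata, backend = NULL,
                                  homology_hits = NULL, ...) {
  validate_dataset(newdata, "newdata")
  if (is.null(backend) && !is.null(homology_hits)) {
    backend <- homology_backend_tsv(homology_hits)
  }
  Xm <- encode_dataset(newdata, "motifs", motifs = object$motifs)
  ds_motif <- decision_score(object$motif_model, Xm)
  Xc <- encode_dataset(newdata, "cksaap", k_max = object$k_max)
  ds_cksaap <- decision_score(object$cksaap_model, Xc)
  pev <- if (is.null(backend)) rep(-3, nrow(newdata)) else {
    best_hit_all(newdata, object$db, backend)$pev
  }
  s <- combine_scores(ds_motif, ds_cksaap, pev, object$weights)
  out <- tibble(id = newdata$id, ds_motif = ds_motif, ds_cksaap = ds_cksaap,
                pev = pev, s_combined = s)
  for (i in seq_len(nrow(object$thresholds))) {
    out[[paste0("call_", object$thresholds$level[i])]] <-
      classify_combined(s, object$thresholds$value[i])
  }
  out
}

#' Detailed single-query report
#'
#' The single-prediction mode: besides the fused scores, reports the match
#' positions of every selected motif present in the query and the database
#' homologs under the reporting E-value ceiling.
#'
#' @param object A `map_predictor`.
#' @param query One-row dataset tibble.
#' @param backend Optional homology backend (see
#'   [predict.map_predictor()]).
#' @param evalue_max Homolog reporting ceiling (default 1e-4).
#' @return List with elements `scores` (one-row prediction tibble),
#'   `motif_positions` (tibble `motif`, `start`) and `homologs` (hit
#'   tibble, possibly empty).
#' @export
map_report <- function(object, query, backend = NULL, evalue_max = 1e-4) {
  stopifnot(inherits(object, "map_predictor"))
  query <- head(query, 1)
  scores <- predict(object, query, backend = backend)
  hits <- map(object$motifs, function(m) {
    st <- match_motif(query$sequence, m)
    if (length(st) == 0) NULL else tibble(motif = m, start = st)
  })
  motif_positions <- bind_rows(hits)
  if (nrow(motif_positions) == 0) {
    motif_positions <- tibble(motif = character(0), start = integer(0))
  }
  homologs <- if (is.null(backend)) {
    tibble(query = character(0), subject = character(0), evalue = numeric(0))
  } else {
    homolog_hits(query, object$db, backend, evalue_max = evalue_max)
  }
  list(scores = scores, motif_positions = motif_positions, homologs = homologs)
}

#' @export
tidy.map_predictor <- function(x, ...) {
  left_join(x$selection,
            select(x$candidates, feature = motif, pos_support, neg_support),
            by = "feature")
}

#' @export
glance.map_predictor <- function(x, ...) {
  tibble(n_motif_features = length(x$motifs),
         n_candidates = nrow(x$candidates),
         k_max = x$k_max,
         n_pos = unname(x$n_train["positive"]),
         n_neg = unname(x$n_train["negative"]),
         n_unlabeled = unname(x$n_train["unlabeled"]))
}

serialize_classifier <- function(m) {
  list(alpha = m$alpha, b = m$b, X = as.vector(m$X), dim = dim(m$X),
       feature_names = m$feature_names, rbf_gamma = m$rbf_gamma,
       config = unclass(m$config), n_labeled = m$n_labeled,
       n_unlabeled = m$n_unlabeled)
}

deserialize_classifier <- function(s) {
  X <- matrix(s$X, nrow = s$dim[1], ncol = s$dim[2])
  colnames(X) <- s$feature_names
  structure(list(alpha = s$alpha, b = s$b, X = X,
                 feature_names = s$feature_names, rbf_gamma = s$rbf_gamma,
                 config = structure(s$config, class = "lapsvm_config"),
                 n_labeled = s$n_labeled, n_unlabeled = s$n_unlabeled),
            class = "map_classifier")
}

#' Save a trained predictor to a versioned JSON file
#'
#' Coefficients are written with full double precision (17 significant
#' digits), so a reloaded model reproduces predictions exactly.
#'
#' @param object A `map_predictor`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictor <- function(object, path) {
  stopifnot(inherits(object, "map_predictor"))
  payload <- list(
    format = "mapredict-model",
    version = 1L,
    package_version = as.character(utils::packageVersion("mapredict")),
    motifs = object$motifs,
    candidates = object$candidates,
    selection = as.data.frame(object$selection),
    motif_model = serialize_classifier(object$motif_model),
    cksaap_model = serialize_classifier(object$cksaap_model),
    k_max = object$k_max,
    db = object$db,
    weights = unclass(object$weights),
    thresholds = object$thresholds,
    n_train = as.list(object$n_train)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 17, null = "null")
  invisible(path)
}

#' Load a predictor saved by [write_predictor()]
#'
#' @param path Path to the model JSON file.
#' @return A `map_predictor`.
#' @export
read_predictor <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(s$format, "mapredict-model")) abort("not a mapredict model file")
  sel <- as_tibble(s$selection)
  class(sel) <- c("mrmr_selection", class(sel))
  structure(list(
    motifs = s$motifs,
    candidates = as_tibble(s$candidates),
    selection = sel,
    motif_model = deserialize_classifier(s$motif_model),
    cksaap_model = deserialize_classifier(s$cksaap_model),
    k_max = s$k_max,
    db = as_tibble(s$db),
    weights = structure(as.list(s$weights), class = "fusion_weights"),
    thresholds = as_tibble(s$thresholds),
    n_train = unlist(s$n_train)
  ), class = "map_predictor")
}
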