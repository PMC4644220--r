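# Three-way score fusion and benchmark statistics.
#
# The final predictor score is a weighted average of the two normalized
# lapSVM decision scores and the transformed homology score:
#
#   S_combined = (1/3) * (a_M * norm(Ds_motif)
#                         + a_C * norm(Ds_cksaap)
#                         + a_B * pEv / 10)
#
# with norm(Ds) = (1 - exp(-Ds)) / (1 + exp(-Ds)) and default weights
# (0.35, 0.5, 0.15). Classification cuts S_combined at fixed stringency
# thresholds chosen to target 99/95/90/80% specificity.

#' Fusion weights for the combined predictor
#'
#' @param motif,cksaap,blast Non-negative weights for the motif lapSVM,
#'   CKSAAP lapSVM and homology terms; defaults 0.35, 0.5, 0.15.
#' @return A named list of class `fusion_weights`.
#' @export
fusion_weights <- function(motif = 0.35, cksaap = 0.5, blast = 0.15) {
  stopifnot(motif >= 0, cksaap >= 0, blast >= 0)
  structure(list(motif = motif, cksaap = cksaap, blast = blast),
            class = "fusion_weights")
}

#' Combine the three predictor scores
#'
#' @param ds_motif,ds_cksaap Raw decision scores of the motif and CKSAAP
#'   classifiers (normalized internally).
#' @param pev Transformed homology score in `[-3, 200]` from
#'   [transform_pev()].
#' @param weights A [fusion_weights()] object.
#' @return Numeric vector of combined scores, strictly increasing in each
#'   argument when its weight is positive.
#' @export
#' @examples
#' combine_scores(0, 0, -3)
combine_scores <- function(ds_motif, ds_cksaap, pev, weights = fusion_weights()) {
  stopifnot(inherits(weights, "fusion_weights"))
  if (any(pev < -3 - 1e-9 | pev > 200 + 1e-9, na.rm = TRUE)) {
    abort("pev must lie in [-3, 200]; apply transform_pev() first")
  }
  (weights$motif * normalize_score(ds_motif) +
     weights$cksaap * normalize_score(ds_cksaap) +
     weights$blast * pev / 10) / 3
}

#' Default stringency thresholds for the combined predictor
#'
#' Fixed cuts on the combined score targeting 99% (very high), 95% (high),
#' 90% (moderate) and 80% (low) specificity.
#'
#' @return Tibble with columns `level` and `value`, strictly decreasing.
#' @export
stringency_thresholds <- function() {
  tibble(level = c("very_high", "high", "moderate", "low"),
         value = c(0.121, 0.019, -0.008, -0.042))
}

#' Classify combined scores at a stringency threshold
#'
#' A score equal to the threshold is called MAP (boundary rule `S >=
#' threshold`).
#'
#' @param s Numeric vector of combined scores.
#' @param threshold A numeric cut, or a stringency level name
#'   (`"very_high"`, `"high"`, `"moderate"`, `"low"`) resolved against
#'   [stringency_thresholds()].
#' @return Character vector of `"MAP"` / `"NOT_MAP"`.
#' @export
classify_combined <- function(s, threshold = "moderate") {
  if (is.character(threshold)) {
    th <- stringency_thresholds()
    threshold <- arg_match(threshold, th$level)
    threshold <- th$value[th$level == threshold]
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  ifelse(s >= threshold, "MAP", "NOT_MAP")
}

#' Confusion counts at a threshold
#'
#' @param scores Numeric vector of scores.
#' @param labels Labels for each score: `"positive"`/`"negative"`, 0/1 or
#'   -1/+1. Unlabeled records are an error — evaluation is on labeled data
#'   only.
#' @param threshold Scores `>= threshold` are predicted positive.
#' @return One-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (any(as.character(labels) %in% c("unlabeled", "unknown"))) {
    abort("labels contain unlabeled/unknown records; evaluate on labeled data only")
  }
  y <- as_pm1(labels)
  pred <- scores >= threshold
  tibble(tp = sum(pred & y > 0), fp = sum(pred & y < 0),
         tn = sum(!pred & y < 0), fn = sum(!pred & y > 0))
}

#' Sensitivity, specificity and MCC from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any denominator factor vanishes.
#'
#' @param counts One-row tibble/list with `tp`, `fp`, `tn`, `fn` (e.g.
#'   from [confusion_counts()]).
#' @return One-row tibble with `sensitivity`, `specificity`, `mcc`.
#' @export
confusion_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (tp + fn == 0) abort("no positive samples (TP + FN = 0)")
  if (tn + fp == 0) abort("no negative samples (TN + FP = 0)")
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp), mcc = mcc)
}

#' ROC curve and AUC
#'
#' AUC is computed in the Mann-Whitney form — the probability that a random
#' positive outscores a random negative, ties counted one half — via mid
#' ranks, so small samples are exact. ROC points sweep every distinct score
#' threshold (prediction rule `score >= threshold`) from (0, 0) to (1, 1).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (see [confusion_counts()]).
#' @return List with `auc` and `roc_points` (tibble of `fpr`, `tpr`,
#'   non-decreasing in both coordinates).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_pm1(labels)
  n_pos <- sum(y > 0)
  n_neg <- sum(y < 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y > 0), numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & y < 0), numeric(1)) / n_neg
  pts <- tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[!duplicated(pts), ]
  list(auc = auc, roc_points = pts)
}

#' Calibrate stringency thresholds to target specificities
#'
#' For each target, returns the smallest threshold whose measured
#' specificity on the given data reaches the target (rule `score >=
#' threshold` predicts positive). When even the maximum observed score
#' fails the target, the maximum plus a small offset is returned with a
#' warning.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; negatives must be present.
#' @param targets Specificity targets in `(0, 1)`; default
#'   `c(0.99, 0.95, 0.90)`.
#' @return Tibble with columns `target`, `threshold`, `sensitivity`,
#'   `specificity` (the measured values at the returned threshold).
#' @export
calibrate_thresholds <- function(scores, labels, targets = c(0.99, 0.95, 0.90)) {
  stopifnot(all(targets > 0), all(targets < 1))
  y <- as_pm1(labels)
  if (sum(y < 0) == 0) abort("negatives must be present to calibrate specificity")
  neg <- scores[y < 0]
  cand <- sort(unique(scores))
  rows <- map(targets, function(tg) {
    spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
    hit <- which(spec >= tg)
    if (length(hit) == 0) {
      warn(sprintf("specificity target %.3f unreachable; returning max score + eps", tg))
      thr <- max(scores) + 1e-8
    } else {
      thr <- cand[hit[1]]
    }
    cc <- confusion_counts(scores, labels, thr)
    m <- confusion_metrics(cc)
    tibble(target = tg, threshold = thr,
           sensitivity = m$sensitivity, specificity = m$specificity)
  })
  bind_rows(rows)
}
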