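test_that("score fusion reproduces hand-computed values and saturation", {
  expect_equal(combine_scores(0, 0, 0), 0)
  expect_equal(combine_scores(0, 0, -3), -0.015)
  # saturation of both classifiers and a clamped homology score
  expect_equal(combine_scores(1000, 1000, 200),
               (0.35 + 0.5 + 0.15 * 20) / 3, tolerance = 1e-12)
  expect_equal(combine_scores(1000, 1000, 200), 1.2833333, tolerance = 1e-6)
  expect_error(combine_scores(0, 0, 300), "\\[-3, 200\\]")
})

test_that("fusion is strictly monotone in each argument and bounded", {
  set.seed(61)
  w <- fusion_weights()
  lo <- -(w$motif + w$cksaap + 0.3 * w$blast) / 3
  hi <- (w$motif + w$cksaap + 20 * w$blast) / 3
  for (i in 1:50) {
    dm <- rnorm(1, 0, 3); dc <- rnorm(1, 0, 3); pe <- runif(1, -3, 200)
    s <- combine_scores(dm, dc, pe)
    expect_gt(s, lo); expect_lt(s, hi)
    eps <- 1e-3
    expect_gt(combine_scores(dm + eps, dc, pe), s)
    expect_gt(combine_scores(dm, dc + eps, pe), s)
    if (pe < 199) expect_gt(combine_scores(dm, dc, pe + eps), s)
  }
})

test_that("stringency classification uses the S >= threshold boundary rule", {
  th <- stringency_thresholds()
  expect_equal(th$value, c(0.121, 0.019, -0.008, -0.042))
  expect_true(all(diff(th$value) < 0))
  expect_equal(classify_combined(0.13, "very_high"), "MAP")
  expect_equal(classify_combined(0.0, "low"), "MAP")
  expect_equal(classify_combined(0.0, "moderate"), "MAP")
  expect_equal(classify_combined(0.0, "high"), "NOT_MAP")
  expect_equal(classify_combined(0.121, 0.121), "MAP")  # boundary: called MAP
})

test_that("confusion counts match hand tallies and reject unlabeled input", {
  cc <- confusion_counts(c(0.9, 0.2, 0.8, 0.1),
                         c("positive", "positive", "negative", "negative"), 0.5)
  expect_equal(unlist(cc), c(tp = 1, fp = 1, tn = 1, fn = 1))
  sep <- confusion_counts(c(1, 1, 0, 0), c("positive", "positive", "negative", "negative"), 0.5)
  expect_equal(sep$fp + sep$fn, 0)
  low <- confusion_counts(c(1, 1, 0.2, 0.3), c("positive", "positive", "negative", "negative"), 0)
  expect_equal(low$tn + low$fn, 0)
  expect_error(confusion_counts(1:3, c("positive", "negative", "unlabeled"), 0.5),
               "unlabeled")
})

test_that("sensitivity, specificity and MCC follow the printed formulas", {
  perfect <- confusion_metrics(list(tp = 48, fn = 0, tn = 2400, fp = 0))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1, mcc = 1))
  m <- confusion_metrics(list(tp = 2, fp = 1, tn = 1, fn = 0))
  expect_equal(m$mcc, 2 / sqrt(12))
  zero <- confusion_metrics(list(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(zero$mcc, 0)
  # zero denominator factor -> MCC defined as 0
  degen <- confusion_metrics(list(tp = 0, fp = 0, tn = 3, fn = 2))
  expect_equal(degen$mcc, 0)
  expect_error(confusion_metrics(list(tp = 0, fp = 1, tn = 1, fn = 0)), "no positive")
})

test_that("AUC matches trivial cases and the pairwise oracle exactly", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("positive", "positive", "negative", "negative"))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(rep("positive", 3), rep("negative", 3)))$auc, 0.5)
  expect_equal(roc_auc(c(0.8, 0.3, 0.5, 0.1),
                       c("positive", "positive", "negative", "negative"))$auc, 0.75)
  set.seed(62)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), 2)  # rounding forces ties
    labels <- ifelse(rbinom(n, 1, 0.4) == 1, "positive", "negative")
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(63)
  scores <- rnorm(150)
  labels <- ifelse(rbinom(150, 1, 0.3) == 1, "positive", "negative")
  scores[labels == "positive"] <- scores[labels == "positive"] + 1
  ref <- suppressMessages(pROC::auc(pROC::roc(labels == "positive", scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(64)
  scores <- rnorm(60)
  labels <- c(rep("positive", 20), rep("negative", 40))
  pts <- roc_auc(scores, labels)$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("raising the threshold trades sensitivity for specificity monotonically", {
  set.seed(65)
  scores <- rnorm(100)
  labels <- ifelse(rbinom(100, 1, 0.3) == 1, "positive", "negative")
  if (length(unique(labels)) < 2) labels[1:2] <- c("positive", "negative")
  ths <- sort(runif(10, -2, 2))
  mets <- lapply(ths, function(t) confusion_metrics(confusion_counts(scores, labels, t)))
  sens <- vapply(mets, function(m) m$sensitivity, numeric(1))
  spec <- vapply(mets, function(m) m$specificity, numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("calibrated thresholds reach their specificity targets", {
  set.seed(66)
  neg <- sort(rnorm(10))
  scores <- c(neg, rnorm(5, 2))
  labels <- c(rep("negative", 10), rep("positive", 5))
  cal <- calibrate_thresholds(scores, labels, targets = 0.90)
  # at most one of the 10 negatives may sit at or above the threshold
  expect_lte(sum(neg >= cal$threshold), 1)
  expect_gte(cal$specificity, 0.90)
  # near-1 target with distinct scores: threshold clears the top negative
  cal2 <- suppressWarnings(calibrate_thresholds(scores, labels, targets = 0.999))
  expect_gt(cal2$threshold, max(neg))
  # re-applying a calibrated threshold reproduces its measured specificity
  cc <- confusion_counts(scores, labels, cal$threshold)
  expect_equal(confusion_metrics(cc)$specificity, cal$specificity)
})

test_that("an unreachable specificity target warns and returns max score + eps", {
  scores <- rep(1, 6)
  labels <- c(rep("negative", 5), "positive")
  expect_warning(cal <- calibrate_thresholds(scores, labels, targets = 0.9),
                 "unreachable")
  expect_gt(cal$threshold, 1)
})

test_that("map_evaluate ties the report to its components", {
  set.seed(67)
  scores <- c(rnorm(20, 1.5), rnorm(100, -1))
  preds <- tibble::tibble(id = sprintf("q%03d", 1:120), s_combined = scores)
  labels <- tibble::tibble(id = preds$id,
                           label = c(rep("positive", 20), rep("negative", 100)))
  ev <- map_evaluate(preds, labels)
  expect_s3_class(ev, "map_evaluation")
  expect_equal(glance(ev)$auc, roc_auc(scores, labels$label)$auc)
  expect_equal(nrow(tidy(ev)), nrow(stringency_thresholds()))
  row <- tidy(ev)[2, ]
  cc <- confusion_counts(scores, labels$label, row$threshold)
  expect_equal(row$sensitivity, confusion_metrics(cc)$sensitivity)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
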