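# Kernel classifiers: supervised squared-hinge SVM and the semi-supervised
# Laplacian SVM (manifold regularization), both solved in the primal over a
# representer expansion on all labeled + unlabeled points.
#
# Objective, for l labeled and u unlabeled points with f = K alpha + b:
#
#   (1/l) sum_i w_i max(0, 1 - y_i f_i)^2
#     + gamma_A * alpha' K alpha
#     + gamma_I / (l+u)^2 * f' L f
#
# where L is the unnormalized Laplacian of a symmetric kNN graph with RBF
# edge weights sharing the kernel width. The squared hinge makes the
# problem piecewise quadratic; Newton iterations on the active set converge
# in a handful of steps and are fully deterministic. The Laplacian term is
# invariant to the bias because L annihilates constants.

#' Laplacian-SVM configuration
#'
#' @param rbf_gamma RBF kernel width `exp(-gamma * ||x - x'||^2)`; `NULL`
#'   means `1 / n_features`, resolved at fit time.
#' @param gamma_A Ambient (RKHS norm) regularization weight, > 0.
#' @param gamma_I Intrinsic (manifold) regularization weight, >= 0; 0 turns
#'   the model into a purely supervised SVM.
#' @param knn Neighbors for the similarity graph.
#' @param balance_classes Weight each labeled point inversely to its class
#'   frequency (recommended for the 1:10 training ratio).
#' @param max_iter Cap on Newton active-set iterations.
#' @return A list of class `lapsvm_config`.
#' @export
lapsvm_config <- function(rbf_gamma = NULL, gamma_A = 1e-4, gamma_I = 1e-2,
                          knn = 7, balance_classes = TRUE, max_iter = 50) {
  stopifnot(is.null(rbf_gamma) || rbf_gamma > 0, gamma_A > 0, gamma_I >= 0, knn >= 1)
  structure(list(rbf_gamma = rbf_gamma, gamma_A = gamma_A, gamma_I = gamma_I,
                 knn = as.integer(knn), balance_classes = isTRUE(balance_classes),
                 max_iter = as.integer(max_iter)),
            class = "lapsvm_config")
}

sqdist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

rbf_kernel <- function(X, Y, gamma) exp(-gamma * sqdist(X, Y))

# unnormalized Laplacian of the symmetric kNN graph with RBF edge weights
knn_laplacian <- function(K, d2, knn) {
  n <- nrow(K)
  W <- matrix(0, n, n)
  k <- min(knn, n - 1)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], method = "radix")
    nb <- setdiff(ord, i)[seq_len(k)]
    W[i, nb] <- K[i, nb]
  }
  W <- pmax(W, t(W))
  diag(rowSums(W)) - W
}

resolve_features <- function(X, labels) {
  if (is.data.frame(X)) {
    if (is.null(labels) && "label" %in% names(X)) labels <- X$label
    X <- feature_matrix(X)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  list(X = X, labels = labels)
}

as_pm1 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    lab <- as.character(labels)
    bad <- !lab %in% c("positive", "negative")
    if (any(bad)) abort("labels must be 'positive' or 'negative'")
    return(ifelse(lab == "positive", 1, -1))
  }
  y <- as.numeric(labels)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) abort("labels must be binary")
  y
}

#' Train a Laplacian SVM
#'
#' @param X Labeled feature tibble (from [encode_dataset()]) or numeric
#'   matrix.
#' @param labels Class labels for the rows of `X` (`"positive"`/
#'   `"negative"`, 0/1 or -1/+1); taken from the `label` column when `X` is
#'   a feature tibble.
#' @param X_unlabeled Optional unlabeled feature tibble/matrix over the
#'   same features; may be `NULL` (supervised case).
#' @param config A [lapsvm_config()].
#' @return An object of class `map_classifier` holding the expansion
#'   coefficients, bias, retained training points and feature names.
#' @export
train_lapsvm <- function(X, labels = NULL, X_unlabeled = NULL, config = lapsvm_config()) {
  rf <- resolve_features(X, labels)
  Xl <- rf$X
  y <- as_pm1(rf$labels)
  if (length(unique(y)) < 2) abort("labeled data must contain both classes")
  Xu <- NULL
  if (!is.null(X_unlabeled)) {
    Xu <- resolve_features(X_unlabeled, NULL)$X
    if (nrow(Xu) == 0) Xu <- NULL
    if (!is.null(Xu) && ncol(Xu) != ncol(Xl)) {
      abort(sprintf("unlabeled features have %d columns, labeled have %d", ncol(Xu), ncol(Xl)))
    }
    if (!is.null(Xu) && !is.null(colnames(Xu)) && !is.null(colnames(Xl))) {
      Xu <- Xu[, colnames(Xl), drop = FALSE]
    }
  }
  l <- nrow(Xl)
  Xall <- rbind(Xl, Xu)
  n <- nrow(Xall)
  gamma <- config$rbf_gamma %||% (1 / ncol(Xall))

  d2 <- sqdist(Xall, Xall)
  K <- exp(-gamma * d2)
  yfull <- c(y, rep(0, n - l))
  wbase <- numeric(n)
  if (config$balance_classes) {
    npos <- sum(y > 0); nneg <- sum(y < 0)
    wbase[seq_len(l)] <- ifelse(y > 0, l / (2 * npos), l / (2 * nneg))
  } else {
    wbase[seq_len(l)] <- 1
  }

  use_lap <- config$gamma_I > 0 && n > 1
  LK <- if (use_lap) (config$gamma_I / n^2) * (knn_laplacian(K, d2, config$knn) %*% K) else NULL

  alpha <- numeric(n)
  b <- 0
  active <- yfull != 0  # start with every labeled point in the hinge
  for (iter in seq_len(config$max_iter)) {
    w <- wbase * active
    sw <- sum(w)
    if (sw == 0) break
    M <- (w / l) * K  # row-scaled kernel
    diag(M) <- diag(M) + config$gamma_A
    if (use_lap) M <- M + LK
    M <- cbind(M, w / l)
    M <- rbind(M, c(as.vector(w %*% K) / l, sw / l))
    rhs <- c(w * yfull / l, sum(w * yfull) / l)
    sol <- solve(M, rhs)
    alpha <- sol[seq_len(n)]
    b <- sol[n + 1]
    f <- as.vector(K %*% alpha) + b
    new_active <- (yfull != 0) & (yfull * f < 1)
    if (identical(new_active, active)) break
    active <- new_active
  }

  structure(list(alpha = alpha, b = b, X = Xall,
                 feature_names = colnames(Xall),
                 rbf_gamma = gamma, config = config,
                 n_labeled = l, n_unlabeled = n - l),
            class = "map_classifier")
}

#' Train a supervised kernel SVM (squared hinge)
#'
#' Soft-margin RBF-kernel SVM with squared-hinge loss, solved as the
#' supervised degenerate case of [train_lapsvm()] (`gamma_I = 0`, no
#' unlabeled points) with the cost parameter mapped to the ambient
#' regularizer by `gamma_A = 1 / (2 * C * l)`.
#'
#' @inheritParams train_lapsvm
#' @param C Soft-margin cost, > 0.
#' @param rbf_gamma RBF kernel width; `NULL` means `1 / n_features`.
#' @param balance_classes Weight classes inversely to frequency.
#' @return A `map_classifier`.
#' @export
train_svm <- function(X, labels = NULL, C = 1, rbf_gamma = NULL, balance_classes = TRUE) {
  stopifnot(C > 0)
  rf <- resolve_features(X, labels)
  l <- nrow(rf$X)
  cfg <- lapsvm_config(rbf_gamma = rbf_gamma, gamma_A = 1 / (2 * C * l),
                       gamma_I = 0, balance_classes = balance_classes)
  train_lapsvm(rf$X, rf$labels, NULL, cfg)
}

#' Raw decision score of a trained classifier
#'
#' @param model A `map_classifier`.
#' @param x A feature vector, matrix or feature tibble; columns are
#'   reordered by name to the model's feature order when names are
#'   available.
#' @return Numeric vector of raw margins; positive means predicted MAP.
#' @export
decision_score <- function(model, x) {
  stopifnot(inherits(model, "map_classifier"))
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  storage.mode(x) <- "double"
  p <- ncol(model$X)
  if (!is.null(colnames(x)) && !is.null(model$feature_names)) {
    miss <- setdiff(model$feature_names, colnames(x))
    if (length(miss) > 0) {
      abort(sprintf("input is missing %d model feature(s), e.g. %s",
                    length(miss), paste(head(miss, 3), collapse = ", ")))
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  if (ncol(x) != p) abort(sprintf("expected %d features, got %d", p, ncol(x)))
  Kx <- rbf_kernel(x, model$X, model$rbf_gamma)
  as.vector(Kx %*% model$alpha) + model$b
}

#' Normalize a raw decision score to (-1, 1)
#'
#' Applies `(1 - exp(-Ds)) / (1 + exp(-Ds))`, computed as `tanh(Ds / 2)`
#' for overflow safety. Odd and strictly increasing, saturating at +/-1.
#'
#' @param ds Numeric vector of raw decision scores.
#' @return Normalized scores in `(-1, 1)`.
#' @export
normalize_score <- function(ds) tanh(ds / 2)

#' 5-fold cross-validated hyperparameter search
#'
#' Stratified, seeded 5-fold split of the labeled data; every grid point is
#' trained on 4 folds (plus all unlabeled points) and scored by AUC on the
#' held-out fold. The grid point with the highest mean AUC wins; ties go to
#' the earlier grid entry.
#'
#' @param X Labeled feature tibble or matrix.
#' @param labels Class labels (see [train_lapsvm()]).
#' @param X_unlabeled Optional unlabeled features used by every fit.
#' @param grid List of [lapsvm_config()] objects.
#' @param seed Integer seed for the fold assignment.
#' @return List with `best_config`, `best_index` and the full `cv` tibble
#'   (columns `config`, `fold`, `auc`, `mean_auc`).
#' @export
tune_5fold <- function(X, labels = NULL, X_unlabeled = NULL, grid, seed = 1) {
  stopifnot(is.list(grid), length(grid) >= 1)
  rf <- resolve_features(X, labels)
  y <- as_pm1(rf$labels)
  if (length(y) < 10) abort("need at least 10 labeled samples")
  if (min(table(y)) < 5) abort("each class needs at least 5 members to stratify 5 folds")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in c(-1, 1)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(1:5, length.out = length(idx)))
  }
  rows <- list()
  for (g in seq_along(grid)) {
    for (k in 1:5) {
      tr <- fold != k
      model <- train_lapsvm(rf$X[tr, , drop = FALSE], y[tr], X_unlabeled, grid[[g]])
      s <- decision_score(model, rf$X[!tr, , drop = FALSE])
      rows[[length(rows) + 1]] <- tibble(config = g, fold = k,
                                         auc = roc_auc(s, y[!tr])$auc)
    }
  }
  cv <- bind_rows(rows)
  means <- vapply(seq_along(grid), function(g) mean(cv$auc[cv$config == g]), numeric(1))
  best <- which.max(means)
  cv$mean_auc <- means[cv$config]
  list(best_config = grid[[best]], best_index = best, cv = cv)
}
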