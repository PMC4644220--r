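sep_toy <- function() {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(0.5, 0.5),
             c(3, 3), c(3, 4), c(4, 3), c(3.5, 3.5))
  colnames(X) <- c("x1", "x2")
  list(X = X, y = rep(c("negative", "positive"), each = 4))
}

test_that("supervised SVM separates a linearly separable toy", {
  toy <- sep_toy()
  m <- train_svm(toy$X, toy$y, C = 10, rbf_gamma = 0.5)
  s <- decision_score(m, toy$X)
  expect_true(all(sign(s) == ifelse(toy$y == "positive", 1, -1)))
  expect_error(train_svm(toy$X, rep("positive", 8)), "both classes")
})

test_that("decision scores are pure and dimension-checked", {
  toy <- sep_toy()
  m <- train_svm(toy$X, toy$y, C = 1, rbf_gamma = 0.5)
  s1 <- decision_score(m, toy$X[1, ])
  s2 <- decision_score(m, toy$X[1, ])
  expect_identical(s1, s2)
  expect_error(decision_score(m, c(1, 2, 3)), "expected 2 features, got 3")
})

test_that("duplicating every training point leaves the decision function unchanged", {
  # the loss is averaged over labeled points, so exact replication of the
  # dataset leaves the regularized objective, and hence the fit, unchanged
  toy <- sep_toy()
  cfg <- lapsvm_config(rbf_gamma = 0.7, gamma_A = 1e-2, gamma_I = 0)
  m1 <- train_lapsvm(toy$X, toy$y, NULL, cfg)
  m2 <- train_lapsvm(rbind(toy$X, toy$X), c(toy$y, toy$y), NULL, cfg)
  set.seed(41)
  probe <- matrix(runif(40, -1, 5), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(decision_score(m1, probe), decision_score(m2, probe),
               tolerance = 1e-6)
})

test_that("shrinking C drives decision scores toward a constant", {
  toy <- sep_toy()
  strong <- train_svm(toy$X, toy$y, C = 10, rbf_gamma = 0.5)
  weak <- train_svm(toy$X, toy$y, C = 1e-6, rbf_gamma = 0.5)
  dev <- function(m) max(abs(decision_score(m, toy$X) - mean(decision_score(m, toy$X))))
  expect_lt(dev(weak), dev(strong))
})

test_that("svm predictions agree in sign with an independent LIBSVM fit", {
  toy <- sep_toy()
  ours <- train_svm(toy$X, toy$y, C = 10, rbf_gamma = 0.5, balance_classes = FALSE)
  ref <- e1071::svm(toy$X, factor(toy$y), kernel = "radial", gamma = 0.5,
                    cost = 10, scale = FALSE)
  set.seed(42)
  probe <- rbind(toy$X, matrix(runif(20, 0, 4), ncol = 2,
                               dimnames = list(NULL, c("x1", "x2"))))
  ref_pred <- predict(ref, probe)
  our_pred <- ifelse(decision_score(ours, probe) >= 0, "positive", "negative")
  expect_gte(mean(our_pred == as.character(ref_pred)), 0.9)
})

test_that("lapSVM with gamma_I = 0 and no unlabeled data equals the supervised SVM", {
  toy <- sep_toy()
  C <- 4
  l <- nrow(toy$X)
  sup <- train_svm(toy$X, toy$y, C = C, rbf_gamma = 0.5)
  lap <- train_lapsvm(toy$X, toy$y, NULL,
                      lapsvm_config(rbf_gamma = 0.5, gamma_A = 1 / (2 * C * l),
                                    gamma_I = 0))
  set.seed(43)
  probe <- matrix(runif(40, -1, 5), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(decision_score(sup, probe), decision_score(lap, probe),
               tolerance = 1e-6)
})

test_that("unlabeled bridges improve accuracy on a two-cluster manifold", {
  # each class lives on a horizontal strand; labels are only available at
  # the left end, test points at the right end, unlabeled points fill the
  # strand in between
  run_one <- function(seed) {
    set.seed(seed)
    strand <- function(y0, xr, n) {
      cbind(x1 = runif(n, xr[1], xr[2]), x2 = y0 + rnorm(n, 0, 0.05))
    }
    Xl <- rbind(strand(0.5, c(0, 0.4), 6), strand(-0.5, c(0, 0.4), 6))
    yl <- rep(c("positive", "negative"), each = 6)
    Xu <- rbind(strand(0.5, c(0.2, 2), 40), strand(-0.5, c(0.2, 2), 40))
    Xt <- rbind(strand(0.5, c(1.6, 2), 10), strand(-0.5, c(1.6, 2), 10))
    yt <- rep(c(1, -1), each = 10)
    cfg_sup <- lapsvm_config(rbf_gamma = 8, gamma_A = 1e-3, gamma_I = 0)
    cfg_semi <- lapsvm_config(rbf_gamma = 8, gamma_A = 1e-3, gamma_I = 10, knn = 7)
    acc <- function(cfg, unl) {
      m <- train_lapsvm(Xl, yl, unl, cfg)
      mean(sign(decision_score(m, Xt)) == yt)
    }
    c(sup = acc(cfg_sup, NULL), semi = acc(cfg_semi, Xu))
  }
  res <- vapply(1:20, run_one, numeric(2))
  expect_gte(mean(res["semi", ]), mean(res["sup", ]))
})

test_that("the decision function ignores unlabeled-sample order", {
  toy <- sep_toy()
  set.seed(44)
  Xu <- matrix(runif(30, 0, 4), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  cfg <- lapsvm_config(rbf_gamma = 0.5, gamma_A = 1e-3, gamma_I = 1)
  m1 <- train_lapsvm(toy$X, toy$y, Xu, cfg)
  m2 <- train_lapsvm(toy$X, toy$y, Xu[sample(nrow(Xu)), ], cfg)
  probe <- matrix(runif(40, -1, 5), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(decision_score(m1, probe), decision_score(m2, probe),
               tolerance = 1e-9)
})

test_that("a consistent feature-column permutation leaves predictions unchanged", {
  toy <- sep_toy()
  m1 <- train_svm(toy$X, toy$y, C = 2, rbf_gamma = 0.5)
  m2 <- train_svm(toy$X[, c(2, 1)], toy$y, C = 2, rbf_gamma = 0.5)
  probe <- toy$X + 0.1
  expect_equal(decision_score(m1, probe),
               decision_score(m2, probe[, c(2, 1)]), tolerance = 1e-9)
})

test_that("normalize_score matches the printed fusion transform", {
  expect_equal(normalize_score(0), 0)
  expect_equal(normalize_score(log(3)), 0.5)
  expect_equal(normalize_score(1000), 1.0)
  expect_equal(normalize_score(-1000), -1.0)
  ds <- seq(-5, 5, by = 0.25)
  expect_equal(normalize_score(ds), (1 - exp(-ds)) / (1 + exp(-ds)))
  expect_equal(normalize_score(-ds), -normalize_score(ds))
})

test_that("5-fold tuning partitions data, is seeded and picks the better kernel width", {
  set.seed(45)
  # two classes at very different length scales: gamma matched to the scale
  # separates, a gamma 1000x too large cannot generalize across folds
  n <- 30
  X <- rbind(matrix(rnorm(2 * n, 0, 1), ncol = 2),
             matrix(rnorm(2 * n, 4, 1), ncol = 2))
  colnames(X) <- c("x1", "x2")
  y <- rep(c("negative", "positive"), each = n)
  grid <- list(lapsvm_config(rbf_gamma = 300, gamma_A = 1e-3, gamma_I = 0),
               lapsvm_config(rbf_gamma = 0.3, gamma_A = 1e-3, gamma_I = 0))
  res <- tune_5fold(X, y, grid = grid, seed = 7)
  expect_equal(res$best_index, 2)
  expect_equal(nrow(res$cv), 10)
  # one-config grid returns that config
  one <- tune_5fold(X, y, grid = grid[2], seed = 7)
  expect_equal(one$best_index, 1)
  expect_error(tune_5fold(X[c(1:3, 31:60), ], y[c(1:3, 31:60)], grid = grid),
               "at least 5")
})
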