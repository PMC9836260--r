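test_that("the Gaussian grade mask peaks at the mean and is symmetric", {
  expect_equal(gaussian_weight(76.4), 1)
  expect_equal(gaussian_weight(76.4 + 5.16), exp(-0.5))
  d <- runif(5, 0, 10)
  expect_equal(gaussian_weight(76.4 + d), gaussian_weight(76.4 - d))
  expect_error(gaussian_weight(70, sigma = 0))
})

test_that("hidden sizes follow the ceil(2/3 nx + ny) rule at the requested depth", {
  expect_equal(hidden_sizes(42, 1, 25), rep(29L, 25))
  expect_equal(hidden_sizes(3, 1, 1), 3L)
  expect_length(hidden_sizes(42, 1, 25), 25)
})

test_that("dropout keeps round(n (1 - rate)) active neurons", {
  expect_equal(dropout_active_count(56, 0.2), 45L)
  expect_equal(dropout_active_count(10, 0), 10L)
  expect_equal(dropout_active_count(10, 0.2), 8L)
  expect_equal(dropout_active_count(1, 0.9), 1L)
  expect_error(dropout_active_count(10, 1), "rate")
  expect_error(dropout_active_count(10, -0.1), "rate")
})

test_that("confusion counts threshold both series at mu and always sum to n", {
  expect_equal(confusion_counts(80, 82), c(TP = 1L, TN = 0L, FP = 0L, FN = 0L))
  expect_equal(confusion_counts(70, 72)[["TN"]], 1L)
  expect_equal(confusion_counts(80, 70)[["FP"]], 1L)
  expect_equal(confusion_counts(70, 80)[["FN"]], 1L)
  expect_error(confusion_counts(c(80, 70), 80), "equal length")
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(1:60, 1)
    pred <- runif(n, 50, 100)
    act <- runif(n, 50, 100)
    for (rule in c("threshold", "band")) {
      cm <- confusion_counts(pred, act, rule = rule)
      expect_equal(sum(cm), n)
    }
  }
})

test_that("F1 is the harmonic mean of precision and recall with safe zeros", {
  m <- f1_metrics(10, 0, 0)
  expect_equal(m$F1, 1)
  expect_equal(f1_metrics(0, 5, 5)$F1, 0)
  # fixed points and published-style operating points
  p <- 0.72
  tp <- 72; fp <- round(tp / p - tp)
  m <- f1_metrics(tp, fp, fp)
  expect_equal(m$precision, m$recall)
  expect_equal(m$F1, m$precision, tolerance = 1e-12)
  set.seed(8)
  for (trial in 1:100) {
    cm <- sample(0:30, 3, replace = TRUE)
    m <- f1_metrics(cm[1], cm[2], cm[3])
    expect_true(m$F1 >= 0 && m$F1 <= 1)
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(m$F1, 2 / (1 / m$precision + 1 / m$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("MAPE matches its definition and rejects zero expectations", {
  expect_equal(mape(c(80, 90), c(80, 90)), 0)
  expect_equal(mape(100, 90), 0.1)
  expect_equal(mape(c(50, 100), c(45, 110)), 0.1)
  expect_error(mape(c(0, 1), c(1, 1)), "zero")
  expect_error(mape(1:3, 1:2), "equal length")
})

test_that("drop-one selection ranks a copied target first and noise last", {
  set.seed(5)
  X <- matrix(rnorm(100 * 4), 100, 4)
  colnames(X) <- paste0("f", 1:4)
  sel <- drop_one_selection(X, X[, 1], seed = 5)
  expect_equal(sel$ranking[1], "f1")
  # pure-noise feature ranks below all signal features in most seeded trials
  last_is_noise <- 0
  for (s in 1:40) {
    set.seed(s)
    F <- matrix(rnorm(60 * 4), 60, 4)
    colnames(F) <- c("s1", "s2", "s3", "noise")
    y <- F[, 1] * 2 + F[, 2] * 1.5 + F[, 3] + rnorm(60, 0, 0.5)
    sel <- drop_one_selection(F, y, seed = s)
    if (tail(sel$ranking, 1) == "noise") last_is_noise <- last_is_noise + 1
  }
  expect_gt(last_is_noise, 30)
})

test_that("the k-scan recovers a small subset on sparse generative data", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    F <- matrix(rnorm(80 * 10), 80, 10)
    colnames(F) <- paste0("f", 1:10)
    y <- F[, 1] * 3 + F[, 2] * 2 + F[, 3] + rnorm(80, 0, 0.3)
    sel <- drop_one_selection(F, y, seed = s)
    if (sel$k <= 5 && min(sel$cv_mae) <= sel$cv_mae[10]) hits <- hits + 1
  }
  expect_gt(hits, 10)
})

test_that("cross-validation is deterministic and learns a constant mapping", {
  X <- matrix(rep(rnorm(5, 0, 1), each = 30), 30, 5)
  cfg <- eva_config(depth = 3, seed = 1, dropout_rate = 0)
  cv <- train_predict_cv(X, rep(75, 30), cfg, K = 2)
  expect_lt(cv$mape, 0.05)
  cv2 <- train_predict_cv(X, rep(75, 30), cfg, K = 2)
  expect_identical(cv, cv2)
  expect_equal(length(cv$fold_mape), 2)
  expect_error(train_predict_cv(X, rep(75, 30), cfg, K = 31), "exceeds")
})

test_that("the MLP beats the train-mean predictor on a linear synthetic cohort", {
  wins <- matrix(0, 2, 10)
  for (s in 1:10) {
    set.seed(s)
    n <- 200
    F <- matrix(rnorm(n * 10), n, 10)
    g <- as.numeric(75 + F %*% c(3, 2, 1, rep(0, 7)) + rnorm(n, 0, 1))
    cfg <- eva_config(depth = 3, seed = s)
    ho <- train_predict_holdout(F, g, cfg)
    test_idx <- ho$predictions$index
    mean_pred <- mean(g[-test_idx])
    wins[, s] <- c(ho$mape, mape(g[test_idx], rep(mean_pred, length(test_idx))))
  }
  expect_lt(median(wins[1, ]), median(wins[2, ]))
})

test_that("deeper configurations still produce finite seeded-deterministic fits", {
  set.seed(2)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- 75 + X[, 1] * 4 + rnorm(60, 0, 1)
  cfg <- eva_config(depth = 25, max_iter = 30, seed = 4)
  f1 <- mlp_fit(X, y, cfg)
  f2 <- mlp_fit(X, y, cfg)
  p <- predict(f1, X)
  expect_true(all(is.finite(p)))
  expect_identical(predict(f1, X), predict(f2, X))
})
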