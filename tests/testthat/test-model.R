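test_that("min-max normalization maps columns to [0,1] and replays on new data", {
  tab <- data.frame(x = c(0, 5, 10), y = c(7, 7, 7), label = c(0, 1, 0))
  out <- normalize_features(tab)
  expect_equal(out$x, c(0, 0.5, 1))
  expect_equal(out$y, c(0, 0, 0))        # constant column, no division by 0
  params <- attr(out, "norm_params")
  replay <- apply_normalization(params, data.frame(x = 20, y = 7))
  expect_equal(unname(replay[1, "x"]), 2)  # outside [0,1] is allowed
})

test_that("adaboost drives training error to zero on separable data", {
  set.seed(10)
  x <- c(stats::runif(50, -2, -0.1), stats::runif(50, 0.1, 2))
  y <- as.integer(x >= 0)
  tab <- data.frame(x = x, label = y)
  m <- fit_adaboost(tab, seed = 1)
  expect_equal(m$train_error[length(m$train_error)], 0)
  # staged training error is non-increasing for separable data
  expect_true(all(diff(m$train_error) <= 1e-12))
  # determinism: identical alphas across runs
  m2 <- fit_adaboost(tab, seed = 1)
  expect_identical(m$alpha, m2$alpha)
  # errors on degenerate input
  expect_error(fit_adaboost(data.frame(x = 1:5, label = 1)), "both classes")
  expect_error(fit_adaboost(data.frame(x = c(1, NA), label = c(0, 1))),
               "missing")
})

test_that("prediction is sign of the weighted sum with ties negative", {
  set.seed(11)
  tab <- data.frame(x = c(-2, -1, 1, 2), label = c(0, 0, 1, 1))
  m <- fit_adaboost(tab, seed = 1, normalize = FALSE)
  pr <- predict(m, data.frame(x = c(-3, 3)))
  expect_equal(pr$label, c(0L, 1L))
  expect_equal(pr$label, as.integer(pr$score > 0))
  # zero rows in, zero rows out
  expect_equal(nrow(predict(m, tab[0, ])), 0)
  # a model forced to score exactly 0 predicts negative
  fake <- m; fake$alpha <- 0
  pr0 <- predict(fake, data.frame(x = 5))
  expect_equal(pr0$score, 0); expect_equal(pr0$label, 0L)
})

test_that("weak learners respect the maximum split budget", {
  set.seed(12)
  n <- 300
  tab <- data.frame(matrix(stats::rnorm(n * 5), n, 5))
  tab$label <- as.integer(tab$X1 + tab$X2 * tab$X3 > 0)
  m <- fit_adaboost(tab, max_splits = 20, seed = 1)
  for (lrn in m$learners) {
    expect_lte(sum(lrn$frame$var != "<leaf>"), 20)
  }
  stump <- fit_stump_baseline(tab, seed = 1)
  expect_lte(sum(stump$learners[[1]]$frame$var != "<leaf>"), 1)
})

test_that("closed-form metric values are reproduced", {
  # TP=3, FP=1, FN=2, TN=4
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  met <- cti_metrics(pred, truth)
  expect_equal(met$precision, 0.75)
  expect_equal(met$recall, 0.6)
  expect_equal(met$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-9)
  expect_equal(met$f1, 0.6667, tolerance = 1e-4)
  # MCC extremes
  expect_equal(cti_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))$mcc, 1)
  expect_equal(cti_metrics(c(1, 1, 0, 0), c(0, 0, 1, 1))$mcc, -1)
  # degenerate denominators are guarded
  expect_equal(cti_metrics(c(0, 0), c(0, 0))$mcc, 0)
  expect_equal(cti_metrics(c(0, 0), c(1, 0))$precision, 0)
})

test_that("rank AUC reproduces the closed-form example and pair counting", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  set.seed(13)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_identical(rank_auc(s, y), pair_count_auc(s, y))
  }
  expect_true(is.na(rank_auc(1:3, c(1, 1, 1))))
})

test_that("MCC flips sign under class-label swap", {
  set.seed(14)
  for (i in 1:20) {
    pred <- sample(0:1, 30, replace = TRUE)
    truth <- sample(0:1, 30, replace = TRUE)
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    m1 <- cti_metrics(pred, truth)$mcc
    m2 <- cti_metrics(1 - pred, truth)$mcc
    expect_equal(m1, -m2, tolerance = 1e-12)
  }
})

test_that("cross-validation partitions rows and ignores row order", {
  set.seed(15)
  n <- 100
  tab <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  tab$label <- as.integer(tab$x1 > 0)
  cv <- kfold_cv(tab, k = 10, seed = 7, n_learners = 3)
  expect_equal(sum(cv$fold_sizes), n)
  expect_equal(length(cv$fold_sizes), 10)
  # stratification keeps folds within one row of each other per class
  expect_true(all(abs(cv$fold_sizes - 10) <= 1))
  # permuting rows leaves the aggregate metrics unchanged
  perm <- sample(n)
  cv2 <- kfold_cv(tab[perm, ], k = 10, seed = 7, n_learners = 3)
  expect_equal(cv$aggregate$counts, cv2$aggregate$counts)
  expect_equal(cv$aggregate$auc, cv2$aggregate$auc)
})

test_that("the ensemble recovers a planted labelling rule and beats the stump", {
  set.seed(16)
  n <- 600
  X <- data.frame(bit = sample(0:1, n, TRUE, prob = c(0.3, 0.7)),
                  gravy = stats::rnorm(n),
                  noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  y <- as.integer(X$bit == 1 & X$gravy > 0)
  tr <- seq_len(400)
  m <- fit_adaboost(X[tr, ], y[tr], seed = 2)
  pr <- predict(m, X[-tr, ])
  auc_boost <- rank_auc(pr$score, y[-tr])
  expect_gte(auc_boost, 0.95)
  stump <- fit_stump_baseline(X[tr, ], y[tr], seed = 2)
  auc_stump <- rank_auc(predict(stump, X[-tr, ])$score, y[-tr])
  expect_gte(auc_boost, auc_stump - 1e-9)
})

test_that("target screen reports percent of compounds predicted positive", {
  ds <- gen_cti_dataset(sim_spec(seed = 21, n_pairs = 400))
  ft <- assemble_feature_table(ds$pairs, ds$compounds, ds$sequences, "MF")
  m <- fit_adaboost(ft, seed = 3)
  scr <- screen_targets(m, ds$compounds, ds$sequences, "MF")
  expect_true(all(scr$success_rate >= 0 & scr$success_rate <= 100))
  expect_equal(nrow(scr), length(unique(ds$sequences$target_id)))
  # the planted rule makes low-GRAVY targets all-negative
  gr <- vapply(ds$sequences$sequence[ds$sequences$variant == "full"],
               gravy, numeric(1))
  low <- ds$sequences$target_id[ds$sequences$variant == "full"][
    gr < ds$truth$gravy_median]
  expect_true(all(scr$success_rate[scr$target_id %in% low] <= 20))
})
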