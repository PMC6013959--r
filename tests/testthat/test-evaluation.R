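test_that("the ROC sweep matches brute-force threshold enumeration", {
  s <- c(0.1, 0.4, 0.35, 0.8); l <- c(0, 0, 1, 1)
  curve <- roc_curve(s, l)
  # brute force over every candidate threshold
  for (i in seq_len(nrow(curve))) {
    th <- curve$threshold[i]
    expect_equal(curve$tp[i], sum(s >= th & l == 1))
    expect_equal(curve$fp[i], sum(s >= th & l == 0))
    expect_equal(curve$pp[i], sum(s >= th))
  }
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(tail(curve$fpr, 1), 1); expect_equal(tail(curve$tpr, 1), 1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
  # degenerate cases
  expect_equal(nrow(roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))), 2)
  perfect <- roc_curve(l, l)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_error(roc_curve(s, c(1, 1, 1, 1)), "both classes")
  expect_error(roc_curve(c(0.1, NA, 0.3, 0.2), l), "finite")
})

test_that("AUC equals pairwise concordance on exhaustive small instances", {
  expect_equal(auc(roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))), 0.75)
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties sometimes
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    got <- auc(roc_curve(s, l))
    expect_equal(got, oracle_auc(s, l), tolerance = 1e-12)
    # label-swap symmetry
    expect_equal(auc(roc_curve(s, 1 - l)), 1 - got, tolerance = 1e-12)
    # independent reference implementation
    expect_equal(got,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("the operating point minimizes the corner distance", {
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  l <- c(1, 1, 0, 1, 0)
  curve <- roc_curve(s, l)
  opt <- optimal_threshold(curve)
  expect_equal(opt$threshold, oracle_optimal(curve))
  # hand-built curve: middle point at distance sqrt(0.04 + 0.01)
  toy <- data.frame(threshold = c(Inf, 0.5, 0), fpr = c(0, 0.2, 1),
                    tpr = c(0, 0.9, 1))
  opt2 <- optimal_threshold(toy)
  expect_equal(opt2$threshold, 0.5)
  expect_equal(opt2$distance, sqrt(0.05), tolerance = 1e-12)
  # a curve through the perfect corner picks it at distance 0
  pc <- roc_curve(c(0.9, 0.8, 0.1), c(1, 1, 0))
  optp <- optimal_threshold(pc)
  expect_equal(optp$distance, 0)
  # diagonal-only curve: tie handled and reported
  flat <- roc_curve(rep(0.5, 4), c(1, 0, 1, 0))
  expect_message(optimal_threshold(flat), "tie")
  set.seed(72)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    s <- runif(n); l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    curve <- roc_curve(s, l)
    got <- suppressMessages(optimal_threshold(curve))
    d <- sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
    expect_equal(got$distance, min(d), tolerance = 1e-12)
  }
})

test_that("confusion metrics follow the standard definitions", {
  # TP=3, FP=1, FN=1, TN=5
  scores <- c(rep(0.9, 3), 0.9, rep(0.1, 1), rep(0.1, 5))
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$recall, 0.75)
  expect_equal(cm$f1, 0.75)
  expect_equal(cm$accuracy, 0.8)
  # perfect classifier at its operating point
  perf <- confusion_metrics(labels, labels, optimal_threshold(
    roc_curve(labels, labels))$threshold)
  expect_equal(unlist(perf[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # all-negative prediction on balanced labels
  bal <- rep(c(1, 0), 5)
  expect_warning(cm0 <- confusion_metrics(rep(0.1, 10), bal, 0.5),
                 "no predicted positives")
  expect_equal(cm0$accuracy, 0.5)
  expect_equal(cm0$recall, 0)
  expect_equal(cm0$precision, 0)
})

test_that("cross-validation partitions rows, stratifies, and is seeded", {
  set.seed(81)
  y <- rbinom(100, 1, 0.3)
  folds <- readmitnet:::stratified_folds(y, 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 100)
  expect_true(all(table(folds, y) > 0))
  expect_identical(folds, readmitnet:::stratified_folds(y, 5, seed = 3))
  # constant-score model scores AUC 0.5
  const_factory <- function(x, y, seed) list(predict = function(n) rep(0.5, nrow(n)))
  x <- matrix(runif(200), 100)
  rep_out <- suppressWarnings(suppressMessages(
    kfold_cv(const_factory, x, y, k = 5, seed = 3, preprocess = FALSE)))
  expect_equal(unname(rep_out$mean[["auc"]]), 0.5)
  # bookkeeping identity: mean/sd recomputed from the fold table
  expect_equal(unname(rep_out$mean[["accuracy"]]),
               mean(rep_out$folds$accuracy))
  expect_equal(unname(rep_out$sd[["accuracy"]]), sd(rep_out$folds$accuracy))
})

test_that("cross-validated logistic AUC approaches the generator's own", {
  set.seed(82)
  n <- 4000
  x <- cbind(a = runif(n), b = runif(n), c = rbinom(n, 1, 0.5))
  eta <- -2 + 2.2 * x[, "a"] - 1.8 * x[, "b"] + 1.1 * x[, "c"]
  y <- rbinom(n, 1, plogis(eta))
  # oracle: population AUC of the true linear predictor (independent
  # reference implementation on a large sample)
  bayes <- as.numeric(pROC::auc(pROC::roc(y, eta, quiet = TRUE,
                                          direction = "<")))
  rep_out <- kfold_cv(logreg_factory(lambda = 1e-5), x, y, k = 10, seed = 4,
                      preprocess = FALSE)
  expect_lt(abs(rep_out$mean[["auc"]] - bayes), 0.03)
})

test_that("no leakage: the scaler and filter are fit on training folds", {
  # a test-fold value outside the training range must be clipped, proving
  # the scaler saw only training rows
  probe_env <- new.env()
  probe_factory <- function(x, y, seed) {
    probe_env$train_max <- max(x)
    list(predict = function(newx) {
      probe_env$test_max <- max(newx)
      rowMeans(newx)
    })
  }
  df <- data.frame(v = c(seq_len(99), 1e6), w = runif(100))
  y <- rep(c(0, 1), 50)
  suppressWarnings(suppressMessages(
    kfold_cv(probe_factory, df, y, k = 5, seed = 9, preprocess = TRUE)))
  expect_lte(probe_env$train_max, 1)
  expect_lte(probe_env$test_max, 1)
  # KL filter fit per fold keeps the model matrix consistent across folds
  rep2 <- suppressWarnings(suppressMessages(
    kfold_cv(logreg_factory(), df, y, k = 5, seed = 9, preprocess = TRUE,
             kl_filter = TRUE)))
  expect_equal(nrow(rep2$folds), 5)
})

test_that("random-search tuning returns the argmax of its trials", {
  sep <- make_separable(150, seed = 20)
  space <- list(lambda = list(type = "choice",
                              values = list(1e-6, 1e-2, 10)))
  maker <- function(cand) logreg_factory(lambda = cand$lambda)
  tuned <- tune_hyperparams(space, maker, sep$x, sep$y, n_iter = 6,
                            subsample = 0.5, k = 3, seed = 2,
                            preprocess = FALSE)
  expect_equal(nrow(tuned$trials), 6)
  expect_equal(tuned$best_auc, max(tuned$trials$auc))
  # a heavy ridge penalty cannot win against the light ones
  expect_lt(tuned$best$lambda, 10)
  # single-point space returns that point
  one <- tune_hyperparams(list(lambda = list(type = "choice",
                                             values = list(0.01))),
                          maker, sep$x, sep$y, n_iter = 1, subsample = 0.5,
                          k = 3, seed = 2, preprocess = FALSE)
  expect_equal(one$best$lambda, 0.01)
  expect_error(tune_hyperparams(list(), maker, sep$x, sep$y), "empty")
})
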