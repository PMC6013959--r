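# Threshold-sweep evaluation: ROC curves with raw counts at every threshold,
# trapezoidal AUC, the distance-to-corner operating point, confusion
# metrics, stratified k-fold cross-validation with leakage-free
# preprocessing, and a seeded random-search tuning harness.

#' ROC curve by serial threshold sweep
#'
#' Sweeps the classification threshold over every distinct score (ties enter
#' together) and records, per threshold, the false- and true-positive rates
#' together with the raw true-positive, false-positive and
#' predicted-positive counts; the counts let downstream consumers (e.g. the
#' cost-savings sweep) work in absolute patients without re-scoring. The
#' all-negative endpoint (0, 0) and the all-positive endpoint (1, 1) are
#' always present. Prediction at threshold `t` is `score >= t`.
#'
#' @param scores Finite numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return Data frame of class `roc_points` with columns `threshold`, `fpr`,
#'   `tpr`, `tp`, `fp`, `pp`, and attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("labels must contain both classes", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp_cum <- cumsum(y)
  fp_cum <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  thr <- s[last]; tp <- tp_cum[last]; fp <- fp_cum[last]
  out <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    tp = c(0L, tp),
    fp = c(0L, fp),
    pp = c(0L, tp + fp)
  )
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  class(out) <- c("roc_points", "data.frame")
  out
}

# AUC directly from scores (used in training histories)
auc_scores <- function(scores, labels) {
  auc(roc_curve(scores, labels))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the false-positive rate; equal to the probability
#' that a random positive outscores a random negative, with half credit for
#' ties.
#'
#' @param curve A `roc_points` object from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  dx <- diff(curve$fpr)
  sum(dx * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Operating-point threshold: minimal distance to the ideal corner
#'
#' Returns the threshold of the curve point minimizing
#' `sqrt(FP^2 + (1 - TP)^2)`, the Euclidean distance to the perfect
#' classifier corner (FP = 0, TP = 1). Ties are broken toward higher TP
#' rate, then lower threshold, and reported via a message.
#'
#' @param curve A `roc_points` object.
#' @return A list: `threshold`, `fpr`, `tpr`, `distance`, `index`.
#' @export
optimal_threshold <- function(curve) {
  d <- sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
  best <- which(d == min(d))
  if (length(best) > 1) {
    message("operating-point tie among ", length(best),
            " points; picking highest TP rate then lowest threshold")
    best <- best[order(-curve$tpr[best], curve$threshold[best])]
  }
  i <- best[1]
  list(threshold = curve$threshold[i], fpr = curve$fpr[i],
       tpr = curve$tpr[i], distance = d[i], index = i)
}

#' Confusion metrics at a threshold
#'
#' Standard accuracy, precision, recall and F1 with prediction
#' `score >= threshold`. When nothing is predicted positive, precision is
#' reported as 0 with a warning (and F1 as 0).
#'
#' @param scores,labels As in [roc_curve()].
#' @param threshold Decision threshold.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, plus the
#'   2x2 counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp == 0) {
    warning("no predicted positives; precision reported as 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}

stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(table(fold, labels) == 0)) {
    stop("a class is absent from some fold; reduce k", call. = FALSE)
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into k stratified folds (both classes present in every
#' fold), and for each fold fits all preprocessing *and* the model on the
#' remaining k-1 folds only: when `x` is a raw (unscaled) feature table the
#' 1-of-K encoder and min-max scaler are fit on the training folds and
#' applied with clipping to the held-out fold, and the total-KL-divergence
#' filter is likewise fit on the training folds. The held-out fold is then
#' scored, its ROC curve built, the operating point chosen on that curve,
#' and the four confusion metrics computed there.
#'
#' @param factory A model factory function `f(x, y, seed)` returning an
#'   object with `$predict(newx)` (see [model_factories]).
#' @param x Raw feature data frame (preprocessing per fold) or an already
#'   scaled numeric matrix (set `preprocess = FALSE`).
#' @param y Binary outcome vector.
#' @param k Number of folds (default 10).
#' @param seed Seed controlling fold assignment and per-fold model seeds.
#' @param preprocess Fit encoder/scaler per training fold. Defaults to
#'   `TRUE` for data frames and is forced off for plain matrices already in
#'   `[0, 1]` when set to `FALSE`.
#' @param kl_filter Apply the total-KL-divergence variable filter, fit per
#'   training fold.
#' @return A list of class `eval_report`: `folds` (per-fold metrics and
#'   chosen threshold), `mean`, `sd`, `curves` (per-fold `roc_points`,
#'   which [savings_sweep()] can consume).
#' @export
kfold_cv <- function(factory, x, y, k = 10, seed = 1L, preprocess = TRUE,
                     kl_filter = FALSE) {
  y <- as.integer(y)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (length(y) < k) stop("need at least k samples", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  rows <- list()
  curves <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (preprocess && is.data.frame(x)) {
      enc <- fit_encoder(x[tr, , drop = FALSE])
      x_tr <- apply_encoder(enc, x[tr, , drop = FALSE])
      x_te <- apply_encoder(enc, x[te, , drop = FALSE], clip = TRUE)
    } else {
      x_tr <- as.matrix(x)[tr, , drop = FALSE]
      x_te <- as.matrix(x)[te, , drop = FALSE]
    }
    if (kl_filter) {
      kl <- total_kl_divergence(x_tr, y[tr])
      keep <- kl$keep_mask
      if (!any(keep)) keep[] <- TRUE
      x_tr <- x_tr[, keep, drop = FALSE]
      x_te <- x_te[, keep, drop = FALSE]
    }
    fit <- factory(x_tr, y[tr], seed = seed + f)
    scores <- fit$predict(x_te)
    curve <- roc_curve(scores, y[te])
    opt <- optimal_threshold(curve)
    cm <- confusion_metrics(scores, y[te], opt$threshold)
    curves[[f]] <- curve
    rows[[f]] <- data.frame(fold = f, auc = auc(curve),
                            threshold = opt$threshold,
                            accuracy = cm$accuracy, precision = cm$precision,
                            recall = cm$recall, f1 = cm$f1)
  }
  folds <- do.call(rbind, rows)
  metrics <- c("auc", "accuracy", "precision", "recall", "f1")
  structure(list(
    folds = folds,
    mean = colMeans(folds[metrics]),
    sd = apply(folds[metrics], 2, stats::sd),
    curves = curves,
    k = k, seed = seed
  ), class = "eval_report")
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat(x$k, "-fold cross-validation (mean ± sd):\n", sep = "")
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.3f ± %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

sample_from_space <- function(space) {
  lapply(space, function(sp) {
    switch(sp$type,
      uniform = stats::runif(1, sp$low, sp$high),
      loguniform = exp(stats::runif(1, sp$low, sp$high)),
      int = sample(seq(sp$low, sp$high), 1L),
      choice = sp$values[[sample.int(length(sp$values), 1L)]],
      stop("unknown search-space type: ", sp$type, call. = FALSE)
    )
  })
}

#' Hyper-parameter search on a random data subset
#'
#' Draws one random subset of the data (default 10%), then runs `n_iter`
#' iterations of seeded random search over the supplied space; each
#' candidate is scored by its mean k-fold cross-validated AUC on the subset
#' and the argmax is returned. (Sequential model-based search such as the
#' tree-structured Parzen estimator would slot in here; this harness uses
#' seeded random draws from the same search distributions.)
#'
#' @param space Named list of search distributions; each element is a list
#'   with `type` (`"uniform"`, `"loguniform"` with log-scale bounds,
#'   `"int"`, `"choice"`) and `low`/`high` or `values`.
#' @param factory_maker Function taking a named list of sampled
#'   hyper-parameters and returning a model factory for [kfold_cv()].
#' @param x,y Full data (matrix or data frame + labels).
#' @param n_iter Number of search iterations (default 100).
#' @param subsample Fraction of the data drawn once for tuning (default
#'   0.10).
#' @param k Folds per evaluation (default 10).
#' @param seed Seed for the subset draw and all candidate draws.
#' @param ... Passed on to [kfold_cv()] (e.g. `preprocess`).
#' @return A list: `best` (hyper-parameter list), `best_auc`, `trials`
#'   (data frame with one row per iteration).
#' @export
tune_hyperparams <- function(space, factory_maker, x, y, n_iter = 100,
                             subsample = 0.10, k = 10, seed = 1L, ...) {
  if (length(space) == 0) stop("empty search space", call. = FALSE)
  n <- length(y)
  idx <- with_seed(seed, sample.int(n, max(ceiling(subsample * n), 2 * k)))
  xs <- if (is.data.frame(x)) x[idx, , drop = FALSE] else
    as.matrix(x)[idx, , drop = FALSE]
  ys <- y[idx]
  trials <- vector("list", n_iter)
  configs <- vector("list", n_iter)
  best_auc <- -Inf; best <- NULL
  for (i in seq_len(n_iter)) {
    cand <- with_seed(seed + i, sample_from_space(space))
    rep_i <- kfold_cv(factory_maker(cand), xs, ys, k = k, seed = seed, ...)
    configs[[i]] <- cand
    trials[[i]] <- data.frame(iter = i, auc = rep_i$mean[["auc"]])
    if (rep_i$mean[["auc"]] > best_auc) {
      best_auc <- rep_i$mean[["auc"]]
      best <- cand
    }
  }
  trials <- do.call(rbind, trials)
  trials$config <- I(configs)
  list(best = best, best_auc = best_auc, trials = trials)
}
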