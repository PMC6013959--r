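# Penalized logistic regression and gradient-boosting baselines, plus the
# uniform model-factory interface used by the cross-validation harness. The
# logistic fit delegates to glmnet and boosting to xgboost; both are
# comparison models, not the architecture this package contributes.

#' Penalized logistic regression baseline
#'
#' Fits an L1- or L2-penalized logistic regression and reports feature
#' importance as the absolute value of the fitted weight coefficients,
#' ranked in descending magnitude.
#'
#' @param x Feature matrix in `[0, 1]`.
#' @param y Binary outcome vector (both classes required).
#' @param penalty `"l2"` (ridge, default) or `"l1"` (lasso).
#' @param lambda Penalty strength; default `6.931e-6` (a tuned value for
#'   this problem class; the usual search is log-uniform over
#'   `[exp(-15), 1]`).
#' @return A list of class `logreg_fit`: `weights` (named, incl.
#'   `(Intercept)`), `importance` (data frame ranked by `|weight|`),
#'   `predict` (function of a new matrix returning probabilities).
#' @export
train_logreg <- function(x, y, penalty = c("l2", "l1"), lambda = 6.931e-6) {
  penalty <- match.arg(penalty)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("labels are degenerate (single class)", call. = FALSE)
  }
  x <- as.matrix(x)
  # glmnet requires >= 2 columns; pad a constant that carries no weight
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, .pad = 0)
  fit <- glmnet::glmnet(x, y, family = "binomial",
                        alpha = if (penalty == "l1") 1 else 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[names(beta) != ".pad"]
  imp <- data.frame(variable = names(beta), weight = beta,
                    importance = abs(beta), stringsAsFactors = FALSE)
  imp <- imp[order(-imp$importance), , drop = FALSE]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(
    weights = c("(Intercept)" = fit$a0, beta),
    importance = imp,
    lambda = lambda, penalty = penalty,
    predict = function(newx) {
      newx <- as.matrix(newx)
      if (padded) newx <- cbind(newx, .pad = 0)
      as.numeric(stats::predict(fit, newx, type = "response"))
    }
  ), class = "logreg_fit")
}

#' Gradient-boosting adapter
#'
#' Thin wrapper around xgboost for comparison runs. Hyper-parameters default
#' to mid-range values of the usual tuning box (depth 3-25, 100-1000 trees,
#' log-uniform learning rate). Returns `NULL` with a warning when xgboost is
#' not installed, so comparisons can proceed without it.
#'
#' @param x,y As in [train_logreg()].
#' @param params Named list overriding `max_depth`, `eta`, `nrounds`,
#'   `min_child_weight`, `gamma`, `alpha`, `lambda`, `subsample`,
#'   `colsample_bytree`.
#' @param seed Seed passed to xgboost.
#' @return A list of class `gbm_fit` with a `predict` function, or `NULL`.
#' @export
train_gbm <- function(x, y, params = list(), seed = 1L) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    warning("xgboost is not installed; skipping the gradient-boosting model")
    return(NULL)
  }
  defaults <- list(max_depth = 5, eta = 0.05, nrounds = 200,
                   min_child_weight = 1, gamma = 0, alpha = 0, lambda = 1,
                   subsample = 0.8, colsample_bytree = 0.8)
  p <- utils::modifyList(defaults, params)
  nrounds <- p$nrounds; p$nrounds <- NULL
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = as.numeric(y))
  booster <- xgboost::xgb.train(
    params = c(p, list(objective = "binary:logistic", nthread = 1,
                       seed = seed)),
    data = dtrain, nrounds = nrounds, verbose = 0)
  structure(list(
    booster = booster, params = p, nrounds = nrounds,
    predict = function(newx) {
      as.numeric(stats::predict(booster, xgboost::xgb.DMatrix(as.matrix(newx))))
    }
  ), class = "gbm_fit")
}

#' Model factories for the cross-validation harness
#'
#' Each factory returns a function `f(x, y, seed)` that fits the model and
#' returns an object with a `$predict(newx)` element producing probability
#' scores, so [kfold_cv()] can treat every model interchangeably.
#'
#' @param config Model configuration ([duns_config()] / [maxout_config()]),
#'   or tuning arguments for the simpler models.
#' @return A factory function.
#' @name model_factories
NULL

#' @rdname model_factories
#' @export
duns_factory <- function(config = duns_config()) {
  function(x, y, seed = config$seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    fit <- train_duns(init_duns(cfg, ncol(x)), x, y, cfg)
    fit$predict <- function(newx) duns_forward(fit$params, newx)$prob
    fit
  }
}

#' @rdname model_factories
#' @export
maxout_factory <- function(config = maxout_config()) {
  function(x, y, seed = config$seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    fit <- train_maxout(init_maxout(cfg, ncol(x)), x, y, cfg)
    fit$predict <- function(newx) maxout_forward(fit$params, newx)$prob
    fit
  }
}

#' @rdname model_factories
#' @param penalty,lambda Passed to [train_logreg()].
#' @export
logreg_factory <- function(penalty = "l2", lambda = 6.931e-6) {
  function(x, y, seed = 1L) train_logreg(x, y, penalty, lambda)
}

#' @rdname model_factories
#' @param params Passed to [train_gbm()].
#' @export
gbm_factory <- function(params = list()) {
  function(x, y, seed = 1L) train_gbm(x, y, params, seed)
}
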