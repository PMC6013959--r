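# Telemonitoring cost-savings model.
#
# Net savings from readmission reduction
#   = total saved readmission cost - total program cost
#   = readmission cost per patient x number of true positives x response rate
#   - program cost per patient x number of predicted positives
#
# swept along an ROC curve's raw counts; the maximum over thresholds and the
# accuracy at that operating point summarize a model's economic value.

#' Cost parameters for the savings model
#'
#' Defaults are the published per-patient figures for a heart-failure
#' telemonitoring program: $9655 saved per prevented readmission, $1500
#' program cost per enrollee, and a 50% chance that enrolling a would-be
#' readmission prevents it.
#'
#' @param readmission_cost_per_patient Cost of one readmission (currency).
#' @param program_cost_per_patient Program cost per enrolled patient.
#' @param response_rate Probability the program prevents a readmission for a
#'   true positive.
#' @return A list of class `cost_params`.
#' @export
cost_params <- function(readmission_cost_per_patient = 9655,
                        program_cost_per_patient = 1500,
                        response_rate = 0.5) {
  if (readmission_cost_per_patient < 0 || program_cost_per_patient < 0) {
    stop("costs must be nonnegative", call. = FALSE)
  }
  check_probability(response_rate, "response_rate")
  structure(list(readmission_cost_per_patient = readmission_cost_per_patient,
                 program_cost_per_patient = program_cost_per_patient,
                 response_rate = response_rate),
            class = "cost_params")
}

#' Net savings from readmission reduction
#'
#' Exact evaluation of the savings equation at given counts; may be
#' negative when program costs outweigh prevented readmissions.
#'
#' @param tp_count Number of true positives (readmissions correctly flagged
#'   for enrollment).
#' @param predicted_positive_count Number of admissions flagged for
#'   enrollment; must be `>= tp_count`.
#' @param params A [cost_params()] object.
#' @return Net savings in currency units.
#' @examples
#' net_savings(100, 200, cost_params())  # 182750
#' @export
net_savings <- function(tp_count, predicted_positive_count,
                        params = cost_params()) {
  if (any(tp_count > predicted_positive_count)) {
    stop("tp_count cannot exceed predicted_positive_count", call. = FALSE)
  }
  if (any(tp_count < 0)) stop("counts must be nonnegative", call. = FALSE)
  params$readmission_cost_per_patient * tp_count * params$response_rate -
    params$program_cost_per_patient * predicted_positive_count
}

#' Sweep net savings along an ROC curve
#'
#' Evaluates the savings equation at every curve point using the raw
#' true-positive and predicted-positive counts carried by the curve, and
#' returns the maximizing threshold with the classification accuracy at that
#' point. Because the all-negative point (zero enrollees, zero savings) is
#' always on the curve, the maximum is never below 0. Ties in the argmax are
#' broken toward the smaller program (fewer predicted positives).
#'
#' @param curve A `roc_points` object from [roc_curve()] (must carry
#'   counts).
#' @param params A [cost_params()] object.
#' @return A list of class `cost_curve`: `sweep` (data frame threshold, tp,
#'   pp, savings, accuracy) and `best` (threshold, savings, accuracy, tp,
#'   pp).
#' @export
savings_sweep <- function(curve, params = cost_params()) {
  if (!all(c("tp", "pp") %in% names(curve))) {
    stop("curve does not carry raw counts; rebuild it with roc_curve()",
         call. = FALSE)
  }
  n_pos <- attr(curve, "n_pos"); n_neg <- attr(curve, "n_neg")
  sav <- net_savings(curve$tp, curve$pp, params)
  tn <- n_neg - curve$fp
  accuracy <- (curve$tp + tn) / (n_pos + n_neg)
  best <- which(sav == max(sav))
  if (length(best) > 1) best <- best[order(curve$pp[best])]
  i <- best[1]
  structure(list(
    sweep = data.frame(threshold = curve$threshold, tp = curve$tp,
                       pp = curve$pp, savings = sav, accuracy = accuracy),
    best = list(threshold = curve$threshold[i], savings = sav[i],
                accuracy = accuracy[i], tp = curve$tp[i], pp = curve$pp[i])
  ), class = "cost_curve")
}

#' Per-fold maximum savings summary
#'
#' Applies [savings_sweep()] to each fold's held-out ROC curve from an
#' [kfold_cv()] report and summarizes the per-fold maxima as mean ± sd of
#' the maximum net savings and of the accuracy at the corresponding
#' threshold.
#'
#' @param report An `eval_report` from [kfold_cv()].
#' @param params A [cost_params()] object.
#' @return A list: `folds` (per-fold best threshold/savings/accuracy),
#'   `mean_savings`, `sd_savings`, `mean_accuracy`, `sd_accuracy`.
#' @export
savings_summary <- function(report, params = cost_params()) {
  rows <- lapply(seq_along(report$curves), function(f) {
    b <- savings_sweep(report$curves[[f]], params)$best
    data.frame(fold = f, threshold = b$threshold, savings = b$savings,
               accuracy = b$accuracy)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean_savings = mean(folds$savings),
       sd_savings = stats::sd(folds$savings),
       mean_accuracy = mean(folds$accuracy),
       sd_accuracy = stats::sd(folds$accuracy))
}
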