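# Index-admission / 30-day-readmission labeling.
#
# Every hospitalization is an index admission with potential for a
# readmission; an index is flagged when the next countable admission of the
# same patient begins within 30 days of its discharge. Planned admissions,
# within-hospital transfers and discharges against medical advice are not
# countable: they are neither flagged as indexes nor usable as readmissions,
# and they are invisible to the gap computation (the gap runs to the next
# *countable* admission).

#' Label index admissions and 30-day readmissions
#'
#' Applies the inclusion/exclusion and flagging rules to an admission table.
#' An admission is countable unless it is planned or its disposition is
#' `transfer` or `against_medical_advice`. For each countable admission the
#' gap to the patient's next countable admission is
#' `next admit_date - this discharge_date` in whole days; the admission is
#' flagged as having a 30-day readmission when that gap is between 0 and 30
#' inclusive (a same-day return counts). A readmission is itself evaluated as
#' an index admission. The cumulative count of a patient's earlier flagged
#' admissions is carried along as a feature
#' (`cumulative_prior_30day_readmissions`).
#'
#' @param x An `emr_cohort` or an admissions data frame with columns
#'   `admission_id`, `patient_id`, `admit_date`, `discharge_date`,
#'   `disposition`, `planned`.
#' @return The admissions data frame, ordered by patient and admission date
#'   (ties broken by discharge date then input order), with added columns
#'   `is_countable`, `days_to_next_countable_admission` (NA when the patient
#'   has no later countable admission), `has_30day_readmission`,
#'   `is_readmission` (this admission begins <=30 days after the previous
#'   countable discharge) and `cumulative_prior_30day_readmissions`.
#' @examples
#' adm <- data.frame(
#'   admission_id = c("a1", "a2"), patient_id = "p1",
#'   admit_date = c(0, 35), discharge_date = c(5, 40),
#'   disposition = "routine", planned = FALSE)
#' label_readmissions(adm)$has_30day_readmission  # 30-day gap: TRUE, NA-next
#' @export
label_readmissions <- function(x) {
  adm <- if (inherits(x, "emr_cohort")) x$admissions else x
  req <- c("admission_id", "patient_id", "admit_date", "discharge_date",
           "disposition", "planned")
  missing_cols <- setdiff(req, names(adm))
  if (length(missing_cols)) {
    stop("admissions table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(adm$discharge_date < adm$admit_date)) {
    stop("data error: discharge before admission for admission(s) ",
         paste(utils::head(adm$admission_id[
           adm$discharge_date < adm$admit_date], 5), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(adm$patient_id, adm$admit_date, adm$discharge_date,
               seq_len(nrow(adm)))
  adm <- adm[ord, , drop = FALSE]
  same <- adm$patient_id[-1] == adm$patient_id[-nrow(adm)]
  overlap <- same & adm$admit_date[-1] < adm$discharge_date[-nrow(adm)]
  if (any(overlap)) {
    bad <- unique(adm$patient_id[-1][overlap])
    stop("data error: overlapping stays for patient(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  adm$is_countable <- !adm$planned & adm$disposition == "routine"
  n <- nrow(adm)
  gap <- rep(NA_integer_, n)
  is_readmit <- rep(FALSE, n)
  flagged <- rep(FALSE, n)
  cumprior <- rep(0L, n)
  for (idx in split(seq_len(n), adm$patient_id)) {
    cnt <- idx[adm$is_countable[idx]]
    if (length(cnt) >= 2) {
      g <- adm$admit_date[cnt[-1]] - adm$discharge_date[cnt[-length(cnt)]]
      gap[cnt[-length(cnt)]] <- as.integer(g)
      hit <- g >= 0 & g <= 30
      flagged[cnt[-length(cnt)]] <- hit
      is_readmit[cnt[-1]] <- hit
    }
    if (length(cnt) >= 1) {
      cumprior[cnt] <- c(0L, cumsum(flagged[cnt])[-length(cnt)])
    }
  }
  adm$days_to_next_countable_admission <- gap
  adm$has_30day_readmission <- flagged
  adm$is_readmission <- is_readmit
  adm$cumulative_prior_30day_readmissions <- cumprior
  rownames(adm) <- NULL
  adm
}

#' Summarize a labeled cohort
#'
#' Computes the headline readmission rate (flagged countable admissions over
#' countable admissions, as a percentage to one decimal) and, when a code
#' subset is supplied, the cross-tabulation of that subset over index
#' admissions and readmissions: how many flagged indexes carry a subset
#' principal code, how many realized readmissions do, and the overlap where
#' both ends of the pair do.
#'
#' @param labeled Output of [label_readmissions()].
#' @param code_subset Optional character vector of principal codes defining a
#'   condition of interest (e.g. the heart-failure codes).
#' @return A list with `n_admissions`, `n_countable`, `n_flagged`,
#'   `rate_percent`, and (when `code_subset` is given) a `code_crosstab` list
#'   with counts and percentages.
#' @export
cohort_summary <- function(labeled, code_subset = NULL) {
  if (is.null(labeled) || nrow(labeled) == 0) {
    stop("empty labeled admission list", call. = FALSE)
  }
  n_countable <- sum(labeled$is_countable)
  n_flagged <- sum(labeled$has_30day_readmission)
  out <- list(
    n_admissions = nrow(labeled),
    n_countable = n_countable,
    n_flagged = n_flagged,
    rate_percent = rate_percent(n_flagged, n_countable)
  )
  if (!is.null(code_subset)) {
    in_set <- labeled$principal_code %in% code_subset
    flagged <- labeled$has_30day_readmission
    readmit <- labeled$is_readmission
    # pair up each flagged index with its realized readmission
    idx_in <- sum(flagged & in_set)
    re_in <- sum(readmit & in_set)
    # overlap: flagged index in the subset whose readmission is also in it
    ord_idx <- which(flagged)
    overlap <- 0L
    cnt_rows <- which(labeled$is_countable)
    nxt <- rep(NA_integer_, nrow(labeled))
    for (idx in split(cnt_rows, labeled$patient_id[cnt_rows])) {
      if (length(idx) >= 2) nxt[idx[-length(idx)]] <- idx[-1]
    }
    overlap <- sum(flagged & in_set & in_set[nxt], na.rm = TRUE)
    out$code_crosstab <- list(
      n_index_in_subset = idx_in,
      n_readmission_in_subset = re_in,
      n_overlap = overlap,
      pct_index_of_flagged = rate_percent(idx_in, max(n_flagged, 1)),
      pct_readmission_of_flagged = rate_percent(re_in, max(n_flagged, 1)),
      pct_overlap_of_flagged = rate_percent(overlap, max(n_flagged, 1)),
      pct_overlap_of_subset_readmissions =
        rate_percent(overlap, max(re_in, 1))
    )
  }
  out
}
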