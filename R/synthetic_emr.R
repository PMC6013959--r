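# Synthetic EMR cohort generator.
#
# Emulates the statistical structure an admission-level readmission model
# assumes: patients with chained inpatient admissions, a ~23.3% 30-day
# readmission rate among countable admissions, excludable planned/transfer/
# against-medical-advice stays, and admission-level covariates that carry
# both linear and nonlinear (XOR / product interaction) signal for the
# outcome. All dates live on an integer-day axis; calendar formatting is an
# I/O concern only.

#' Configuration for a synthetic EMR cohort
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. The defaults describe the cohort the package's
#' examples and tests simulate: roughly 2.4 admissions per patient, a 23.3%
#' realized 30-day readmission rate among countable admissions, small
#' fractions of planned / transfer / against-medical-advice stays, and an
#' outcome driven by a logistic risk model with a few linear effects plus one
#' XOR interaction, so that the data contain both linear and nonlinear
#' structure.
#'
#' @param n_patients Number of patients.
#' @param mean_admissions_per_patient Mean admissions per patient (>= 1);
#'   per-patient counts are `1 + Poisson(mean - 1)`.
#' @param target_readmit_rate Fraction of countable admissions that should be
#'   followed by a countable admission within 30 days of discharge. The
#'   generator calibrates the risk-model intercept so the realized rate
#'   converges to this value.
#' @param n_binary_codes Number of binary covariates (surfaced downstream as
#'   diagnosis codes).
#' @param n_continuous_vars Number of continuous covariates in `[0, 1]`
#'   (surfaced downstream as abnormal-lab intensities).
#' @param n_note_tokens Vocabulary size for note token streams.
#' @param frac_planned,frac_transfer,frac_ama Marginal probabilities that an
#'   admission is planned, ends in a within-hospital transfer, or ends with
#'   the patient leaving against medical advice. Such admissions are excluded
#'   from readmission counting.
#' @param linear_weights Numeric vector of length
#'   `n_binary_codes + n_continuous_vars` of linear risk weights (binary
#'   covariates first). Default: moderate effects on the first five
#'   covariates, zero elsewhere.
#' @param nonlinear_pairs Interaction terms as a 3-column matrix (or list of
#'   length-3 vectors) `(i, j, weight)`. When covariates `i` and `j` are both
#'   binary the term is `weight * XOR(x_i, x_j)`; otherwise
#'   `weight * x_i * x_j`. Default: one XOR interaction on the first two
#'   (balanced) binary covariates.
#' @param noise_sd Standard deviation of Gaussian noise added to the linear
#'   predictor of the risk model.
#' @param seed Integer seed; the same config and seed yield byte-identical
#'   cohorts.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 2000L,
                          mean_admissions_per_patient = 2.4,
                          target_readmit_rate = 0.233,
                          n_binary_codes = 30L,
                          n_continuous_vars = 5L,
                          n_note_tokens = 200L,
                          frac_planned = 0.05,
                          frac_transfer = 0.03,
                          frac_ama = 0.02,
                          linear_weights = NULL,
                          nonlinear_pairs = NULL,
                          noise_sd = 0.5,
                          seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  n_binary_codes <- check_count(n_binary_codes, "n_binary_codes")
  n_continuous_vars <- check_count(n_continuous_vars, "n_continuous_vars",
                                   positive = FALSE)
  n_note_tokens <- check_count(n_note_tokens, "n_note_tokens")
  check_positive(mean_admissions_per_patient, "mean_admissions_per_patient")
  if (mean_admissions_per_patient < 1) {
    stop("configuration error: `mean_admissions_per_patient` must be >= 1",
         call. = FALSE)
  }
  check_probability(target_readmit_rate, "target_readmit_rate")
  check_probability(frac_planned, "frac_planned")
  check_probability(frac_transfer, "frac_transfer")
  check_probability(frac_ama, "frac_ama")
  if (frac_transfer + frac_ama > 1) {
    stop("configuration error: `frac_transfer` + `frac_ama` must be <= 1",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("configuration error: `noise_sd` must be a nonnegative number",
         call. = FALSE)
  }
  p_cov <- n_binary_codes + n_continuous_vars
  if (is.null(linear_weights)) {
    linear_weights <- rep(0, p_cov)
    base <- c(1.2, -0.9, 0.7, 0.5, -0.4)
    linear_weights[seq_len(min(5L, p_cov))] <- base[seq_len(min(5L, p_cov))]
  }
  if (length(linear_weights) != p_cov || !is.numeric(linear_weights)) {
    stop("configuration error: `linear_weights` must be numeric of length ",
         p_cov, call. = FALSE)
  }
  if (is.null(nonlinear_pairs)) {
    nonlinear_pairs <- if (n_binary_codes >= 2L) {
      matrix(c(1, 2, 1.0), nrow = 1L)
    } else {
      matrix(numeric(0), ncol = 3L)
    }
  }
  if (is.list(nonlinear_pairs)) {
    nonlinear_pairs <- do.call(rbind, lapply(nonlinear_pairs, as.numeric))
  }
  nonlinear_pairs <- matrix(as.numeric(nonlinear_pairs), ncol = 3L)
  if (nrow(nonlinear_pairs) > 0) {
    idx <- nonlinear_pairs[, 1:2]
    if (any(idx < 1 | idx > p_cov | idx != floor(idx))) {
      stop("configuration error: `nonlinear_pairs` index out of covariate range 1..",
           p_cov, call. = FALSE)
    }
  }
  structure(list(
    n_patients = n_patients,
    mean_admissions_per_patient = mean_admissions_per_patient,
    target_readmit_rate = target_readmit_rate,
    n_binary_codes = n_binary_codes,
    n_continuous_vars = n_continuous_vars,
    n_note_tokens = n_note_tokens,
    frac_planned = frac_planned,
    frac_transfer = frac_transfer,
    frac_ama = frac_ama,
    linear_weights = as.numeric(linear_weights),
    nonlinear_pairs = nonlinear_pairs,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Linear + interaction part of the risk score (no intercept, no noise).
risk_signal <- function(X, config) {
  eta <- drop(X %*% config$linear_weights)
  np <- config$nonlinear_pairs
  if (nrow(np) > 0) {
    for (r in seq_len(nrow(np))) {
      i <- np[r, 1]; j <- np[r, 2]; w <- np[r, 3]
      xi <- X[, i]; xj <- X[, j]
      if (all(xi %in% c(0, 1)) && all(xj %in% c(0, 1))) {
        eta <- eta + w * (xi + xj - 2 * xi * xj)  # XOR
      } else {
        eta <- eta + w * xi * xj
      }
    }
  }
  eta
}

#' Generate a synthetic EMR cohort
#'
#' Simulates an admission-level EMR extract: patients with one or more
#' chronologically ordered hospital stays, per-admission exclusion flags
#' (planned admissions, within-hospital transfers, discharges against medical
#' advice), demographics, and event tables (diagnoses, labs with abnormality
#' flags, medications, procedures, sectioned note token streams) whose
#' content is tied to a latent logistic risk model.
#'
#' The generator first samples the admission skeleton and latent covariates,
#' then calibrates the risk-model intercept (by root finding) so that the
#' expected fraction of countable admissions followed by a countable
#' admission within 30 days equals `config$target_readmit_rate`. Inter-
#' admission gaps are drawn from a mixture: a geometric distribution
#' truncated to 0–30 days for realized readmissions, and a uniform
#' distribution on 31–365 days otherwise. Event tables are derived from the
#' covariates: a binary covariate that is "on" plants the matching diagnosis
#' code within the two years before discharge, and each continuous covariate
#' sets the intensity of abnormal results for one lab code near admission and
#' discharge. Note tokens follow a Zipf distribution whose head is tilted
#' towards a high-risk sub-vocabulary for high-risk admissions, so
#' bag-of-words features carry outcome signal.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `emr_cohort`: a list of data frames
#'   (`admissions`, `demographics`, `diagnoses`, `labs`, `medications`,
#'   `procedures`, `notes`), the latent design matrix `covariates`
#'   (admission_id plus x1..xp; ground truth for testing, never used by the
#'   feature extractor), a `truth` table with the per-admission readmission
#'   probability, and the `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' head(coh$admissions)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  with_seed(config$seed, {
    n_pat <- config$n_patients
    n_adm_pat <- 1L + stats::rpois(n_pat, config$mean_admissions_per_patient - 1)
    n <- sum(n_adm_pat)
    patient_idx <- rep(seq_len(n_pat), n_adm_pat)
    adm_seq <- sequence(n_adm_pat)
    is_last <- adm_seq == n_adm_pat[patient_idx]

    planned <- stats::runif(n) < config$frac_planned
    u <- stats::runif(n)
    disposition <- rep("routine", n)
    disposition[u < config$frac_transfer] <- "transfer"
    disposition[u >= config$frac_transfer &
                  u < config$frac_transfer + config$frac_ama] <-
      "against_medical_advice"
    countable <- !planned & disposition == "routine"

    # Latent covariates: balanced prevalence for the first two binary codes
    # (so a default XOR interaction is balanced), moderate prevalence for the
    # rest; continuous covariates uniform on [0, 1].
    nb <- config$n_binary_codes
    nc <- config$n_continuous_vars
    prev <- c(0.5, 0.5, stats::runif(max(nb - 2L, 0L), 0.1, 0.5))[seq_len(nb)]
    Xb <- matrix(stats::rbinom(n * nb, 1L, rep(prev, each = n)), nrow = n)
    Xc <- if (nc > 0) matrix(stats::runif(n * nc), nrow = n) else
      matrix(numeric(0), nrow = n, ncol = 0)
    X <- cbind(Xb, Xc)
    colnames(X) <- paste0("x", seq_len(ncol(X)))

    eta <- risk_signal(X, config) +
      if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0

    # An admission can only realize a 30-day readmission when it is countable
    # and its immediate successor (same patient) is countable; calibrate the
    # intercept so the expected flagged fraction of countable admissions hits
    # the target.
    next_countable <- c(countable[-1], FALSE) & !is_last
    eligible <- countable & next_countable
    n_countable <- sum(countable)
    n_eligible <- sum(eligible)
    p_true <- rep(NA_real_, n)
    flagged <- rep(FALSE, n)
    if (n_eligible > 0 && config$target_readmit_rate > 0) {
      needed <- config$target_readmit_rate * n_countable / n_eligible
      if (needed >= 0.999) {
        warning("target_readmit_rate unattainable given exclusion fractions; ",
                "saturating at the eligible admissions")
        needed <- 0.999
      }
      eta_el <- eta[eligible]
      b0 <- stats::uniroot(
        function(b) mean(stats::plogis(b + eta_el)) - needed,
        interval = c(-60, 60), tol = 1e-10
      )$root
      p_true[eligible] <- stats::plogis(b0 + eta_el)
      flagged[eligible] <- stats::runif(n_eligible) < p_true[eligible]
    }

    # Dates on an integer-day axis. Gap = next admit - this discharge.
    los <- 1L + stats::rpois(n, 4)
    gap <- integer(n)
    n_flag <- sum(flagged)
    if (n_flag > 0) {
      short <- stats::dgeom(0:30, 0.12)
      gap[flagged] <- sample(0:30, n_flag, replace = TRUE, prob = short)
    }
    long_idx <- !is_last & !flagged
    gap[long_idx] <- sample(31:365, sum(long_idx), replace = TRUE)
    first_admit <- sample(0:729, n_pat, replace = TRUE)
    step <- los + gap
    lag_step <- c(0L, step[-n])
    lag_step[adm_seq == 1L] <- 0L
    offset <- stats::ave(lag_step, patient_idx, FUN = cumsum)
    admit <- first_admit[patient_idx] + offset
    discharge <- admit + los

    admission_id <- sprintf("A%06d", seq_len(n))
    patient_id <- sprintf("P%05d", patient_idx)
    principal_code <- paste0("C", sample(1:20, n, replace = TRUE,
                                         prob = stats::dgeom(0:19, 0.15)))
    admissions <- data.frame(
      admission_id = admission_id,
      patient_id = patient_id,
      admit_date = admit,
      discharge_date = discharge,
      disposition = disposition,
      planned = planned,
      principal_code = principal_code,
      stringsAsFactors = FALSE
    )

    demographics <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n_pat)),
      age = pmin(pmax(round(stats::rnorm(n_pat, 76, 12)), 18), 89),
      sex = sample(c("male", "female"), n_pat, replace = TRUE,
                   prob = c(0.53, 0.47)),
      race = sample(c("white", "black", "hispanic", "asian", "other"), n_pat,
                    replace = TRUE, prob = c(0.845, 0.079, 0.038, 0.02, 0.018)),
      marital_status = sample(c("married", "widowed", "single", "divorced"),
                              n_pat, replace = TRUE,
                              prob = c(0.46, 0.21, 0.2, 0.13)),
      median_income = round(stats::rlnorm(n_pat, log(55000), 0.4)),
      stringsAsFactors = FALSE
    )

    # Diagnoses: binary covariate c "on" plants code Dc somewhere in the two
    # years before discharge.
    on <- which(Xb == 1L, arr.ind = TRUE)
    diagnoses <- data.frame(
      admission_id = admission_id[on[, 1]],
      code = sprintf("D%03d", on[, 2]),
      event_date = discharge[on[, 1]] -
        sample(0:729, nrow(on), replace = TRUE),
      stringsAsFactors = FALSE
    )

    # Labs: continuous covariate l drives the abnormal-result intensity of
    # lab code Ll in both the admission-side and discharge-side windows.
    labs <- local({
      if (nc == 0) {
        return(data.frame(admission_id = character(0), code = character(0),
                          event_date = integer(0), abnormal = logical(0)))
      }
      rows <- vector("list", 2L * nc + 1L)
      k <- 1L
      for (l in seq_len(nc)) {
        n_ab_a <- stats::rpois(n, 3 * Xc[, l])
        n_ab_d <- stats::rpois(n, 3 * Xc[, l])
        ia <- rep(seq_len(n), n_ab_a)
        id <- rep(seq_len(n), n_ab_d)
        rows[[k]] <- data.frame(
          admission_id = admission_id[ia],
          code = sprintf("L%02d", l),
          event_date = pmin(admit[ia] + sample(0:7, length(ia), replace = TRUE),
                            discharge[ia]),
          abnormal = TRUE, stringsAsFactors = FALSE)
        rows[[k + 1L]] <- data.frame(
          admission_id = admission_id[id],
          code = sprintf("L%02d", l),
          event_date = pmax(discharge[id] -
                              sample(0:7, length(id), replace = TRUE),
                            admit[id]),
          abnormal = TRUE, stringsAsFactors = FALSE)
        k <- k + 2L
      }
      n_norm <- stats::rpois(n, 1)
      ino <- rep(seq_len(n), n_norm)
      rows[[k]] <- data.frame(
        admission_id = admission_id[ino],
        code = sprintf("L%02d", sample(seq_len(nc), length(ino), replace = TRUE)),
        event_date = admit[ino] +
          (stats::runif(length(ino)) * (los[ino] + 1)) %/% 1,
        abnormal = FALSE, stringsAsFactors = FALSE)
      do.call(rbind, rows)
    })

    # Medications / procedures: mostly noise events within the stay.
    meds <- local({
      n_med <- stats::rpois(n, 3)
      i <- rep(seq_len(n), n_med)
      data.frame(
        admission_id = admission_id[i],
        code = sprintf("RX%02d", sample(1:40, length(i), replace = TRUE,
                                        prob = stats::dgeom(0:39, 0.1))),
        event_date = admit[i] + (stats::runif(length(i)) * (los[i] + 1)) %/% 1,
        stringsAsFactors = FALSE)
    })
    procs <- local({
      n_pr <- stats::rpois(n, 1.5)
      i <- rep(seq_len(n), n_pr)
      data.frame(
        admission_id = admission_id[i],
        code = sprintf("PR%02d", sample(1:20, length(i), replace = TRUE)),
        event_date = admit[i] + (stats::runif(length(i)) * (los[i] + 1)) %/% 1,
        stringsAsFactors = FALSE)
    })

    notes <- generate_notes(admission_id, admit, discharge, eta, config)

    covariates <- data.frame(admission_id = admission_id, X,
                             stringsAsFactors = FALSE)
    truth <- data.frame(
      admission_id = admission_id,
      eligible = eligible,
      p_readmit = p_true,
      flagged = flagged,
      stringsAsFactors = FALSE
    )

    structure(list(
      admissions = admissions,
      demographics = demographics,
      diagnoses = diagnoses,
      labs = labs,
      medications = meds,
      procedures = procs,
      notes = notes,
      covariates = covariates,
      truth = truth,
      config = config
    ), class = "emr_cohort")
  })
}

# Zipf token streams per note section; the head of the distribution shifts
# towards a 20-word "high-risk" sub-vocabulary as the risk score grows.
generate_notes <- function(admission_id, admit, discharge, eta, config) {
  n <- length(admission_id)
  sections <- list(
    physician_note = c(social_history = 0.8, assessment = 0.9, plan = 0.85,
                       family_history = 0.3),
    discharge_summary = c(hospital_course = 0.95, allergies = 0.7,
                          hospital_reason = 0.9, significant_findings = 0.6)
  )
  vsize <- config$n_note_tokens
  zipf <- (1 / seq_len(vsize)); zipf <- zipf / sum(zipf)
  n_risk <- min(20L, vsize)
  zipf_risk <- (1 / seq_len(n_risk)); zipf_risk <- zipf_risk / sum(zipf_risk)
  # per-admission probability of drawing a token from the risk vocabulary;
  # a constant risk score (degenerate config) tilts nothing
  sd_eta <- stats::sd(eta)
  tilt <- if (!is.finite(sd_eta) || sd_eta == 0) rep(0.5, n) else
    stats::plogis((eta - mean(eta)) / sd_eta)
  tokens_per_section <- 20L

  out <- vector("list", length(sections))
  for (t in seq_along(sections)) {
    type <- names(sections)[t]
    probs <- sections[[t]]
    present <- matrix(stats::runif(n * length(probs)) <
                        rep(probs, each = n), nrow = n)
    idx <- which(present, arr.ind = TRUE)
    n_docs <- nrow(idx)
    if (n_docs == 0) next
    slot_adm <- rep(idx[, 1], each = tokens_per_section)
    from_risk <- stats::runif(length(slot_adm)) < 0.25 * tilt[slot_adm]
    tok <- integer(length(slot_adm))
    tok[from_risk] <- sample(seq_len(n_risk), sum(from_risk), replace = TRUE,
                             prob = zipf_risk)
    tok[!from_risk] <- sample(seq_len(vsize), sum(!from_risk), replace = TRUE,
                              prob = zipf)
    words <- sprintf("w%04d", tok)
    text <- vapply(split(words, rep(seq_len(n_docs),
                                    each = tokens_per_section)),
                   paste, character(1), collapse = " ")
    out[[t]] <- data.frame(
      admission_id = admission_id[idx[, 1]],
      note_type = type,
      note_date = if (type == "physician_note") admit[idx[, 1]] else
        discharge[idx[, 1]],
      section = names(probs)[idx[, 2]],
      text = unname(text),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out[order(out$admission_id, out$note_type, out$section), , drop = FALSE]
}

#' @method print emr_cohort
#' @export
print.emr_cohort <- function(x, ...) {
  cat("Synthetic EMR cohort:", nrow(x$demographics), "patients,",
      nrow(x$admissions), "admissions\n")
  cat("  event rows: diagnoses", nrow(x$diagnoses), "| labs", nrow(x$labs),
      "| medications", nrow(x$medications), "| procedures",
      nrow(x$procedures), "| note sections", nrow(x$notes), "\n")
  invisible(x)
}
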