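# Feature vector generation.
#
# Windowed value expressions per data type:
#   demographics  patient-level          binary (1-of-K) / continuous
#   admissions    admit -> discharge     continuous/discrete
#   diagnoses     discharge-2y -> discharge   binary occurrence
#   labs          admit -> admit+7d and discharge-7d -> discharge,
#                 abnormal-occurrence counts (two variables per code)
#   medications   admit -> discharge     occurrence counts (after code mapping)
#   procedures    admit -> discharge     occurrence counts
#   notes         admit -> discharge     BOW binary presence per word, except
#                 the allergies section which uses counts
# Missing entries are zero-filled, every column is min-max scaled to [0, 1],
# and variables are filtered by total (symmetrized) KL divergence between the
# readmitted and non-readmitted class-conditional distributions.

DAYS_2Y <- 730L
DAYS_7D <- 7L

#' Select note sections present in at least half the notes
#'
#' A section is retained when it appears in >= 50% of the notes of its note
#' type; a note is one (admission, note type) document.
#'
#' @param notes Note-section table with columns `admission_id`, `note_type`,
#'   `section`.
#' @return Data frame of retained `note_type` / `section` pairs with the
#'   presence fraction.
#' @export
select_note_sections <- function(notes) {
  if (is.null(notes) || nrow(notes) == 0) {
    return(data.frame(note_type = character(0), section = character(0),
                      presence = numeric(0)))
  }
  out <- lapply(split(notes, notes$note_type), function(d) {
    n_docs <- length(unique(d$admission_id))
    pres <- tapply(d$admission_id, d$section,
                   function(a) length(unique(a))) / n_docs
    data.frame(note_type = d$note_type[1], section = names(pres),
               presence = as.numeric(pres), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$presence >= 0.5, , drop = FALSE]
}

#' Bag-of-words variables from token streams
#'
#' Builds, for every word that appears more than `min_total_count - 1` times
#' in the whole corpus, two variables per document: the within-document count
#' (`<word>.count`) and binary presence (`<word>.bin`). Words whose
#' corpus-wide total count is `<= min_total_count - 1` are dropped (with the
#' default, words appearing five times or fewer).
#'
#' @param docs Named list of character token vectors, one per document, or a
#'   data frame with `doc_id` and `token` columns.
#' @param normalizer Deterministic token -> token function applied before
#'   counting; return `NA` to drop a token. Default lowercases.
#' @param min_total_count Minimum corpus-wide count for a word to be kept.
#' @return Numeric matrix (documents x 2*words) with document names as rows.
#' @export
build_bow <- function(docs, normalizer = tolower, min_total_count = 6) {
  if (is.data.frame(docs)) {
    docs <- split(as.character(docs$token), docs$doc_id)
  }
  if (length(docs) == 0) return(matrix(numeric(0), nrow = 0, ncol = 0))
  doc_ids <- names(docs)
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(docs))
  tok <- normalizer(unlist(docs, use.names = FALSE))
  doc_of <- rep(seq_along(docs), lengths(docs))
  keep_tok <- !is.na(tok)
  tok <- tok[keep_tok]; doc_of <- doc_of[keep_tok]
  totals <- table(tok)
  vocab <- sort(names(totals)[totals >= min_total_count])
  if (length(vocab) == 0) {
    return(matrix(numeric(0), nrow = length(docs), ncol = 0,
                  dimnames = list(doc_ids, NULL)))
  }
  counts <- matrix(0, nrow = length(docs), ncol = length(vocab),
                   dimnames = list(doc_ids, vocab))
  in_vocab <- tok %in% vocab
  tt <- table(doc_of[in_vocab], tok[in_vocab])
  counts[as.integer(rownames(tt)), colnames(tt)] <- as.matrix(tt)
  out <- cbind(counts, (counts > 0) * 1)
  colnames(out) <- c(paste0(vocab, ".count"), paste0(vocab, ".bin"))
  out
}

count_in_window <- function(events, adm, from, to, value = "count") {
  # events: admission_id, code, event_date (+abnormal); from/to named by
  # admission_id. Returns admissions x codes matrix of windowed counts.
  codes <- sort(unique(events$code))
  m <- matrix(0, nrow = nrow(adm), ncol = length(codes),
              dimnames = list(adm$admission_id, codes))
  if (nrow(events) == 0 || length(codes) == 0) return(m)
  ev <- events[events$admission_id %in% adm$admission_id, , drop = FALSE]
  lo <- from[ev$admission_id]; hi <- to[ev$admission_id]
  inw <- ev$event_date >= lo & ev$event_date <= hi
  ev <- ev[inw, , drop = FALSE]
  if (nrow(ev) == 0) return(m)
  tt <- table(ev$admission_id, ev$code)
  m[rownames(tt), colnames(tt)] <- as.matrix(tt)
  if (value == "binary") m <- (m > 0) * 1
  m
}

apply_lookup <- function(codes, lookup, label) {
  # two-column lookup (source_code, target_code); unmapped pass through raw
  if (is.null(lookup) || nrow(lookup) == 0) return(codes)
  map <- stats::setNames(as.character(lookup[[2]]), as.character(lookup[[1]]))
  mapped <- map[codes]
  coverage <- mean(!is.na(mapped))
  message(sprintf("%s code mapping coverage: %.1f%%", label, 100 * coverage))
  ifelse(is.na(mapped), codes, mapped)
}

#' Extract windowed feature variables from a labeled cohort
#'
#' Turns a cohort plus its readmission labels into one raw feature row per
#' countable admission, applying the per-data-type windows and value
#' expressions described in the package vignette: patient-level demographics
#' (categoricals kept for later 1-of-K coding), within-stay admission
#' variables (length of stay, age at admission, cumulative prior 30-day
#' readmissions), two-year diagnosis-code occurrence flags, admission-side
#' and discharge-side abnormal-lab counts, within-stay medication and
#' procedure counts (medication codes passed through an optional
#' source-to-ATC lookup), and bag-of-words note variables over the sections
#' retained by [select_note_sections()] (binary presence, except counts for
#' the allergies section).
#'
#' @param cohort An `emr_cohort`.
#' @param labeled Output of [label_readmissions()] on that cohort.
#' @param lookups Optional named list of two-column data frames
#'   (`source_code`, `target_code`): elements `medications` and/or `wkf`
#'   (diagnosis code to well-known-factor group). Unmapped codes pass
#'   through under their raw identity; mapping coverage is reported.
#' @param min_word_count Corpus frequency cutoff passed to [build_bow()].
#' @return A list of class `raw_features`: `data` (one data frame row per
#'   countable admission; categorical columns are characters), `labels`
#'   (binary 30-day readmission outcome), `row_keys` (admission ids) and
#'   `column_types`.
#' @export
extract_features <- function(cohort, labeled, lookups = list(),
                             min_word_count = 6) {
  adm <- labeled[labeled$is_countable, , drop = FALSE]
  from_admit <- stats::setNames(adm$admit_date, adm$admission_id)
  to_discharge <- stats::setNames(adm$discharge_date, adm$admission_id)

  demo <- cohort$demographics[match(adm$patient_id,
                                    cohort$demographics$patient_id), ,
                              drop = FALSE]
  raw <- data.frame(
    demo_age = demo$age,
    demo_sex = demo$sex,
    demo_race = demo$race,
    demo_marital_status = demo$marital_status,
    demo_median_income = demo$median_income,
    adm_length_of_stay = adm$discharge_date - adm$admit_date,
    adm_cumulative_30day_readmissions =
      adm$cumulative_prior_30day_readmissions,
    stringsAsFactors = FALSE
  )

  # diagnoses: binary occurrence in [discharge - 2y, discharge]
  dx <- cohort$diagnoses
  if (!is.null(lookups$wkf)) {
    wkf_codes <- apply_lookup(dx$code, lookups$wkf, "WKF")
    extra <- dx; extra$code <- paste0("wkf_", wkf_codes)
    dx <- rbind(dx, extra[wkf_codes != dx$code, , drop = FALSE])
  }
  dx_m <- count_in_window(dx, adm, from = to_discharge - DAYS_2Y,
                          to = to_discharge, value = "binary")
  colnames(dx_m) <- paste0("dx_", colnames(dx_m))

  # labs: abnormal-occurrence counts in the two one-week windows
  labs_ab <- cohort$labs[cohort$labs$abnormal, , drop = FALSE]
  lab_admit <- count_in_window(labs_ab, adm, from = from_admit,
                               to = from_admit + DAYS_7D)
  lab_disch <- count_in_window(labs_ab, adm, from = to_discharge - DAYS_7D,
                               to = to_discharge)
  colnames(lab_admit) <- paste0("lab_admit_", colnames(lab_admit))
  colnames(lab_disch) <- paste0("lab_discharge_", colnames(lab_disch))

  # medications / procedures: within-stay occurrence counts
  med <- cohort$medications
  if (!is.null(lookups$medications)) {
    med$code <- apply_lookup(med$code, lookups$medications, "medication")
  }
  med_m <- count_in_window(med, adm, from = from_admit, to = to_discharge)
  colnames(med_m) <- paste0("med_", colnames(med_m))
  pr_m <- count_in_window(cohort$procedures, adm, from = from_admit,
                          to = to_discharge)
  colnames(pr_m) <- paste0("proc_", colnames(pr_m))

  # notes: BOW over retained sections; binary except allergies (counts)
  notes <- cohort$notes[cohort$notes$admission_id %in% adm$admission_id, ,
                        drop = FALSE]
  kept_sections <- select_note_sections(notes)
  bow <- NULL
  if (nrow(kept_sections) > 0 && nrow(notes) > 0) {
    keep <- paste(notes$note_type, notes$section) %in%
      paste(kept_sections$note_type, kept_sections$section)
    notes <- notes[keep, , drop = FALSE]
    pieces <- lapply(split(notes, notes$section), function(d) {
      docs <- lapply(split(d$text, d$admission_id),
                     function(s) unlist(strsplit(s, " ", fixed = TRUE)))
      b <- build_bow(docs, min_total_count = min_word_count)
      if (ncol(b) == 0) return(NULL)
      use <- if (d$section[1] == "allergies") ".count$" else ".bin$"
      b <- b[, grepl(use, colnames(b)), drop = FALSE]
      full <- matrix(0, nrow = nrow(adm), ncol = ncol(b),
                     dimnames = list(adm$admission_id,
                                     paste0("note_", d$section[1], "_",
                                            colnames(b))))
      full[rownames(b), ] <- b
      full
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces)) bow <- do.call(cbind, pieces)
  }

  data <- cbind(raw, as.data.frame(dx_m), as.data.frame(lab_admit),
                as.data.frame(lab_disch), as.data.frame(med_m),
                as.data.frame(pr_m))
  if (!is.null(bow)) data <- cbind(data, as.data.frame(bow))
  rownames(data) <- NULL
  structure(list(
    data = data,
    labels = as.integer(adm$has_30day_readmission),
    row_keys = adm$admission_id,
    column_types = vapply(data, function(col)
      if (is.numeric(col)) "numeric" else "categorical", character(1))
  ), class = "raw_features")
}

#' Fit the 1-of-K encoder and min-max scaler on training data
#'
#' Categorical (character/factor) columns are expanded to one indicator per
#' observed level; numeric columns keep their identity. Missing values are
#' treated as zero. Min-max parameters are recorded per expanded column so
#' the same affine map can be applied to held-out data (with clipping to
#' `[0, 1]`); constant columns map to all zeros.
#'
#' @param data Data frame of raw feature columns (or a `raw_features` list).
#' @return An `encoder` object for [apply_encoder()].
#' @export
fit_encoder <- function(data) {
  if (inherits(data, "raw_features")) data <- data$data
  levels_map <- lapply(data, function(col) {
    if (is.numeric(col)) NULL else sort(unique(as.character(col[!is.na(col)])))
  })
  expanded <- expand_onehot(data, levels_map)
  mins <- apply(expanded, 2, min)
  maxs <- apply(expanded, 2, max)
  structure(list(levels_map = levels_map, mins = mins, maxs = maxs,
                 columns = colnames(expanded)),
            class = "encoder")
}

expand_onehot <- function(data, levels_map) {
  cols <- lapply(names(data), function(nm) {
    col <- data[[nm]]
    lv <- levels_map[[nm]]
    if (is.null(lv)) {
      v <- as.numeric(col)
      v[is.na(v)] <- 0
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      m <- vapply(lv, function(l) as.numeric(!is.na(col) & col == l),
                  numeric(length(col)))
      if (!is.matrix(m)) m <- matrix(m, nrow = length(col))
      colnames(m) <- paste0(nm, ".", lv)
      m
    }
    m
  })
  do.call(cbind, cols)
}

#' Apply a fitted encoder to data
#'
#' @param encoder From [fit_encoder()].
#' @param data Data frame with the same raw columns the encoder was fit on.
#' @param clip Clip scaled values into `[0, 1]` (used for held-out data whose
#'   range may exceed the training range). Default `TRUE`.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
apply_encoder <- function(encoder, data, clip = TRUE) {
  if (inherits(data, "raw_features")) data <- data$data
  x <- expand_onehot(data, encoder$levels_map)
  rng <- encoder$maxs - encoder$mins
  scale <- ifelse(rng > 0, 1 / rng, 0)
  x <- sweep(x, 2, encoder$mins, "-")
  x <- sweep(x, 2, scale, "*")
  if (clip) x <- pmin(pmax(x, 0), 1)
  x
}

#' One-shot 1-of-K coding, zero imputation and min-max scaling
#'
#' Convenience wrapper equal to fitting the encoder on `data` and applying it
#' to the same data. For cross-validation use [fit_encoder()] /
#' [apply_encoder()] on the training fold only.
#'
#' @inheritParams fit_encoder
#' @return Numeric matrix in `[0, 1]`, with the fitted encoder attached as
#'   attribute `"encoder"`.
#' @examples
#' encode_and_scale(data.frame(a = c(2, 4, 6)))  # 0, 0.5, 1
#' @export
encode_and_scale <- function(data) {
  enc <- fit_encoder(data)
  out <- apply_encoder(enc, data)
  attr(out, "encoder") <- enc
  out
}

#' Total Kullback-Leibler divergence variable filter
#'
#' For every column, estimates the class-conditional distributions P (30-day
#' readmission) and Q (no readmission) — Bernoulli for binary columns, a
#' fixed-bin histogram over the pooled range for the rest — with additive
#' smoothing `eps` per cell, and scores the column by the total (symmetrized)
#' divergence `D = KL(P||Q) + KL(Q||P)`. Columns with `D` greater than or
#' equal to `mean(D) + 0.5 * sd(D)` are retained.
#'
#' @param x Numeric matrix (columns are variables).
#' @param labels Binary outcome vector; both classes must be present with at
#'   least two observations each.
#' @param eps Additive smoothing pseudo-mass per cell (default `1e-9`).
#' @param n_bins Histogram bins for non-binary columns (default 10).
#' @return A list of class `kl_report`: `table` (variable, divergence, kept),
#'   `divergence`, `threshold`, `keep_mask`, `smoothing_epsilon`, `n_bins`.
#' @examples
#' x <- cbind(sig = c(rep(1, 8), rep(0, 8)), noise = rep(c(0, 1), 8))
#' total_kl_divergence(x, rep(c(1, 0), each = 8))$keep_mask
#' @export
total_kl_divergence <- function(x, labels, eps = 1e-9, n_bins = 10) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (min(table(labels)) < 2) {
    stop("need at least 2 observations per class", call. = FALSE)
  }
  x <- as.matrix(x)
  pos <- labels == 1
  D <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (all(v %in% c(0, 1))) {
      cells <- rbind(p = c(sum(v[pos] == 0), sum(v[pos] == 1)),
                     q = c(sum(v[!pos] == 0), sum(v[!pos] == 1)))
    } else {
      rng <- range(v)
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
      bin <- pmin.int(pmax.int(findInterval(v, brk), 1L), n_bins)
      cells <- rbind(p = tabulate(bin[pos], n_bins),
                     q = tabulate(bin[!pos], n_bins))
    }
    p <- cells["p", ] + eps; p <- p / sum(p)
    q <- cells["q", ] + eps; q <- q / sum(q)
    sum(p * log(p / q)) + sum(q * log(q / p))
  }, numeric(1))
  sd_d <- stats::sd(D)
  if (is.na(sd_d)) sd_d <- 0
  tau <- mean(D) + 0.5 * sd_d
  keep <- D >= tau
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  structure(list(
    table = data.frame(variable = vars, divergence = D, kept = keep,
                       stringsAsFactors = FALSE),
    divergence = stats::setNames(D, vars),
    threshold = tau,
    keep_mask = stats::setNames(keep, vars),
    smoothing_epsilon = eps,
    n_bins = n_bins
  ), class = "kl_report")
}

#' @method print kl_report
#' @export
print.kl_report <- function(x, ...) {
  cat("Total KL divergence filter: kept", sum(x$keep_mask), "of",
      length(x$keep_mask), "variables (threshold",
      format(x$threshold, digits = 4), ")\n")
  invisible(x)
}
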