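# Shared fixtures and independent oracles used across the suite.

# Hand-built admission table; dates are integer days.
make_admissions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(admission_id = r[[1]], patient_id = r[[2]],
               admit_date = r[[3]], discharge_date = r[[4]],
               disposition = if (length(r) >= 5) r[[5]] else "routine",
               planned = if (length(r) >= 6) r[[6]] else FALSE,
               principal_code = if (length(r) >= 7) r[[7]] else "C1",
               stringsAsFactors = FALSE)
  }))
}

# Brute-force readmission labeler: for every countable admission, scan all
# later countable admissions of the same patient and flag on the first one
# (by admit date) within 30 days of discharge.
oracle_label <- function(adm) {
  countable <- !adm$planned & adm$disposition == "routine"
  flag <- logical(nrow(adm))
  for (i in seq_len(nrow(adm))) {
    if (!countable[i]) next
    later <- which(adm$patient_id == adm$patient_id[i] & countable &
                     adm$admit_date >= adm$discharge_date[i] &
                     seq_len(nrow(adm)) != i)
    later <- later[adm$admit_date[later] > adm$admit_date[i] |
                     (adm$admit_date[later] == adm$admit_date[i] &
                        later > i)]
    if (length(later) == 0) next
    nxt <- later[which.min(adm$admit_date[later])]
    flag[i] <- (adm$admit_date[nxt] - adm$discharge_date[i]) <= 30
  }
  flag
}

# Pairwise-concordance AUC oracle (half credit for ties).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  grid <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}

# Exhaustive operating-point oracle: evaluate the corner distance at every
# curve point.
oracle_optimal <- function(curve) {
  d <- sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
  curve$threshold[which.min(d)]
}

# Independent total-KL oracle for one column (same binning contract,
# separate code path via R's hist()).
oracle_total_kl <- function(v, labels, eps = 1e-9, n_bins = 10) {
  pos <- labels == 1
  if (all(v %in% c(0, 1))) {
    tab <- rbind(c(sum(v[pos] == 0), sum(v[pos] == 1)),
                 c(sum(v[!pos] == 0), sum(v[!pos] == 1)))
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    cut_all <- function(z) {
      b <- cut(z, breaks = brk, include.lowest = TRUE, right = FALSE,
               labels = FALSE)
      b[z >= brk[n_bins + 1]] <- n_bins
      tabulate(b, n_bins)
    }
    tab <- rbind(cut_all(v[pos]), cut_all(v[!pos]))
  }
  p <- tab[1, ] + eps; p <- p / sum(p)
  q <- tab[2, ] + eps; q <- q / sum(q)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

# Small scaled feature set with a known signal column, for model tests.
make_separable <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- cbind(a = runif(n), b = runif(n))
  y <- as.integer(x[, "a"] + x[, "b"] > 1)
  list(x = x, y = y)
}

# The XOR-plus-linear study cohort used by the model-separation checks.
xor_cohort_config <- function(seed = 42) {
  cohort_config(
    n_patients = 500, mean_admissions_per_patient = 8,
    target_readmit_rate = 0.233, n_binary_codes = 16, n_continuous_vars = 4,
    n_note_tokens = 50, frac_planned = 0, frac_transfer = 0, frac_ama = 0,
    linear_weights = c(0, 0, 0.8, -0.6, rep(0, 14), 0.5, 0),
    nonlinear_pairs = matrix(c(1, 2, 4), 1), noise_sd = 0.3, seed = seed)
}

xor_model_matrix <- function(coh) {
  el <- coh$truth$eligible
  list(x = as.matrix(coh$covariates[el, -1]),
       y = as.integer(coh$truth$flagged[el]))
}
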