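test_that("config validation names the offending field", {
  expect_error(cohort_config(target_readmit_rate = 1.2),
               "target_readmit_rate")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(frac_planned = -0.1), "frac_planned")
  expect_error(cohort_config(n_binary_codes = 4, n_continuous_vars = 0,
                             nonlinear_pairs = matrix(c(1, 9, 1), 1)),
               "out of covariate range")
})

test_that("same config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_patients = 80, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and the RNG state of the session is untouched
  set.seed(5); before <- runif(3)
  set.seed(5); generate_cohort(cfg); after <- runif(3)
  expect_identical(before, after)
})

test_that("degenerate exclusion fractions propagate to flags", {
  coh <- generate_cohort(cohort_config(n_patients = 60, frac_planned = 1,
                                       seed = 3))
  expect_true(all(coh$admissions$planned))
  coh2 <- generate_cohort(cohort_config(n_patients = 60, frac_planned = 0,
                                        frac_transfer = 0, frac_ama = 0,
                                        seed = 3))
  expect_false(any(coh2$admissions$planned))
  expect_true(all(coh2$admissions$disposition == "routine"))
})

test_that("admission dates are ordered and events stay in their windows", {
  coh <- generate_cohort(cohort_config(n_patients = 150, seed = 9))
  adm <- coh$admissions
  expect_true(all(adm$discharge_date >= adm$admit_date))
  for (p in split(adm, adm$patient_id)) {
    if (nrow(p) > 1) {
      expect_true(all(diff(p$admit_date) > 0))
      expect_true(all(p$admit_date[-1] >= p$discharge_date[-nrow(p)]))
    }
  }
  key <- match(coh$diagnoses$admission_id, adm$admission_id)
  expect_true(all(coh$diagnoses$event_date >= adm$discharge_date[key] - 730))
  expect_true(all(coh$diagnoses$event_date <= adm$discharge_date[key]))
  keyl <- match(coh$labs$admission_id, adm$admission_id)
  expect_true(all(coh$labs$event_date >= adm$admit_date[keyl]))
  expect_true(all(coh$labs$event_date <= adm$discharge_date[keyl]))
})

test_that("realized readmission rate converges to the target", {
  cfg <- cohort_config(n_patients = 10000, n_note_tokens = 30, seed = 77)
  coh <- generate_cohort(cfg)
  lab <- label_readmissions(coh)
  n_countable <- sum(lab$is_countable)
  realized <- sum(lab$has_30day_readmission)
  # exact binomial 99% interval around the target at this cohort size
  ci <- qbinom(c(0.005, 0.995), n_countable, cfg$target_readmit_rate)
  expect_gte(realized, ci[1])
  expect_lte(realized, ci[2])
})

test_that("pure XOR risk defeats a linear model but not the true risk", {
  cfg <- cohort_config(
    n_patients = 1500, mean_admissions_per_patient = 6,
    n_binary_codes = 2, n_continuous_vars = 0, n_note_tokens = 20,
    frac_planned = 0, frac_transfer = 0, frac_ama = 0,
    linear_weights = c(0, 0), nonlinear_pairs = matrix(c(1, 2, 3), 1),
    noise_sd = 0, seed = 21)
  coh <- generate_cohort(cfg)
  el <- coh$truth$eligible
  x <- as.matrix(coh$covariates[el, c("x1", "x2")])
  y <- as.integer(coh$truth$flagged[el])
  p_true <- coh$truth$p_readmit[el]

  # closed-form AUC over the four XOR cells: risk takes two values,
  # p1 = plogis(b + w) when XOR = 1, p0 = plogis(b) otherwise
  p0 <- min(p_true); p1 <- max(p_true)
  xor_on <- as.integer(xor(x[, 1] == 1, x[, 2] == 1))
  pos1 <- sum(y == 1 & xor_on == 1); pos0 <- sum(y == 1 & xor_on == 0)
  neg1 <- sum(y == 0 & xor_on == 1); neg0 <- sum(y == 0 & xor_on == 0)
  auc_cells <- (pos1 * neg0 + 0.5 * (pos1 * neg1 + pos0 * neg0)) /
    ((pos1 + pos0) * (neg1 + neg0))
  expect_equal(auc(roc_curve(p_true, y)), auc_cells, tolerance = 1e-12)
  expect_gt(auc_cells, 0.6)   # the true risk separates the classes

  lin <- glm(y ~ x, family = binomial)
  auc_lin <- auc(roc_curve(fitted(lin), y))
  expect_lt(abs(auc_lin - 0.5), 0.05)
})

test_that("zero- and one-probability limits produce no / all flags", {
  base <- list(n_patients = 120, mean_admissions_per_patient = 4,
               n_binary_codes = 2, n_continuous_vars = 0, n_note_tokens = 20,
               frac_planned = 0, frac_transfer = 0, frac_ama = 0,
               linear_weights = c(0, 0),
               nonlinear_pairs = matrix(numeric(0), ncol = 3),
               noise_sd = 0, seed = 13)
  lo <- generate_cohort(do.call(cohort_config,
                                c(base, target_readmit_rate = 0)))
  expect_false(any(lo$truth$flagged))
  hi <- suppressWarnings(
    generate_cohort(do.call(cohort_config,
                            c(base, target_readmit_rate = 1))))
  el <- hi$truth$eligible
  expect_gt(mean(hi$truth$flagged[el]), 0.99)
  gaps <- label_readmissions(hi)
  expect_true(all(gaps$days_to_next_countable_admission[
    hi$truth$flagged] <= 30))
})

test_that("noise-free linear risk weights are recoverable by regression", {
  w <- c(1.5, -1.2, 0.9, -0.6, 0.45, -0.3, 0.2, -0.1, 0.05, 0)
  cfg <- cohort_config(
    n_patients = 2700, mean_admissions_per_patient = 8,
    n_binary_codes = 10, n_continuous_vars = 0, n_note_tokens = 20,
    frac_planned = 0, frac_transfer = 0, frac_ama = 0,
    linear_weights = w, nonlinear_pairs = matrix(numeric(0), ncol = 3),
    noise_sd = 0, seed = 87)
  coh <- generate_cohort(cfg)
  el <- coh$truth$eligible
  expect_gt(sum(el), 18000)
  x <- as.matrix(coh$covariates[el, -1])
  y <- as.integer(coh$truth$flagged[el])
  fit <- suppressWarnings(glm(y ~ x, family = binomial))
  est <- coef(fit)[-1]
  expect_gte(cor(est, w, method = "spearman"), 0.9)
  expect_true(all(sign(est[abs(w) > 0.2]) == sign(w[abs(w) > 0.2])))
})

test_that("cohorts round-trip through the CSV/JSONL directory format", {
  coh <- generate_cohort(cohort_config(n_patients = 25, seed = 4))
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "admissions.csv", "demographics.csv", "diagnoses.csv", "labs.csv",
    "medications.csv", "procedures.csv", "notes.jsonl", "config.json")))))
  back <- read_cohort(dir)
  expect_equal(back$admissions, coh$admissions)
  expect_equal(back$notes$text, coh$notes$text)
  expect_equal(back$config$linear_weights, coh$config$linear_weights)
  expect_identical(generate_cohort(back$config), coh)
  unlink(dir, recursive = TRUE)
})
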