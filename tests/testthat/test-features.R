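test_that("note sections are retained at the 50% presence boundary", {
  mk <- function(section, ids) data.frame(
    admission_id = ids, note_type = "discharge_summary",
    section = section, stringsAsFactors = FALSE)
  ids <- sprintf("a%02d", 1:10)
  notes <- rbind(mk("anchor", ids),          # defines the 10 documents
                 mk("half", ids[1:5]),       # 5 of 10 -> retained
                 mk("rare", ids[1:4]),       # 4 of 10 -> dropped
                 mk("universal", ids))
  kept <- select_note_sections(notes)
  expect_setequal(kept$section, c("anchor", "half", "universal"))
  expect_equal(nrow(select_note_sections(notes[0, ])), 0)
})

test_that("bag-of-words applies the corpus frequency cutoff at 5", {
  docs <- list(d1 = c(rep("five", 3), rep("six", 3), "once"),
               d2 = c(rep("five", 2), rep("six", 3)),
               d3 = character(0))
  bow <- build_bow(docs)
  expect_setequal(colnames(bow), c("six.count", "six.bin"))
  expect_equal(unname(bow["d1", "six.count"]), 3)
  expect_equal(unname(bow["d2", "six.bin"]), 1)
  expect_equal(unname(bow["d3", ]), c(0, 0))
  # a word reaching exactly 6 via the normalizer is kept
  docs2 <- list(d = c("Mixed", "mixed", "MIXED", "mixed", "mixed", "mixed"))
  expect_setequal(colnames(build_bow(docs2)),
                  c("mixed.count", "mixed.bin"))
})

test_that("lab and diagnosis windows clip events as specified", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 2,
                                       n_continuous_vars = 1))
  lab <- label_readmissions(coh)
  first <- which(lab$is_countable)[1]
  # pin a 20-day stay so the admit-side and discharge-side windows are
  # disjoint, then craft events around the window edges
  lab$admit_date[first] <- 100
  lab$discharge_date[first] <- 120
  adm <- lab[first, ]
  coh$labs <- data.frame(
    admission_id = adm$admission_id, code = "L01",
    event_date = c(107,   # admit + 7: inside the admit-side window
                   108,   # admit + 8: outside both windows
                   113,   # discharge - 7: inside the discharge-side window
                   121),  # past discharge
    abnormal = TRUE, stringsAsFactors = FALSE)
  coh$diagnoses <- data.frame(
    admission_id = adm$admission_id, code = "D001",
    event_date = c(adm$discharge_date - 365,  # one year back: counted
                   adm$discharge_date - 731), # beyond two years: not
    stringsAsFactors = FALSE)
  feats <- extract_features(coh, lab)
  row <- which(feats$row_keys == adm$admission_id)
  expect_equal(feats$data$lab_admit_L01[row], 1)
  expect_equal(feats$data$lab_discharge_L01[row], 1)
  expect_equal(feats$data$dx_D001[row], 1)
  expect_true(all(feats$data$dx_D001[-row] == 0))
})

test_that("medication counts and lookup mapping work within the stay", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 2))
  lab <- label_readmissions(coh)
  adm <- lab[lab$is_countable, ][1, ]
  coh$medications <- data.frame(
    admission_id = adm$admission_id, code = c("drugA", "drugA", "drugA"),
    event_date = adm$admit_date, stringsAsFactors = FALSE)
  lk <- data.frame(source_code = "drugA", target_code = "ATC1")
  feats <- suppressMessages(
    extract_features(coh, lab, lookups = list(medications = lk)))
  row <- which(feats$row_keys == adm$admission_id)
  expect_equal(feats$data$med_ATC1[row], 3)
  expect_false("med_drugA" %in% names(feats$data))
})

test_that("encoding one-hot-expands, zero-fills and min-max scales", {
  df <- data.frame(num = c(2, 4, 6), cat = c("A", "B", "C"),
                   miss = c(NA, 1, NA), stringsAsFactors = FALSE)
  x <- encode_and_scale(df)
  expect_equal(unname(x[, "num"]), c(0, 0.5, 1))
  expect_equal(unname(x[, "cat.B"]), c(0, 1, 0))
  expect_equal(sum(x[1, c("cat.A", "cat.B", "cat.C")]), 1)
  expect_equal(unname(x[, "miss"]), c(0, 1, 0))   # NA -> 0, then scaled
  # all-missing column collapses to zeros
  x2 <- encode_and_scale(data.frame(empty = c(NA_real_, NA_real_)))
  expect_true(all(x2 == 0))
  # idempotence: scaling a scaled matrix changes nothing
  rescaled <- encode_and_scale(as.data.frame(x))
  expect_equal(as.numeric(rescaled), as.numeric(x))
  expect_equal(colnames(rescaled), colnames(x))
  # column count after one-hot equals the sum of cardinalities
  expect_equal(ncol(x), 1 + 3 + 1)
})

test_that("held-out data is scaled by training parameters and clipped", {
  enc <- fit_encoder(data.frame(v = c(0, 10)))
  out <- apply_encoder(enc, data.frame(v = c(-5, 5, 20)))
  expect_equal(unname(out[, 1]), c(0, 0.5, 1))
})

test_that("total KL divergence matches the hand-derived Bernoulli value", {
  # class rates 0.8 vs 0.2 -> D = 2 * 0.6 * ln 4 (no smoothing)
  v <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  y <- rep(c(1, 0), each = 10)
  d <- total_kl_divergence(cbind(v = v), y, eps = 0)$divergence
  expect_equal(unname(d), 2 * 0.6 * log(4), tolerance = 1e-12)
  # identical class rates -> D = 0
  same <- rep(c(1, 0), 10)
  expect_equal(unname(total_kl_divergence(cbind(s = same), y)$divergence), 0,
               tolerance = 1e-6)
})

test_that("KL report agrees with an independent recomputation", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 40
    p <- sample(2:10, 1)
    x <- sapply(seq_len(p), function(j) {
      if (runif(1) < 0.5) rbinom(n, 1, runif(1, 0.2, 0.8)) else runif(n)
    })
    colnames(x) <- paste0("V", seq_len(p))
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    rep_out <- total_kl_divergence(x, y)
    want <- vapply(seq_len(p), function(j) oracle_total_kl(x[, j], y),
                   numeric(1))
    expect_equal(unname(rep_out$divergence), want, tolerance = 1e-10)
    tau <- mean(want) + 0.5 * sd(want)
    expect_equal(rep_out$threshold, tau, tolerance = 1e-10)
    expect_equal(unname(rep_out$keep_mask), want >= tau)
  }
})

test_that("KL divergence is symmetric in the class labels and nonnegative", {
  set.seed(23)
  x <- cbind(a = rbinom(30, 1, 0.5), b = runif(30))
  y <- c(0, 1, rbinom(28, 1, 0.5))
  d1 <- total_kl_divergence(x, y)$divergence
  d2 <- total_kl_divergence(x, 1 - y)$divergence
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_true(all(d1 >= 0))
  expect_error(total_kl_divergence(x, rep(1, 30)), "both classes")
})

test_that("shifting every divergence equally leaves the keep mask fixed", {
  d <- c(0.1, 0.5, 0.9, 0.2, 0.7)
  mask <- d >= mean(d) + 0.5 * sd(d)
  d2 <- d + 3
  expect_equal(d2 >= mean(d2) + 0.5 * sd(d2), mask)
})

test_that("planted signal outranks noise through the full pipeline", {
  cfg <- cohort_config(n_patients = 900, mean_admissions_per_patient = 4,
                       n_binary_codes = 10, n_continuous_vars = 2,
                       n_note_tokens = 40,
                       linear_weights = c(3, rep(0, 11)),
                       nonlinear_pairs = matrix(numeric(0), ncol = 3),
                       noise_sd = 0.2, seed = 51)
  coh <- generate_cohort(cfg)
  lab <- label_readmissions(coh)
  feats <- extract_features(coh, lab)
  x <- encode_and_scale(feats$data)
  kl <- total_kl_divergence(x, feats$labels)
  d <- kl$divergence
  # the diagnosis code planted on the weight-3 covariate beats the
  # pure-noise diagnosis columns (weights 6..10 are zero)
  noise_cols <- paste0("dx_D", sprintf("%03d", 6:10))
  expect_true(all(d["dx_D001"] > d[noise_cols]))
})
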