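make_calls <- function(det, genes, samples) {
  # det: logical genes x samples detection pattern
  m <- matrix(ifelse(det, "positive", "negative"), length(genes),
              dimnames = list(genes, samples))
  m
}

test_that("CTC status flags follow the detected-marker count thresholds", {
  genes <- c("EpCAM", "TWIST1", "MET", "KRT5", "VEGFC", "CCND1", "TFRC",
             "KRT18", "FSCN1", "ECT2")
  det <- matrix(FALSE, 10, 3, dimnames = list(genes, c("a", "b", "c")))
  det[c("MET", "KRT5"), "a"] <- TRUE                   # 2 detected
  det[c("EpCAM", "TWIST1"), "c"] <- TRUE               # hybrid pair
  st <- classify_samples(make_calls(det, genes, c("a", "b", "c")), genes)
  expect_equal(st$n_detected, c(2, 0, 2))
  expect_equal(st$ctc_positive, c(TRUE, FALSE, TRUE))
  expect_equal(st$ctc_high, c(FALSE, FALSE, FALSE))
  expect_equal(st$hybrid_emt, c(FALSE, FALSE, TRUE))
  expect_error(classify_samples(make_calls(det, genes, letters[1:3]),
                                c(genes, "MISSING")), "MISSING")
})

test_that("a high call counts as detected and hybrid-EMT accepts high + positive", {
  genes <- c("EpCAM", "TWIST1", "MET")
  m <- matrix("negative", 3, 1, dimnames = list(genes, "s"))
  m["EpCAM", ] <- "high"; m["TWIST1", ] <- "positive"
  st <- classify_samples(m, genes)
  expect_equal(st$n_detected, 2)
  expect_true(st$ctc_positive && st$hybrid_emt)
  expect_false(st$ctc_high)
})

test_that("CTC-high and hybrid-EMT are subsets of CTC-positive on synthetic cohorts", {
  for (s in 1:5) {
    co <- gen_cohort(sim_config(seed = s))
    st <- classify_cohort(co)
    expect_true(all(st$ctc_positive[st$ctc_high]))
    expect_true(all(st$ctc_positive[st$hybrid_emt]))
    # raising k_high never increases the CTC-high count
    st6 <- classify_cohort(co, k_high = 6)
    expect_lte(sum(st6$ctc_high), sum(st$ctc_high))
  }
})

test_that("ROC sensitivity and specificity match confusion-matrix enumeration at every threshold", {
  set.seed(17)
  n_det <- sample(0:10, 20, replace = TRUE)
  outcome <- rbinom(20, 1, 0.4)
  if (length(unique(outcome)) < 2) outcome[1:2] <- c(0, 1)
  roc <- roc_threshold(n_det, outcome, k_max = 10)
  for (k in 0:10) {
    pred <- n_det >= k
    tp <- sum(pred & outcome == 1); fn <- sum(!pred & outcome == 1)
    tn <- sum(!pred & outcome == 0); fp <- sum(pred & outcome == 0)
    row <- roc$thresholds[roc$thresholds$k == k, ]
    expect_equal(row$sensitivity, tp / (tp + fn))
    expect_equal(row$specificity, tn / (tn + fp))
  }
  # monotonicity of the ROC coordinates in k
  expect_true(all(diff(roc$thresholds$sensitivity) <= 0))
  expect_true(all(diff(roc$thresholds$specificity) >= 0))
  expect_true(roc$auc >= 0 && roc$auc <= 1)
})

test_that("perfect separation yields J = 1 at the smallest separating threshold and AUC = 1", {
  n_det <- c(5, 6, 7, 0, 1, 2)
  outcome <- c(1, 1, 1, 0, 0, 0)
  roc <- roc_threshold(n_det, outcome, k_max = 7)
  expect_equal(max(roc$thresholds$youden_j), 1)
  expect_equal(roc$chosen_k, 3)
  expect_equal(roc$auc, 1)
  # uninformative predictor: every sample the same count
  roc0 <- roc_threshold(rep(4, 6), outcome, k_max = 10)
  expect_equal(roc0$auc, 0.5)
  expect_equal(max(roc0$thresholds$youden_j), 0)
  expect_error(roc_threshold(n_det, rep(1, 6)), "classes")
})

test_that("AUC equals the Mann-Whitney U statistic over case-control pairs", {
  set.seed(29)
  for (i in 1:10) {
    n_det <- sample(0:10, 30, replace = TRUE)
    outcome <- rbinom(30, 1, 0.5)
    if (length(unique(outcome)) < 2) next
    roc <- roc_threshold(n_det, outcome, k_max = 10)
    cases <- n_det[outcome == 1]; controls <- n_det[outcome == 0]
    u <- sum(vapply(cases, function(x)
      sum(x > controls) + 0.5 * sum(x == controls), numeric(1)))
    expect_equal(roc$auc, u / (length(cases) * length(controls)),
                 tolerance = 1e-12)
  }
})

test_that("trajectories report the sign of the count change and per-arm decrease fractions", {
  st <- data.frame(sample_id = c("P1_BL", "P1_FU", "P2_BL", "P2_FU",
                                 "P3_BL", "P3_FU", "P4_FU"),
                   n_detected = c(6, 2, 3, 3, 1, 4, 2),
                   ctc_positive = TRUE, ctc_high = FALSE, hybrid_emt = FALSE)
  samples <- data.frame(
    sample_id = st$sample_id,
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P4"),
    timepoint = c("baseline", "preIII", "baseline", "postop", "baseline",
                  "preIII", "preIII"),
    role = "case", stringsAsFactors = FALSE)
  expect_warning(tr <- marker_trajectory(st, samples), "P4")
  expect_equal(tr$trajectories$direction, c("decrease", "unchanged",
                                            "increase"))
  expect_equal(tr$summary$frac_decrease, 1 / 3)
})

test_that("a 5-of-9 decreasing palliative arm reports fraction 0.556", {
  n <- 9
  st <- data.frame(
    sample_id = c(sprintf("P%d_BL", 1:n), sprintf("P%d_FU", 1:n)),
    n_detected = c(rep(6, n), c(2, 2, 2, 2, 2, 8, 8, 6, 6)),
    ctc_positive = TRUE, ctc_high = FALSE, hybrid_emt = FALSE)
  samples <- data.frame(
    sample_id = st$sample_id,
    patient_id = rep(sprintf("P%d", 1:n), 2),
    timepoint = rep(c("baseline", "preIII"), each = n),
    role = "case", stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = sprintf("P%d", 1:n),
                         treatment_arm = "palliative")
  tr <- marker_trajectory(st, samples, patients)
  expect_equal(tr$summary$arm, "palliative")
  expect_equal(tr$summary$n_decrease, 5)
  expect_equal(round(tr$summary$frac_decrease, 3), 0.556)
})

test_that("cohort summary saturates at 100% and 0% in the degenerate cases", {
  genes <- sprintf("g%d", 1:10)
  samples <- data.frame(sample_id = c("a", "b"), patient_id = c("P1", "P2"),
                        timepoint = "baseline", role = "case")
  all_det <- matrix("high", 10, 2, dimnames = list(genes, c("a", "b")))
  st <- suppressWarnings(classify_samples(all_det, genes))
  summ <- summarize_cohort(st, samples)
  expect_equal(summ$sample_level$ctc_positive_rate, 1)
  expect_equal(summ$patient_level$ctc_high_rate, 1)
  none <- matrix("negative", 10, 2, dimnames = list(genes, c("a", "b")))
  st0 <- suppressWarnings(classify_samples(none, genes))
  expect_equal(summarize_cohort(st0, samples)$sample_level$ctc_positive_rate,
               0)
  expect_error(summarize_cohort(st0[0, ], samples), "empty")
})
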