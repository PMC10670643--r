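test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(censor_time = 0), "censor_time")
  expect_error(sim_config(marker_fraction = 1.5), "rates")
  expect_error(sim_config(nb_mean_tumor = 0), "positive")
  expect_error(sim_config(arm_fractions = c(palliative = 0.5,
                                            curative = 0.3)), "sum to 1")
})

test_that("identical configs give byte-identical serialized outputs", {
  cfg <- sim_config(seed = 1)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("substreams decouple the generators from one another", {
  cfg <- sim_config(seed = 5)
  co1 <- gen_cohort(cfg)
  invisible(gen_single_cell_counts(cfg))  # interleaved other generator
  co2 <- gen_cohort(cfg)
  expect_identical(co1, co2)
})

test_that("marker bookkeeping follows the configured fraction", {
  cfg <- sim_config(marker_fraction = 0.25, n_genes = 40)
  sc <- gen_single_cell_counts(cfg)
  expect_length(sc$ground_truth$true_marker_genes, 10)
  expect_equal(dim(sc$counts),
               c(40, cfg$n_pbmc_cells + cfg$n_tumor_cells))
  expect_true(all(sc$counts >= 0) && all(sc$counts == round(sc$counts)))
  # zero PBMC mean forces markers through the stage-1 filter
  cfg0 <- sim_config(nb_mean_pbmc = 0)
  sc0 <- gen_single_cell_counts(cfg0)
  res <- filter_by_singlecell(sc0$counts, sc0$populations)
  mk <- res$gene %in% sc0$ground_truth$true_marker_genes
  expect_true(all(res$mean_pbmc[mk] == 0))
  expect_true(all(res$pass[mk]))
})

test_that("Ct encodes log2 template abundance with the stated clipping and missing rules", {
  cfg <- sim_config(seed = 2, ct_noise_sd = 0)
  set.seed(1)
  ct1 <- ctcpanel:::ct_from_abundance(c(64, 128, 0, NA, 2^40), 38, 0)
  expect_equal(ct1[2], ct1[1] - 1)       # doubling lowers Ct by one cycle
  expect_true(is.na(ct1[3]))             # zero template -> Undetermined
  expect_true(is.na(ct1[4]))
  expect_equal(ct1[5], 10)               # clipped at the low end
  expect_true(is.na(ctcpanel:::ct_from_abundance(2^-10, 38, 0)))  # > 40
})

test_that("spike-in layout carries every requested level per cell line", {
  cfg <- sim_config(seed = 3)
  sp <- gen_ct_tables(cfg, "spike_in", spike_levels = c(5, 50, 500, 5000))
  for (cl in cfg$cell_lines) {
    lev <- unique(sp$manifest$spike_cells[sp$manifest$cell_line == cl])
    expect_setequal(lev, c(0, 5, 50, 500, 5000))
  }
  expect_setequal(sp$manifest$sample_id, colnames(sp$ct$ct))
  expect_true(all(!is.na(sp$ct$ct["GAPDH", ])))
})

test_that("pure and pilot layouts include the reference gene in every sample", {
  cfg <- sim_config(seed = 8)
  for (design in c("pure", "pilot")) {
    tab <- gen_ct_tables(cfg, design)
    expect_true(all(!is.na(tab$ct$ct[cfg$reference_gene, ])))
    expect_s3_class(tab$ct, "ct_table")
  }
})

test_that("latent burden prevalence obeys the law of large numbers", {
  cfg <- sim_config(seed = 13, n_patients = 10000, burden_prevalence = 0.5)
  co <- gen_cohort(cfg)
  sd3 <- 3 * sqrt(0.25 / 10000)
  expect_lt(abs(mean(co$ground_truth$burden) - 0.5), sd3)
})

test_that("cohort structure matches the configured arms, pairing and schema", {
  cfg <- sim_config(seed = 6)
  co <- gen_cohort(cfg)
  expect_equal(nrow(co$patients), 55)
  expect_equal(sum(co$patients$treatment_arm == "palliative"), 24)
  fup <- co$samples[co$samples$timepoint != "baseline", ]
  expect_equal(nrow(fup), 22)
  arm <- co$patients$treatment_arm[match(fup$patient_id,
                                         co$patients$patient_id)]
  expect_true(all(fup$timepoint[arm == "palliative"] == "preIII"))
  expect_true(all(fup$timepoint[arm == "curative"] == "postop"))
  expect_true(all(co$patients$os_days > 0))
  expect_true(all(co$patients$os_event %in% 0:1))
  # written cohort passes the schema validator
  d <- file.path(tempdir(), "cohort_schema")
  write_cohort(co$patients, co$samples, d)
  expect_silent(read_cohort(d))
  unlink(d, recursive = TRUE)
})

test_that("a null burden effect leaves the survival arms exchangeable", {
  ps <- vapply(1:20, function(s) {
    co <- gen_cohort(sim_config(seed = s, log_hr_ctc_high = 0))
    g <- unname(co$ground_truth$burden) == 1
    if (length(unique(g)) < 2) return(NA_real_)
    logrank_test(co$patients$os_days, co$patients$os_event, g)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  # p-values behave like draws from a uniform: no mass piled near zero
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("default cohort is calibrated to the published CTC-positive rate", {
  # 60 replicate cohorts: enough pooled patients that the binomial interval
  # reflects calibration error rather than Monte Carlo luck
  rates <- vapply(1:60, function(s) {
    co <- gen_cohort(sim_config(seed = s))
    st <- classify_cohort(co)
    summarize_cohort(st, co$samples)$patient_level$ctc_positive_rate
  }, numeric(1))
  n <- 60 * 55
  half <- 1.96 * sqrt(0.836 * (1 - 0.836) / n)
  expect_lt(abs(mean(rates) - 0.836), half)
})
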