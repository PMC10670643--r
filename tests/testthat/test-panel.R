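test_that("single-cell filter keeps PBMC-silent, tumor-expressed genes", {
  counts <- rbind(A = c(0, 0, 4, 4),   # PBMC mean 0, tumor mean 4 -> kept
                  B = c(1, 1, 4, 4),   # PBMC mean 1 -> excluded
                  C = c(0, 0, 1, 0))   # tumor mean 0.5 -> excluded
  colnames(counts) <- c("p1", "p2", "t1", "t2")
  pops <- c(p1 = "PBMC", p2 = "PBMC", t1 = "tumor", t2 = "tumor")
  res <- filter_by_singlecell(counts, pops, pbmc_max = 0.10, tumor_min = 1.0)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE))
  expect_equal(res$mean_pbmc, c(0, 1, 0))
  expect_error(filter_by_singlecell(counts, c(p1 = "PBMC", p2 = "PBMC",
                                              t1 = "x", t2 = "x")),
               "population")
})

test_that("single-cell filter boundary semantics are strict on both sides", {
  counts <- rbind(EXACT_PBMC = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 30, 30),
                  EXACT_TUM = c(rep(0, 10), 1, 1),
                  GOOD = c(rep(0, 10), 3, 3))
  colnames(counts) <- sprintf("c%d", 1:12)
  pops <- rep(c("PBMC", "tumor"), c(10, 2))
  res <- filter_by_singlecell(counts, pops)
  # PBMC mean exactly 0.10 fails the strict <; tumor mean exactly 1.0 fails >
  expect_equal(res$pass, c(FALSE, FALSE, TRUE))
})

test_that("Ct filter excludes PBMC-enriched and tumor-low genes", {
  pb <- c(a = 28, b = 35, c = 35, d = NA, e = 31)
  tu <- c(a = 22, b = 32, c = 22, d = 25, e = NA)
  res <- filter_by_ct(pb, tu, cutoff = 30)
  res <- res[match(letters[1:5], res$gene), ]
  # a: PBMC 28 < 30 excluded; b: tumor 32 > 30 excluded; c: kept;
  # d: PBMC undetected is fine -> kept; e: tumor undetected -> excluded
  expect_equal(res$pass, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_error(filter_by_ct(pb, tu, genes = c("a", "zz")), "zz")
})

test_that("spike-in filter requires detection at the required level in every cell line", {
  genes <- c("both", "one_line", "high_only")
  samples <- c("L1_500", "L2_500", "L1_5000", "L2_5000")
  calls <- matrix("negative", 3, 4, dimnames = list(genes, samples))
  calls["both", c("L1_500", "L2_500")] <- "positive"
  calls["one_line", "L1_500"] <- "high"
  calls["high_only", c("L1_5000", "L2_5000")] <- "positive"
  manifest <- data.frame(sample_id = samples,
                         cell_line = rep(c("L1", "L2"), 2),
                         spike_cells = rep(c(500, 5000), each = 2))
  res <- filter_by_spikein(calls, manifest, required_level = 500)
  expect_equal(res$pass[match(genes, res$gene)], c(TRUE, FALSE, FALSE))
  expect_error(filter_by_spikein(calls, manifest, required_level = 50),
               "50")
})

test_that("pilot positivity keeps the closed 30% boundary", {
  genes <- c("low", "boundary", "ok")
  calls <- matrix("negative", 3, 10, dimnames = list(genes, sprintf("s%d", 1:10)))
  calls["low", 1:2] <- "positive"        # 20%
  calls["boundary", 1:3] <- "positive"   # exactly 30% -> kept
  calls["ok", 1:5] <- c("positive", "high", "positive", "high", "positive")
  res <- filter_by_pilot_positivity(calls, min_rate = 0.30)
  expect_equal(res$pass, c(FALSE, TRUE, TRUE))
  expect_equal(res$rate, c(0.2, 0.3, 0.5))
  expect_error(filter_by_pilot_positivity(calls[, 0]), "pilot")
})

test_that("pilot rates like 4/14 and 5/14 fall on the right side of 30%", {
  calls <- matrix("negative", 2, 14,
                  dimnames = list(c("g4", "g5"), sprintf("s%d", 1:14)))
  calls["g4", 1:4] <- "positive"   # 28.6% -> excluded
  calls["g5", 1:5] <- "positive"   # 35.7% -> kept
  res <- filter_by_pilot_positivity(calls)
  expect_equal(res$pass, c(FALSE, TRUE))
})

test_that("the cascade recovers the ground-truth panel with a complete audit trail", {
  out <- derive_panel_from_sim(sim_config(seed = 4))
  expect_setequal(out$panel$genes, out$truth$true_marker_genes)
  audit <- out$panel$audit
  # every candidate appears exactly once with a terminal status
  expect_equal(sort(audit$gene), sort(names(out$truth$gene_roles)))
  expect_true(all(audit$status %in% c("panel", "excluded")))
  # each decoy class is eliminated at its engineered stage
  roles <- out$truth$gene_roles[audit$gene]
  stage_of <- c(sc_fail = "single_cell", ct_fail = "ct_filter",
                spike_fail = "spike_in", pilot_fail = "pilot")
  decoys <- roles != "marker"
  expect_equal(unname(audit$eliminated_at[decoys]),
               unname(stage_of[roles[decoys]]))
  # panel genes passed all four stages
  pg <- audit[audit$status == "panel", ]
  expect_true(all(pg$pass_single_cell & pg$pass_ct_filter &
                    pg$pass_spike_in & pg$pass_pilot))
})

test_that("stage subsets are anti-monotone and stages 1-2 commute", {
  cfg <- sim_config(seed = 9)
  sc <- gen_single_cell_counts(cfg)
  pure <- gen_ct_tables(cfg, "pure")
  cand <- setdiff(rownames(pure$ct$ct), "GAPDH")
  s1 <- filter_by_singlecell(sc$counts, sc$populations)
  s2 <- filter_by_ct(pure$ct$ct[cand, "PBMC"], pure$ct$ct[cand, "KYSE270"])
  keep1 <- s1$gene[s1$pass]; keep2 <- s2$gene[s2$pass]
  # 1 then 2 equals 2 then 1: both are per-gene predicates
  expect_setequal(intersect(keep1, keep2), intersect(keep2, keep1))
  expect_true(all(keep1 %in% s1$gene))
  # cascade output is a subset of every stage's survivors
  out <- derive_panel_from_sim(cfg)
  expect_true(all(out$panel$genes %in% keep1))
  expect_true(all(out$panel$genes %in% keep2))
})

test_that("an empty final panel aborts naming the fatal stage", {
  counts <- rbind(A = c(5, 5, 0, 0), B = c(4, 4, 0, 0))
  colnames(counts) <- c("p1", "p2", "t1", "t2")
  pops <- c("PBMC", "PBMC", "tumor", "tumor")
  expect_error(
    derive_panel(counts, pops, ct_pbmc = c(A = 35, B = 35),
                 ct_tumor = c(A = 22, B = 22),
                 spike_calls = matrix("positive", 2, 1,
                                      dimnames = list(c("A", "B"), "x")),
                 spike_manifest = data.frame(sample_id = "x",
                                             cell_line = "L",
                                             spike_cells = 500),
                 pilot_calls = matrix("positive", 2, 1,
                                      dimnames = list(c("A", "B"), "p"))),
    "single_cell")
})
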