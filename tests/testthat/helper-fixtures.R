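# shared fixtures, all built in code

# small random Ct table: reference gene well detected in every sample
random_ct_table <- function(n_genes = 5, n_samples = 4, ref = "GAPDH") {
  genes <- c(ref, sprintf("G%02d", seq_len(n_genes)))
  m <- matrix(stats::runif(length(genes) * n_samples, 18, 36),
              length(genes), n_samples,
              dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
  m[ref, ] <- stats::runif(n_samples, 18, 24)
  ct_table(m, ref)
}

# quantify + classify a generated cohort with the ground-truth panel
classify_cohort <- function(cohort, k_pos = 2, k_high = 5) {
  dct <- delta_ct(cohort$ct)
  hd <- cohort$samples$sample_id[cohort$samples$role == "healthy_control"]
  cal <- calibrator_delta_ct(dct, hd)
  fc <- fold_change(dct, cal)
  calls <- call_markers(fc[setdiff(rownames(fc), cohort$ct$reference_gene), ,
                           drop = FALSE])
  classify_samples(calls, cohort$ground_truth$true_marker_genes,
                   k_pos = k_pos, k_high = k_high)
}

# run the four-stage cascade on generated screen/spike/pilot data
derive_panel_from_sim <- function(config, tumor_line = "KYSE270") {
  ref <- config$reference_gene
  sc <- gen_single_cell_counts(config)
  pure <- gen_ct_tables(config, "pure")
  spike <- gen_ct_tables(config, "spike_in")
  pilot <- gen_ct_tables(config, "pilot")
  sdct <- delta_ct(spike$ct)
  scal <- calibrator_delta_ct(
    sdct, spike$manifest$sample_id[spike$manifest$spike_cells == 0])
  spike_calls <- call_markers(fold_change(sdct, scal))
  pdct <- delta_ct(pilot$ct)
  hd <- pilot$manifest$sample_id[pilot$manifest$role == "healthy_control"]
  pcal <- calibrator_delta_ct(pdct, hd)
  pilot_calls <- call_markers(
    fold_change(pdct, pcal)[setdiff(rownames(pdct), ref),
                            setdiff(colnames(pdct), hd), drop = FALSE])
  cand <- setdiff(rownames(pure$ct$ct), ref)
  list(panel = derive_panel(sc$counts, sc$populations,
                            ct_pbmc = pure$ct$ct[cand, "PBMC"],
                            ct_tumor = pure$ct$ct[cand, tumor_line],
                            spike_calls = spike_calls,
                            spike_manifest = spike$manifest,
                            pilot_calls = pilot_calls),
       truth = sc$ground_truth)
}

# brute-force two-sided Fisher p by enumeration over tables with fixed
# margins, point probabilities from choose() -- independent of dhyper
fisher_oracle <- function(tab, tie_tol = 1e-7) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- sum(tab)
  lo <- max(0, r1 - c2); hi <- min(r1, c1)
  prob <- function(x) choose(c1, x) * choose(c2, r1 - x) / choose(n, r1)
  probs <- vapply(lo:hi, prob, numeric(1))
  p_obs <- probs[a - lo + 1]
  included <- probs <= p_obs * (1 + tie_tol)
  list(p = min(sum(probs[included]), 1), included_a = (lo:hi)[included],
       p_obs = p_obs)
}
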