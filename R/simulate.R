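#' Simulation configuration for a synthetic CTC study
#'
#' Bundles every tunable of the synthetic-data generators: the single-cell
#' screen (negative-binomial counts for a PBMC background and a tumor
#' population), the RT-qPCR layer (Ct values falling log2-linearly with
#' template abundance plus Gaussian cycle noise, clipped to the instrument
#' range), and the patient cohort (treatment arms, a binary latent CTC
#' burden driving marker fold changes, and proportional-hazards survival
#' times with administrative censoring).
#'
#' Defaults emulate the structure of a 55-patient esophageal cancer liquid
#' biopsy study: a 24/31 palliative/curative split, 22/55 paired follow-up
#' samples, five healthy-donor controls, a 14-sample pilot study, and
#' spike-in series of two tumor cell lines into 50,000 PBMCs. The
#' fold-change means are calibrated so the downstream classifier labels
#' about 83.6% of patients CTC-positive and about half CTC-high at baseline.
#'
#' @param seed integer master seed; each generator draws from a named
#'   substream so outputs are reproducible and independent of generator
#'   order.
#' @param n_pbmc_cells,n_tumor_cells cells per population in the single-cell
#'   screen.
#' @param n_genes number of candidate genes.
#' @param marker_fraction fraction of candidates that are true CTC markers.
#' @param nb_mean_pbmc,nb_mean_tumor negative-binomial mean counts of a true
#'   marker in PBMCs and tumor cells.
#' @param nb_dispersion negative-binomial size parameter k
#'   (variance = mu + mu^2 / k).
#' @param ct_intercept Ct at unit relative template abundance (cycles).
#' @param ct_noise_sd Gaussian measurement noise on Ct (cycles).
#' @param n_patients cohort size (>= 2).
#' @param arm_fractions named fractions for the palliative/curative split.
#' @param burden_prevalence fraction of patients with high latent CTC
#'   burden.
#' @param fc_mu_pos,fc_mu_neg mean per-gene log2 fold change (vs the
#'   healthy-donor calibrator) under high and low burden.
#' @param fc_sd SD of the per-gene log2 fold change.
#' @param hazard_baseline baseline overall-survival hazard (events/day) for
#'   low-burden patients.
#' @param log_hr_ctc_high log hazard ratio of high vs low latent burden.
#' @param pfs_hazard_ratio multiplier of `hazard_baseline` for the
#'   progression hazard (progression precedes death).
#' @param censor_time administrative censoring time (days, > 0).
#' @param paired_fraction fraction of patients with a paired follow-up
#'   sample.
#' @param followup_lfc_shift mean drop in log2 fold change at the follow-up
#'   time point (treatment effect).
#' @param n_healthy_donors,n_pilot_samples control and pilot sample counts.
#' @param spike_levels spiked tumor-cell numbers per series (must include
#'   the level required by the spike-in filter, 500 by default).
#' @param spike_pbmc PBMC background per spike-in reaction.
#' @param cell_lines names of the spike-in tumor cell lines.
#' @param reference_gene housekeeping reference gene name.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_pbmc_cells = 600L, n_tumor_cells = 300L,
                       n_genes = 40L, marker_fraction = 0.25,
                       nb_mean_pbmc = 0.02, nb_mean_tumor = 5,
                       nb_dispersion = 2,
                       ct_intercept = 38, ct_noise_sd = 0.25,
                       n_patients = 55L,
                       arm_fractions = c(palliative = 24 / 55,
                                         curative = 31 / 55),
                       burden_prevalence = 28 / 55,
                       fc_mu_pos = 2.1, fc_mu_neg = 0.19, fc_sd = 1,
                       hazard_baseline = log(2) / 300,
                       log_hr_ctc_high = log(2.6),
                       pfs_hazard_ratio = 2,
                       censor_time = 730,
                       paired_fraction = 22 / 55,
                       followup_lfc_shift = 0.6,
                       n_healthy_donors = 5L, n_pilot_samples = 14L,
                       spike_levels = c(5, 50, 500),
                       spike_pbmc = 50000,
                       cell_lines = c("KYSE30", "KYSE270"),
                       reference_gene = "GAPDH") {
  cfg <- as.list(environment())
  with(cfg, {
    if (n_pbmc_cells < 1 || n_tumor_cells < 1 || n_genes < 1)
      stop("cell and gene counts must be positive")
    if (n_patients < 2) stop("n_patients must be >= 2")
    if (censor_time <= 0) stop("censor_time must be positive")
    rates <- c(marker_fraction, burden_prevalence, paired_fraction,
               arm_fractions)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (abs(sum(arm_fractions) - 1) > 1e-8)
      stop("arm_fractions must sum to 1")
    if (nb_mean_pbmc < 0 || nb_mean_tumor <= 0 || nb_dispersion <= 0 ||
        hazard_baseline <= 0 || ct_noise_sd < 0)
      stop("means, dispersion and hazards must be positive")
  })
  structure(cfg, class = "sim_config")
}

# Deterministic per-generator seed derived from the master seed, so that
# adding a generator never shifts the draws of another.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 59999
  as.integer((abs(as.integer(seed)) %% 30000) * 60000 + h)
}

# role catalog for the candidate genes: true markers plus decoys, each decoy
# engineered to violate exactly one cascade stage
gene_catalog <- function(config) {
  pools <- list(
    marker = c("CCND1", "ECT2", "EpCAM", "FSCN1", "KRT5", "KRT18", "MET",
               "TFRC", "TWIST1", "VEGFC"),
    sc_fail = c("PTPRC", "CD3E", "CD14", "MS4A1", "HBB", "LYZ", "NKG7",
                "ITGAM"),
    ct_fail = c("EGFR", "KRT8", "LEF1", "MYL9", "TGFB1", "VIM", "XPO1",
                "CTNNB1", "DKK3", "MMP3", "SERPINE1", "SNAI1"),
    spike_fail = c("FAT1", "IL12B", "FN1", "CDH2"),
    pilot_fail = c("CDH1", "GATA4", "CCNE1", "MUC1", "KRT19", "SNAI2",
                   "KRT14"))
  n_marker <- round(config$n_genes * config$marker_fraction)
  n_decoy <- config$n_genes - n_marker
  take <- function(role, n) {
    pool <- pools[[role]]
    nm <- if (n <= length(pool)) pool[seq_len(n)] else
      c(pool, sprintf("%s_X%02d", toupper(role), seq_len(n - length(pool))))
    if (n == 0) character(0) else nm[seq_len(n)]
  }
  decoy_roles <- c("sc_fail", "ct_fail", "spike_fail", "pilot_fail")
  # spread decoys over the failure classes in proportion to the pool sizes
  quota <- c(sc_fail = 8, ct_fail = 12, spike_fail = 4, pilot_fail = 7)
  alloc <- pmin(quota, n_decoy)  # greedy by class order
  while (sum(alloc) > n_decoy) {
    k <- which.max(alloc)
    alloc[k] <- alloc[k] - 1L
  }
  while (sum(alloc) < n_decoy) {
    k <- which.min(alloc)
    alloc[k] <- alloc[k] + 1L
  }
  genes <- c(take("marker", n_marker),
             unlist(lapply(decoy_roles, function(r) take(r, alloc[[r]])),
                    use.names = FALSE))
  roles <- c(rep("marker", n_marker),
             rep(decoy_roles, times = alloc[decoy_roles]))
  data.frame(gene = genes, role = roles, stringsAsFactors = FALSE)
}

# Ct from relative template abundance; zero template or clipping past the
# 40-cycle instrument limit becomes "Undetermined" (NA)
ct_from_abundance <- function(abundance, intercept, noise_sd) {
  ct <- rep(NA_real_, length(abundance))
  pos <- !is.na(abundance) & abundance > 0
  ct[pos] <- intercept - log2(abundance[pos]) +
    stats::rnorm(sum(pos), 0, noise_sd)
  ct[!is.na(ct) & ct > 40] <- NA_real_
  pmax(ct, 10)
}

#' Generate a labeled single-cell count matrix
#'
#' Draws negative-binomial counts for a PBMC background population and a
#' tumor population. True marker genes have PBMC mean `nb_mean_pbmc` and
#' tumor mean `nb_mean_tumor`; decoys of the `sc_fail` class are expressed
#' in PBMCs (mean 2.0) so they fail the stage-1 screen, while all other
#' decoys mimic markers at this stage.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (genes x cells integer matrix), `populations`
#'   (label per cell) and `ground_truth` (list with `true_marker_genes`,
#'   `gene_roles`).
#' @export
gen_single_cell_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "single_cell"))
  cat <- gene_catalog(config)
  n_pb <- config$n_pbmc_cells; n_tu <- config$n_tumor_cells
  mu_pb <- ifelse(cat$role == "sc_fail", 2.0, config$nb_mean_pbmc)
  mu_tu <- rep(config$nb_mean_tumor, nrow(cat))
  draw <- function(mu, n) t(vapply(mu, function(m)
    stats::rnbinom(n, size = config$nb_dispersion, mu = m), numeric(n)))
  counts <- cbind(draw(mu_pb, n_pb), draw(mu_tu, n_tu))
  dimnames(counts) <- list(cat$gene,
                           c(sprintf("PBMC_%04d", seq_len(n_pb)),
                             sprintf("TUMOR_%04d", seq_len(n_tu))))
  populations <- stats::setNames(rep(c("PBMC", "tumor"), c(n_pb, n_tu)),
                                 colnames(counts))
  list(counts = counts, populations = populations,
       ground_truth = list(true_marker_genes = cat$gene[cat$role == "marker"],
                           gene_roles = stats::setNames(cat$role, cat$gene)))
}

# abundance of the reference gene: constant, plenty of template everywhere
REF_ABUNDANCE <- 1024
BASE_ABUNDANCE <- 4  # background abundance giving Ct ~ 36 at default intercept

#' Generate Ct tables for the study layouts
#'
#' Four layouts feed the pipeline:
#' * `"pure"`: one PBMC sample and one sample per tumor cell line, for the
#'   stage-2 Ct filter. Half of the `ct_fail` decoys are PBMC-enriched
#'   (PBMC Ct < 30), half are lowly expressed in tumor cells (tumor Ct > 30).
#' * `"spike_in"`: per cell line, one PBMC-only control plus one sample per
#'   spike level; spiked tumor cells add template proportional to the cell
#'   number. `spike_fail` decoys are silent in the first cell line.
#' * `"pilot"`: pilot blood samples plus healthy-donor controls;
#'   `pilot_fail` decoys are essentially never detected.
#' * `"cohort"`: delegates to [gen_cohort()].
#'
#' @param config a [sim_config()].
#' @param design one of `"pure"`, `"spike_in"`, `"pilot"`, `"cohort"`.
#' @param spike_levels override of the spike series (cells per reaction).
#' @return list with `ct` (a [ct_table]) and `manifest` (a data frame
#'   describing the samples); the cohort design additionally returns the
#'   [gen_cohort()] elements.
#' @export
gen_ct_tables <- function(config,
                          design = c("pure", "spike_in", "pilot", "cohort"),
                          spike_levels = config$spike_levels) {
  stopifnot(inherits(config, "sim_config"))
  design <- match.arg(design)
  if (design == "cohort") return(gen_cohort(config))
  cat <- gene_catalog(config)
  genes <- c(config$reference_gene, cat$gene)
  noise <- config$ct_noise_sd
  set.seed(substream_seed(config$seed, paste0("ct_", design)))

  if (design == "pure") {
    # abundance per gene in the PBMC sample and in each tumor line
    ct_fail_idx <- which(cat$role == "ct_fail")
    pbmc_hot <- cat$gene[ct_fail_idx[seq_along(ct_fail_idx) %% 2 == 1]]
    tumor_cold <- cat$gene[ct_fail_idx[seq_along(ct_fail_idx) %% 2 == 0]]
    ab_pbmc <- stats::setNames(rep(BASE_ABUNDANCE, nrow(cat)), cat$gene)
    ab_pbmc[pbmc_hot] <- 2^12              # Ct ~ 26 < 30 in PBMCs
    ab_tumor <- stats::setNames(rep(2^16, nrow(cat)), cat$gene)  # Ct ~ 22
    ab_tumor[tumor_cold] <- 2^4            # Ct ~ 34 > 30 in tumor cells
    samples <- c("PBMC", config$cell_lines)
    ab <- cbind(PBMC = c(REF_ABUNDANCE, ab_pbmc))
    for (cl in config$cell_lines)
      ab <- cbind(ab, c(REF_ABUNDANCE, ab_tumor))
    colnames(ab) <- samples
    rownames(ab) <- genes
    ct <- apply(ab, 2, ct_from_abundance, intercept = config$ct_intercept,
                noise_sd = noise)
    rownames(ct) <- genes
    ct[config$reference_gene, ] <-
      ct_from_abundance(rep(REF_ABUNDANCE, length(samples)),
                        config$ct_intercept, noise)
    manifest <- data.frame(sample_id = samples,
                           role = c("pbmc", rep("tumor",
                                                length(config$cell_lines))),
                           cell_line = c(NA, config$cell_lines),
                           stringsAsFactors = FALSE)
    return(list(ct = ct_table(ct, config$reference_gene),
                manifest = manifest))
  }

  if (design == "spike_in") {
    if (!length(spike_levels)) stop("spike series must be non-empty")
    levels_all <- c(0, sort(spike_levels))
    per_cell <- BASE_ABUNDANCE * 16 / 500  # fc ~ 17 at the 500-cell level
    cts <- NULL; ids <- character(0)
    manifest <- NULL
    for (li in seq_along(config$cell_lines)) {
      cl <- config$cell_lines[li]
      for (lev in levels_all) {
        # PBMC-only controls in triplicate, spiked levels in duplicate
        n_rep <- if (lev == 0) 3L else 2L
        expr <- ifelse(cat$role == "spike_fail" & li == 1, 0, per_cell)
        ab <- BASE_ABUNDANCE + lev * expr
        for (r in seq_len(n_rep)) {
          ct <- ct_from_abundance(c(REF_ABUNDANCE, ab), config$ct_intercept,
                                  noise)
          cts <- cbind(cts, ct)
          id <- sprintf("%s_spike%d_r%d", cl, lev, r)
          ids <- c(ids, id)
          manifest <- rbind(manifest,
                            data.frame(sample_id = id, cell_line = cl,
                                       spike_cells = lev,
                                       stringsAsFactors = FALSE))
        }
      }
    }
    dimnames(cts) <- list(genes, ids)
    return(list(ct = ct_table(cts, config$reference_gene),
                manifest = manifest))
  }

  # pilot: clinical pilot samples + healthy-donor controls
  n_p <- config$n_pilot_samples; n_h <- config$n_healthy_donors
  if (n_p < 1) stop("need at least one pilot sample")
  ids <- c(sprintf("PILOT%02d", seq_len(n_p)), sprintf("HD%02d", seq_len(n_h)))
  mu <- ifelse(cat$role == "pilot_fail", -2, 2.5)
  cts <- vapply(seq_along(ids), function(j) {
    hd <- j > n_p
    lfc <- if (hd) stats::rnorm(nrow(cat), 0, 0.3) else
      stats::rnorm(nrow(cat), mu, 0.8)
    ct_from_abundance(c(REF_ABUNDANCE, BASE_ABUNDANCE * 2^lfc),
                      config$ct_intercept, noise)
  }, numeric(length(genes)))
  dimnames(cts) <- list(genes, ids)
  manifest <- data.frame(sample_id = ids,
                         role = rep(c("pilot", "healthy_control"),
                                    c(n_p, n_h)),
                         stringsAsFactors = FALSE)
  list(ct = ct_table(cts, config$reference_gene), manifest = manifest)
}

#' Generate a survival-annotated synthetic patient cohort
#'
#' Each patient carries a binary latent CTC burden (prevalence
#' `burden_prevalence`) that drives (i) the per-marker log2 fold changes of
#' the baseline blood sample relative to healthy donors
#' (`N(fc_mu_pos, fc_sd)` under high burden, `N(fc_mu_neg, fc_sd)` under
#' low), (ii) mildly tilted TNM/metastasis categories, and (iii)
#' exponential proportional-hazards survival times
#' (`h = hazard_baseline * exp(log_hr_ctc_high * burden)`) with
#' administrative censoring at `censor_time`. A `paired_fraction` subset of
#' patients contributes a follow-up sample (pre-III in the palliative arm,
#' one-month post-op in the curative arm) with fold changes attenuated by
#' `followup_lfc_shift`. Healthy-donor samples for the 2^-ddCt calibrator
#' are appended to the Ct table.
#'
#' @param config a [sim_config()].
#' @return list with `patients` (cohort schema data frame), `samples`
#'   (manifest), `ct` (a [ct_table] over the panel genes), and
#'   `ground_truth` (`burden` per patient, `log_hr_ctc_high`,
#'   `true_marker_genes`).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$censor_time <= 0) stop("censor_time must be positive")
  set.seed(substream_seed(config$seed, "cohort"))
  n <- config$n_patients
  cat <- gene_catalog(config)
  panel_genes <- cat$gene[cat$role == "marker"]
  pid <- sprintf("P%03d", seq_len(n))
  n_pall <- round(n * config$arm_fractions[["palliative"]])
  arm <- sample(rep(c("palliative", "curative"), c(n_pall, n - n_pall)))
  burden <- stats::rbinom(n, 1, config$burden_prevalence)

  age <- pmin(pmax(round(stats::rnorm(n, 68, 9)), 33), 82)
  gender <- sample(c("F", "M"), n, TRUE, prob = c(6, 49) / 55)
  location <- sample(c("lower", "upper/middle"), n, TRUE,
                     prob = c(25, 30) / 55)
  adv <- stats::rbinom(n, 1, ifelse(burden == 1, 0.75, 0.45))  # TNM III-IV
  tnm_stage <- ifelse(adv == 1, sample(c("III", "IV"), n, TRUE),
                      sample(c("0", "I", "II"), n, TRUE))
  t_hi <- stats::rbinom(n, 1, 45 / 55)
  t_stage <- ifelse(t_hi == 1, sample(c("T3", "T4"), n, TRUE),
                    sample(c("T0", "T1", "T2"), n, TRUE))
  n_hi <- stats::rbinom(n, 1, 28 / 55)
  n_stage <- ifelse(n_hi == 1, sample(c("N2", "N3"), n, TRUE),
                    sample(c("N0", "N1"), n, TRUE))
  m_stage <- ifelse(stats::rbinom(n, 1,
                                  ifelse(burden == 1, 0.40, 0.10)) == 1,
                    "M1", "M0")

  lp <- config$log_hr_ctc_high * burden
  t_death <- stats::rexp(n, config$hazard_baseline * exp(lp))
  t_prog <- stats::rexp(n, config$hazard_baseline * config$pfs_hazard_ratio *
                          exp(lp))
  t_prog <- pmin(t_prog, t_death)
  os_days <- pmax(1, ceiling(pmin(t_death, config$censor_time)))
  os_event <- as.integer(t_death <= config$censor_time)
  pfs_days <- pmax(1, ceiling(pmin(t_prog, config$censor_time)))
  pfs_event <- as.integer(t_prog <= config$censor_time)

  patients <- data.frame(patient_id = pid, age = age, gender = gender,
                         location = location, t_stage = t_stage,
                         n_stage = n_stage, m_stage = m_stage,
                         tnm_stage = tnm_stage, treatment_arm = arm,
                         pfs_days = pfs_days, pfs_event = pfs_event,
                         os_days = os_days, os_event = os_event,
                         stringsAsFactors = FALSE)

  n_paired <- round(n * config$paired_fraction)
  paired <- sort(sample(seq_len(n), n_paired))
  base_ids <- sprintf("%s_BL", pid)
  fup_ids <- sprintf("%s_FU", pid[paired])
  hd_ids <- sprintf("HD%02d", seq_len(config$n_healthy_donors))
  samples <- rbind(
    data.frame(sample_id = base_ids, patient_id = pid,
               timepoint = "baseline", role = "case",
               stringsAsFactors = FALSE),
    data.frame(sample_id = fup_ids, patient_id = pid[paired],
               timepoint = ifelse(arm[paired] == "palliative", "preIII",
                                  "postop"),
               role = "case", stringsAsFactors = FALSE),
    data.frame(sample_id = hd_ids, patient_id = NA_character_,
               timepoint = "baseline", role = "healthy_control",
               stringsAsFactors = FALSE))

  g <- length(panel_genes)
  lfc_mu <- ifelse(burden == 1, config$fc_mu_pos, config$fc_mu_neg)
  draw_sample <- function(mu) stats::rnorm(g, mu, config$fc_sd)
  lfc <- cbind(
    vapply(seq_len(n), function(i) draw_sample(lfc_mu[i]), numeric(g)),
    vapply(paired, function(i)
      draw_sample(lfc_mu[i] - config$followup_lfc_shift), numeric(g)),
    vapply(seq_len(config$n_healthy_donors),
           function(i) stats::rnorm(g, 0, 0.3), numeric(g)))
  ab <- rbind(REF_ABUNDANCE, BASE_ABUNDANCE * 2^lfc)
  ct <- apply(ab, 2, ct_from_abundance, intercept = config$ct_intercept,
              noise_sd = config$ct_noise_sd)
  dimnames(ct) <- list(c(config$reference_gene, panel_genes),
                       c(base_ids, fup_ids, hd_ids))

  list(patients = patients, samples = samples,
       ct = ct_table(ct, config$reference_gene),
       ground_truth = list(burden = stats::setNames(burden, pid),
                           log_hr_ctc_high = config$log_hr_ctc_high,
                           true_marker_genes = panel_genes))
}

#' Write a complete synthetic study to disk
#'
#' Generates and serializes every input the pipeline consumes: the
#' single-cell screen (Matrix Market triplet plus gene/cell/population
#' files), the pure-population, spike-in, pilot and cohort Ct tables (TSV),
#' the manifests (CSV), the cohort metadata (`patients.csv`,
#' `samples.csv`) and a ground-truth JSON sidecar (never consumed by the
#' pipeline itself).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- gen_single_cell_counts(config)
  write_counts(sc$counts, sc$populations, file.path(dir, "counts"))
  pure <- gen_ct_tables(config, "pure")
  write_ct_table(pure$ct, file.path(dir, "ct_pure.tsv"))
  utils::write.csv(pure$manifest, file.path(dir, "pure_manifest.csv"),
                   row.names = FALSE)
  spike <- gen_ct_tables(config, "spike_in")
  write_ct_table(spike$ct, file.path(dir, "ct_spike.tsv"))
  utils::write.csv(spike$manifest, file.path(dir, "spike_manifest.csv"),
                   row.names = FALSE)
  pilot <- gen_ct_tables(config, "pilot")
  write_ct_table(pilot$ct, file.path(dir, "ct_pilot.tsv"))
  utils::write.csv(pilot$manifest, file.path(dir, "pilot_manifest.csv"),
                   row.names = FALSE)
  cohort <- gen_cohort(config)
  write_ct_table(cohort$ct, file.path(dir, "ct_cohort.tsv"))
  write_cohort(cohort$patients, cohort$samples, dir)
  truth <- list(
    true_marker_genes = sc$ground_truth$true_marker_genes,
    gene_roles = as.list(sc$ground_truth$gene_roles),
    burden = as.list(cohort$ground_truth$burden),
    log_hr_ctc_high = cohort$ground_truth$log_hr_ctc_high,
    seed = config$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
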