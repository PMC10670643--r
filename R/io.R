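#' Read a Ct table from TSV
#'
#' Expects a tab-separated file whose first column is named `gene` and whose
#' remaining columns are sample IDs; cells hold numeric Ct values or the
#' missing encodings `NA` / `Undetermined` / empty. Duplicate gene rows and
#' non-numeric junk are rejected with descriptive errors.
#'
#' @param path file path.
#' @param reference_gene reference gene expected in the table.
#' @return a [ct_table].
#' @export
read_ct_table <- function(path, reference_gene = "GAPDH") {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!ncol(df) || names(df)[1] != "gene")
    stop("first column of a Ct table must be 'gene': ", path)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup))
    stop("duplicated gene row(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m %in% c("", "NA", "Undetermined")] <- NA
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m),
                                 dimnames = list(df$gene, colnames(m))))
  junk <- !is.na(m) & is.na(num)
  if (any(junk))
    stop("non-numeric Ct value(s), e.g. '", m[junk][1], "' for gene ",
         df$gene[row(m)[junk][1]])
  ct_table(num, reference_gene)
}

#' Write a Ct table to TSV
#'
#' @param x a [ct_table] (or bare numeric matrix with dimnames).
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_ct_table <- function(x, path) {
  m <- if (inherits(x, "ct_table")) x$ct else x
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a labeled count matrix (Matrix Market triplet)
#'
#' Reads `counts.mtx` (genes x cells), `genes.tsv`, `cells.tsv` and
#' `populations.tsv` (columns `cell`, `population`) from a directory,
#' checking that dimensions agree and that every cell has a population
#' label.
#'
#' @param dir directory containing the four files.
#' @return list with `counts` (sparse genes x cells matrix), `populations`
#'   (named vector per cell).
#' @export
read_counts <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "counts.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells))
    stop("dimension mismatch: matrix is ", nrow(counts), " x ", ncol(counts),
         " but genes.tsv has ", length(genes), " and cells.tsv has ",
         length(cells), " entries")
  pops <- utils::read.delim(file.path(dir, "populations.tsv"),
                            stringsAsFactors = FALSE)
  missing <- setdiff(cells, pops$cell)
  if (length(missing))
    stop("populations.tsv missing cell(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  dimnames(counts) <- list(genes, cells)
  list(counts = counts,
       populations = stats::setNames(pops$population, pops$cell)[cells])
}

#' Write a labeled count matrix (Matrix Market triplet)
#'
#' @param counts genes x cells count matrix.
#' @param populations population label per cell.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_counts <- function(counts, populations, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  utils::write.table(data.frame(cell = colnames(counts),
                                population = as.character(populations)),
                     file.path(dir, "populations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read cohort metadata
#'
#' Reads and validates `patients.csv` and `samples.csv`: required columns,
#' event flags in \{0, 1\}, positive integer day counts, referential
#' integrity of `patient_id` (healthy-control samples may carry `NA`), and
#' exactly one baseline sample per case patient.
#'
#' @param dir directory holding `patients.csv` and `samples.csv`.
#' @return list with `patients` and `samples` data frames.
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(tnm_stage = "character"))
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             stringsAsFactors = FALSE)
  p_cols <- c("patient_id", "age", "gender", "location", "t_stage",
              "n_stage", "m_stage", "tnm_stage", "treatment_arm",
              "pfs_days", "pfs_event", "os_days", "os_event")
  s_cols <- c("sample_id", "patient_id", "timepoint", "role")
  if (!all(p_cols %in% names(patients)))
    stop("patients.csv missing column(s): ",
         paste(setdiff(p_cols, names(patients)), collapse = ", "))
  if (!all(s_cols %in% names(samples)))
    stop("samples.csv missing column(s): ",
         paste(setdiff(s_cols, names(samples)), collapse = ", "))
  if (anyDuplicated(patients$patient_id)) stop("duplicated patient_id")
  for (cl in c("pfs_event", "os_event"))
    if (!all(patients[[cl]] %in% c(0L, 1L)))
      stop(cl, " must be 0/1")
  for (cl in c("pfs_days", "os_days"))
    if (any(patients[[cl]] <= 0 | patients[[cl]] != round(patients[[cl]])))
      stop(cl, " must be positive integer day counts")
  ref <- samples$patient_id[!is.na(samples$patient_id)]
  orphan <- setdiff(ref, patients$patient_id)
  if (length(orphan))
    stop("samples reference unknown patient(s): ",
         paste(orphan, collapse = ", "))
  base <- samples[samples$role == "case" & samples$timepoint == "baseline", ]
  dup <- base$patient_id[duplicated(base$patient_id)]
  if (length(dup))
    stop("more than one baseline sample for patient(s): ",
         paste(unique(dup), collapse = ", "))
  missing_base <- setdiff(patients$patient_id, base$patient_id)
  if (length(missing_base))
    stop("no baseline sample for patient(s): ",
         paste(missing_base, collapse = ", "))
  list(patients = patients, samples = samples)
}

#' Write cohort metadata
#'
#' @param patients,samples cohort data frames (see [read_cohort()]).
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(patients, samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE)
  invisible(dir)
}

#' Pipeline run configuration
#'
#' All analysis thresholds live here, never hard-coded downstream; the
#' config is echoed into the summary JSON for provenance.
#'
#' @param pos_fc,high_fc fold-change thresholds for positive/high calls.
#' @param k_pos,k_high detected-marker counts for CTC-positive/CTC-high.
#' @param pbmc_max,tumor_min,ct_cutoff,required_level,min_rate panel-cascade
#'   thresholds.
#' @param reference_gene housekeeping gene.
#' @param tumor_line cell line whose pure-population Ct feeds the stage-2
#'   filter.
#' @param endpoint survival endpoint for the ROC outcome, `"os"` or
#'   `"pfs"`.
#' @param seed integer seed echoed into outputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(pos_fc = 2, high_fc = 5, k_pos = 2, k_high = 5,
                       pbmc_max = 0.10, tumor_min = 1.0, ct_cutoff = 30,
                       required_level = 500, min_rate = 0.30,
                       reference_gene = "GAPDH", tumor_line = "KYSE270",
                       endpoint = c("os", "pfs"), seed = 1L) {
  endpoint <- match.arg(endpoint)
  thr <- c(pos_fc, high_fc, k_pos, k_high, pbmc_max, tumor_min, ct_cutoff,
           required_level, min_rate)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  cfg <- as.list(environment())
  cfg$thr <- NULL
  structure(cfg, class = "run_config")
}

stage_try <- function(stage, input, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed (input: ", input, "): ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full CTC analysis pipeline on a simulated or on-disk study
#'
#' Chains the five analysis stages on the inputs laid out by
#' [simulate_study()]: (1) derive the panel through the four-stage cascade,
#' (2) quantify the cohort Ct table into fold changes and marker calls
#' (calibrated on the healthy-donor samples), (3) classify samples into CTC
#' status groups, pick the ROC threshold against the survival endpoint and
#' compute trajectories, (4) run the Fisher association scan against the
#' clinical dichotomies, and (5) estimate KM curves, log-rank and Cox models
#' stratified by CTC-high and hybrid-EMT. Writes tabular exports and a
#' machine-readable `summary.json`; any stage failure aborts with the stage
#' name and offending input path.
#'
#' @param input_dir directory holding the study inputs (layout of
#'   [simulate_study()]).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return invisibly, the summary list (also serialized as JSON).
#' @export
run_pipeline <- function(input_dir, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## stage 1: panel derivation
  panel <- stage_try("derive-panel", input_dir, {
    sc <- read_counts(file.path(input_dir, "counts"))
    pure <- read_ct_table(file.path(input_dir, "ct_pure.tsv"),
                          config$reference_gene)
    spike <- read_ct_table(file.path(input_dir, "ct_spike.tsv"),
                           config$reference_gene)
    spike_manifest <- utils::read.csv(file.path(input_dir,
                                                "spike_manifest.csv"),
                                      stringsAsFactors = FALSE)
    pilot <- read_ct_table(file.path(input_dir, "ct_pilot.tsv"),
                           config$reference_gene)
    pilot_manifest <- utils::read.csv(file.path(input_dir,
                                                "pilot_manifest.csv"),
                                      stringsAsFactors = FALSE)
    cand <- setdiff(rownames(pure$ct), config$reference_gene)
    ct_pure_mat <- pure$ct
    spike_dct <- delta_ct(spike)
    spike_cal <- calibrator_delta_ct(
      spike_dct, spike_manifest$sample_id[spike_manifest$spike_cells == 0])
    spike_calls <- call_markers(fold_change(spike_dct, spike_cal),
                                config$pos_fc, config$high_fc)
    pilot_dct <- delta_ct(pilot)
    hd <- pilot_manifest$sample_id[pilot_manifest$role == "healthy_control"]
    pilot_cal <- calibrator_delta_ct(pilot_dct, hd)
    pilot_calls <- call_markers(
      fold_change(pilot_dct, pilot_cal)[, setdiff(colnames(pilot_dct), hd),
                                        drop = FALSE],
      config$pos_fc, config$high_fc)
    derive_panel(sc$counts, sc$populations,
                 ct_pbmc = ct_pure_mat[cand, "PBMC"],
                 ct_tumor = ct_pure_mat[cand, config$tumor_line],
                 spike_calls = spike_calls, spike_manifest = spike_manifest,
                 pilot_calls = pilot_calls[setdiff(rownames(pilot_calls),
                                                   config$reference_gene), ,
                                           drop = FALSE],
                 pbmc_max = config$pbmc_max, tumor_min = config$tumor_min,
                 ct_cutoff = config$ct_cutoff,
                 required_level = config$required_level,
                 min_rate = config$min_rate)
  })
  jsonlite::write_json(list(genes = panel$genes,
                            thresholds = panel$thresholds),
                       file.path(out_dir, "panel.json"), auto_unbox = TRUE)
  utils::write.table(panel$audit, file.path(out_dir, "panel_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 2: cohort quantification
  quant <- stage_try("quantify", file.path(input_dir, "ct_cohort.tsv"), {
    cohort_ct <- read_ct_table(file.path(input_dir, "ct_cohort.tsv"),
                               config$reference_gene)
    meta <- read_cohort(input_dir)
    dct <- delta_ct(cohort_ct)
    hd <- meta$samples$sample_id[meta$samples$role == "healthy_control"]
    cal <- calibrator_delta_ct(dct, intersect(hd, colnames(dct)))
    fc <- fold_change(dct, cal)
    calibrator_id <- attr(fc, "calibrator_id")
    fc <- fc[setdiff(rownames(fc), config$reference_gene), , drop = FALSE]
    calls <- call_markers(fc, config$pos_fc, config$high_fc)
    list(fc = fc, calls = calls, meta = meta, calibrator_id = calibrator_id)
  })
  long <- data.frame(gene = rep(rownames(quant$fc), ncol(quant$fc)),
                     sample = rep(colnames(quant$fc),
                                  each = nrow(quant$fc)),
                     fc = as.vector(quant$fc),
                     call = as.vector(quant$calls))
  utils::write.table(long, file.path(out_dir, "fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: classification
  cls <- stage_try("classify", file.path(out_dir, "panel.json"), {
    panel_in_calls <- intersect(panel$genes, rownames(quant$calls))
    if (!length(panel_in_calls))
      stop("no panel gene measured in the cohort Ct table")
    statuses <- classify_samples(quant$calls, panel_in_calls,
                                 config$k_pos, config$k_high)
    meta <- quant$meta
    base <- meta$samples[meta$samples$role == "case" &
                           meta$samples$timepoint == "baseline", ]
    st_base <- statuses[match(base$sample_id, statuses$sample_id), ]
    pat <- meta$patients[match(base$patient_id, meta$patients$patient_id), ]
    outcome <- if (config$endpoint == "os") pat$os_event else pat$pfs_event
    roc <- if (length(unique(outcome)) > 1)
      roc_threshold(st_base$n_detected, outcome,
                    k_max = length(panel_in_calls)) else NULL
    traj <- marker_trajectory(statuses, meta$samples, meta$patients)
    list(statuses = statuses, st_base = st_base, patients = pat,
         roc = roc, traj = traj,
         summary = summarize_cohort(statuses, meta$samples))
  })
  utils::write.table(cls$statuses, file.path(out_dir, "ctc_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cls$roc))
    utils::write.table(cls$roc$thresholds, file.path(out_dir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(cls$traj$trajectories))
    utils::write.table(cls$traj$trajectories,
                       file.path(out_dir, "trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 4: association scan
  assoc <- stage_try("associate", file.path(input_dir, "patients.csv"), {
    statuses <- list(
      ctc_positive = cls$st_base$ctc_positive,
      ctc_high = cls$st_base$ctc_high,
      hybrid_emt = cls$st_base$hybrid_emt)
    associate_markers(cls$patients, statuses,
                      variables = c("age", "tnm_stage", "tumor_size",
                                    "node_stage", "distant_metastasis"))
  })
  utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 5: survival
  surv <- stage_try("survive", file.path(input_dir, "patients.csv"), {
    pat <- cls$patients
    strata <- list(ctc_high = cls$st_base$ctc_high,
                   hybrid_emt = cls$st_base$hybrid_emt)
    time <- if (config$endpoint == "os") pat$os_days else pat$pfs_days
    event <- if (config$endpoint == "os") pat$os_event else pat$pfs_event
    out <- list()
    for (nm in names(strata)) {
      g <- strata[[nm]]
      km1 <- km_estimate(time[g], event[g])
      km0 <- km_estimate(time[!g], event[!g])
      utils::write.table(km1$table,
                         file.path(out_dir, sprintf("km_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lr <- logrank_test(time, event, g)
      covs <- data.frame(stratum = as.integer(g),
                         gender = as.integer(pat$gender == "M"),
                         age = pat$age,
                         tnm_advanced = as.integer(pat$tnm_stage %in%
                                                     c("III", "IV")),
                         arm = as.integer(pat$treatment_arm == "curative"))
      cox <- withCallingHandlers(cox_ph(time, event, covs),
                                 warning = function(w)
                                   invokeRestart("muffleWarning"))
      out[[nm]] <- list(median_high = median_survival(km1),
                        median_rest = median_survival(km0),
                        logrank_p = lr$p_value, cox = cox)
    }
    cox_rows <- do.call(rbind, lapply(names(out), function(nm)
      cbind(stratum = nm, out[[nm]]$cox$coefficients)))
    utils::write.table(cox_rows, file.path(out_dir, "cox.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  summary <- list(
    config = unclass(config),
    panel = list(genes = panel$genes, n_candidates = nrow(panel$audit)),
    quantification = list(n_genes = nrow(quant$fc),
                          n_samples = ncol(quant$fc),
                          calibrator = quant$calibrator_id),
    classification = list(
      sample_level = as.list(cls$summary$sample_level),
      patient_level = as.list(cls$summary$patient_level),
      roc = if (!is.null(cls$roc))
        list(auc = cls$roc$auc, chosen_k = cls$roc$chosen_k) else NULL,
      trajectory = if (nrow(cls$traj$summary)) cls$traj$summary else NULL),
    association = list(n_tests = nrow(assoc),
                       min_p = min(assoc$p),
                       significant = assoc[assoc$p < 0.05,
                                           c("marker", "variable", "p")]),
    survival = lapply(surv, function(s)
      list(median_high = s$median_high, median_rest = s$median_rest,
           logrank_p = s$logrank_p,
           hr = s$cox$coefficients$hr[s$cox$coefficients$term ==
                                        "`stratum`" |
                                        s$cox$coefficients$term == "stratum"][1],
           cox_p = s$cox$coefficients$p[1])))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(summary)
}

#' Validate a pipeline summary against the shipped schema
#'
#' Checks that every block and field required by
#' `inst/schema/summary_schema.json` is present in the summary list.
#'
#' @param summary summary list returned by [run_pipeline()] (or read back
#'   from `summary.json`).
#' @return TRUE invisibly; errors listing any missing field.
#' @export
validate_summary <- function(summary) {
  schema <- jsonlite::read_json(system.file("schema", "summary_schema.json",
                                            package = "ctcpanel"))
  missing <- character(0)
  for (block in names(schema$required)) {
    if (is.null(summary[[block]])) {
      missing <- c(missing, block)
      next
    }
    for (field in unlist(schema$required[[block]]))
      if (is.null(summary[[block]][[field]]))
        missing <- c(missing, paste0(block, ".", field))
  }
  if (length(missing))
    stop("summary missing required field(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
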