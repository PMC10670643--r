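#' Stage 1: single-cell expression screen
#'
#' Keeps candidate genes that are essentially silent in the PBMC background
#' yet expressed in tumor cells, judged on raw per-cell mean counts from a
#' labeled single-cell screen: `mean(PBMC) < pbmc_max` and
#' `mean(tumor) > tumor_min`, both strict.
#'
#' @param counts count matrix, genes x cells (raw counts, no normalization).
#' @param populations population label per cell (same order/names as the
#'   columns of `counts`); must contain both population labels.
#' @param pbmc_max strict upper bound on the PBMC mean (default 0.10).
#' @param tumor_min strict lower bound on the tumor mean (default 1.0).
#' @param pbmc_label,tumor_label population labels (defaults `"PBMC"`,
#'   `"tumor"`).
#' @return data frame `gene, mean_pbmc, mean_tumor, pass`.
#' @export
filter_by_singlecell <- function(counts, populations, pbmc_max = 0.10,
                                 tumor_min = 1.0, pbmc_label = "PBMC",
                                 tumor_label = "tumor") {
  if (length(populations) != ncol(counts))
    stop("'populations' must label every cell (column) of 'counts'")
  pb <- populations == pbmc_label
  tu <- populations == tumor_label
  if (!any(pb) || !any(tu))
    stop("both populations ('", pbmc_label, "', '", tumor_label,
         "') need at least one cell")
  mean_pb <- Matrix::rowMeans(counts[, pb, drop = FALSE])
  mean_tu <- Matrix::rowMeans(counts[, tu, drop = FALSE])
  data.frame(gene = rownames(counts),
             mean_pbmc = as.numeric(mean_pb),
             mean_tumor = as.numeric(mean_tu),
             pass = as.numeric(mean_pb) < pbmc_max &
               as.numeric(mean_tu) > tumor_min,
             stringsAsFactors = FALSE)
}

#' Stage 2: Ct specificity filter
#'
#' Excludes genes that are enriched in the PBMC background (PBMC Ct below
#' `cutoff`) or lowly expressed in tumor cells (tumor Ct above `cutoff`).
#' A missing tumor Ct counts as "not expressed" and excludes the gene; a
#' missing PBMC Ct counts as "not detected in background", which is the
#' favourable case.
#'
#' @param ct_pbmc,ct_tumor named numeric vectors of Ct values per candidate
#'   gene (NA = undetected).
#' @param cutoff Ct cutoff in cycles (default 30).
#' @param genes candidate genes to evaluate; default: every gene named in
#'   either vector. A candidate absent from both vectors is an error.
#' @return data frame `gene, ct_pbmc, ct_tumor, pass`.
#' @export
filter_by_ct <- function(ct_pbmc, ct_tumor, cutoff = 30,
                         genes = union(names(ct_pbmc), names(ct_tumor))) {
  if (!length(genes)) stop("no candidate genes supplied")
  orphan <- genes[!genes %in% names(ct_pbmc) & !genes %in% names(ct_tumor)]
  if (length(orphan))
    stop("gene(s) missing from both Ct vectors: ",
         paste(orphan, collapse = ", "))
  pb <- ct_pbmc[genes]; tu <- ct_tumor[genes]
  excl <- (!is.na(pb) & pb < cutoff) | is.na(tu) | tu > cutoff
  data.frame(gene = genes, ct_pbmc = unname(pb), ct_tumor = unname(tu),
             pass = !excl, stringsAsFactors = FALSE)
}

#' Stage 3: spike-in sensitivity filter
#'
#' Keeps genes positively detected (marker call `positive` or `high`) at the
#' required spike level in every tumor cell line of the spike-in series.
#'
#' @param calls marker-call matrix over the spike-in samples (genes x
#'   samples), from [call_markers()] with a PBMC-only control as calibrator.
#' @param manifest data frame `sample_id, cell_line, spike_cells`.
#' @param required_level spike level (cells) at which detection is required
#'   (default 500).
#' @param cell_lines cell lines that must all detect the gene; default: all
#'   lines present in the manifest.
#' @return data frame `gene, <one logical column per cell line>, pass`.
#' @export
filter_by_spikein <- function(calls, manifest, required_level = 500,
                              cell_lines = unique(manifest$cell_line)) {
  stopifnot(all(c("sample_id", "cell_line", "spike_cells") %in%
                  names(manifest)))
  det <- matrix(FALSE, nrow(calls), length(cell_lines),
                dimnames = list(rownames(calls), cell_lines))
  for (cl in cell_lines) {
    sel <- manifest$cell_line == cl & manifest$spike_cells == required_level
    if (!any(sel))
      stop("spike level ", required_level, " absent from manifest for cell line ",
           cl)
    ids <- intersect(manifest$sample_id[sel], colnames(calls))
    if (!length(ids))
      stop("no calls for spike level ", required_level, " in cell line ", cl)
    det[, cl] <- apply(is_detected(calls[, ids, drop = FALSE]), 1, all)
  }
  out <- data.frame(gene = rownames(calls), det, pass = apply(det, 1, all),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Stage 4: pilot-study positivity filter
#'
#' Keeps genes whose overall positivity rate across pilot blood samples is
#' at least `min_rate`; a rate of exactly 30% is kept (only rates *below*
#' the cutoff are excluded).
#'
#' @param calls marker-call matrix over the pilot samples (genes x samples).
#' @param min_rate minimum positivity rate (default 0.30).
#' @return data frame `gene, n_positive, n_samples, rate, pass`.
#' @export
filter_by_pilot_positivity <- function(calls, min_rate = 0.30) {
  if (!ncol(calls)) stop("need at least one pilot sample")
  npos <- rowSums(is_detected(calls))
  rate <- npos / ncol(calls)
  data.frame(gene = rownames(calls), n_positive = unname(npos),
             n_samples = ncol(calls), rate = unname(rate),
             pass = unname(rate >= min_rate), stringsAsFactors = FALSE)
}

#' Derive a CTC panel through the four-stage cascade
#'
#' Applies, in order: (1) the single-cell screen, (2) the Ct specificity
#' filter, (3) the spike-in sensitivity filter and (4) the pilot positivity
#' filter. Each stage only evaluates genes that survived the previous one;
#' the returned audit trail records every candidate exactly once with its
#' terminal status and, for excluded genes, the eliminating stage.
#'
#' @param sc_counts,sc_populations single-cell screen inputs (see
#'   [filter_by_singlecell()]).
#' @param ct_pbmc,ct_tumor pure-population Ct vectors (see [filter_by_ct()]).
#' @param spike_calls,spike_manifest spike-in inputs (see
#'   [filter_by_spikein()]).
#' @param pilot_calls pilot-sample call matrix (see
#'   [filter_by_pilot_positivity()]).
#' @param pbmc_max,tumor_min,ct_cutoff,required_level,min_rate stage
#'   thresholds (defaults 0.10, 1.0, 30, 500 cells, 0.30).
#' @param annotation optional named character vector annotating panel genes
#'   (e.g. epithelial/mesenchymal).
#' @return object of class `ctc_panel`: list with `genes` (the surviving,
#'   ordered panel), `audit` (per-gene per-stage trail) and `thresholds`.
#' @export
derive_panel <- function(sc_counts, sc_populations, ct_pbmc, ct_tumor,
                         spike_calls, spike_manifest, pilot_calls,
                         pbmc_max = 0.10, tumor_min = 1.0, ct_cutoff = 30,
                         required_level = 500, min_rate = 0.30,
                         annotation = NULL) {
  stages <- c("single_cell", "ct_filter", "spike_in", "pilot")
  s1 <- filter_by_singlecell(sc_counts, sc_populations, pbmc_max, tumor_min)
  audit <- data.frame(gene = s1$gene, mean_pbmc = s1$mean_pbmc,
                      mean_tumor = s1$mean_tumor, pass_single_cell = s1$pass,
                      ct_pbmc = NA_real_, ct_tumor = NA_real_,
                      pass_ct_filter = NA, pass_spike_in = NA,
                      pilot_rate = NA_real_, pass_pilot = NA,
                      stringsAsFactors = FALSE)
  alive <- s1$gene[s1$pass]
  if (!length(alive)) stop("empty panel: last gene(s) lost at stage 'single_cell'")

  s2 <- filter_by_ct(ct_pbmc[intersect(names(ct_pbmc), alive)],
                     ct_tumor[intersect(names(ct_tumor), alive)], ct_cutoff,
                     genes = alive)
  i <- match(s2$gene, audit$gene)
  audit$ct_pbmc[i] <- s2$ct_pbmc
  audit$ct_tumor[i] <- s2$ct_tumor
  audit$pass_ct_filter[i] <- s2$pass
  alive <- s2$gene[s2$pass]
  if (!length(alive)) stop("empty panel: last gene(s) lost at stage 'ct_filter'")

  s3 <- filter_by_spikein(spike_calls[intersect(rownames(spike_calls), alive),
                                      , drop = FALSE],
                          spike_manifest, required_level)
  i <- match(s3$gene, audit$gene)
  audit$pass_spike_in[i] <- s3$pass
  alive <- s3$gene[s3$pass]
  if (!length(alive)) stop("empty panel: last gene(s) lost at stage 'spike_in'")

  s4 <- filter_by_pilot_positivity(pilot_calls[intersect(rownames(pilot_calls),
                                                         alive), , drop = FALSE],
                                   min_rate)
  i <- match(s4$gene, audit$gene)
  audit$pilot_rate[i] <- s4$rate
  audit$pass_pilot[i] <- s4$pass
  alive <- s4$gene[s4$pass]

  pass_cols <- paste0("pass_", stages)
  elim <- apply(audit[pass_cols], 1, function(v) {
    k <- which(!is.na(v) & !v)
    if (length(k)) stages[min(k)] else NA_character_
  })
  audit$eliminated_at <- elim
  audit$status <- ifelse(audit$gene %in% alive, "panel", "excluded")
  if (!length(alive)) stop("empty panel: last gene(s) lost at stage 'pilot'")
  structure(list(genes = alive,
                 annotation = if (!is.null(annotation))
                   annotation[alive] else NULL,
                 audit = audit,
                 thresholds = list(pbmc_max = pbmc_max, tumor_min = tumor_min,
                                   ct_cutoff = ct_cutoff,
                                   required_level = required_level,
                                   min_rate = min_rate)),
            class = "ctc_panel")
}

#' @export
print.ctc_panel <- function(x, ...) {
  cat("CTC panel (", length(x$genes), " genes): ",
      paste(x$genes, collapse = ", "), "\n", sep = "")
  cat("candidates screened: ", nrow(x$audit), "\n", sep = "")
  invisible(x)
}
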