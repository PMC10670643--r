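#' Classify samples into CTC status groups
#'
#' Counts detected panel markers per sample (call `positive` or `high`) and
#' derives the sample-level CTC labels: CTC-positive (at least `k_pos`
#' detected markers), CTC-high (at least `k_high`), and hybrid-EMT
#' (co-detection of the epithelial and mesenchymal anchor genes, by default
#' EpCAM and TWIST1).
#'
#' @param calls marker-call matrix from [call_markers()] (genes x samples).
#' @param panel a `ctc_panel` from [derive_panel()] or a character vector of
#'   panel genes; every panel gene must be present in `calls`.
#' @param k_pos detected-marker count for CTC-positive (default 2).
#' @param k_high detected-marker count for CTC-high (default 5).
#' @param epithelial_gene,mesenchymal_gene genes whose co-detection defines
#'   the hybrid-EMT phenotype. If either is outside the panel the hybrid
#'   flag is `NA` with a warning.
#' @return data frame of class `ctc_status` with columns `sample_id,
#'   n_detected, ctc_positive, ctc_high, hybrid_emt`.
#' @export
classify_samples <- function(calls, panel, k_pos = 2, k_high = 5,
                             epithelial_gene = "EpCAM",
                             mesenchymal_gene = "TWIST1") {
  genes <- if (inherits(panel, "ctc_panel")) panel$genes else panel
  if (!length(genes)) stop("empty panel")
  miss <- setdiff(genes, rownames(calls))
  if (length(miss))
    stop("panel gene(s) missing from calls: ", paste(miss, collapse = ", "))
  det <- is_detected(calls[genes, , drop = FALSE])
  n_det <- colSums(det)
  hybrid <- if (all(c(epithelial_gene, mesenchymal_gene) %in% genes)) {
    det[epithelial_gene, ] & det[mesenchymal_gene, ]
  } else {
    warning("hybrid-EMT anchor gene(s) outside the panel; flag set to NA")
    rep(NA, ncol(det))
  }
  out <- data.frame(sample_id = colnames(calls),
                    n_detected = unname(n_det),
                    ctc_positive = unname(n_det >= k_pos),
                    ctc_high = unname(n_det >= k_high),
                    hybrid_emt = unname(hybrid),
                    stringsAsFactors = FALSE)
  class(out) <- c("ctc_status", "data.frame")
  out
}

#' ROC analysis for the detected-marker count threshold
#'
#' For every integer threshold `k` in `0..k_max`, classifies samples with
#' `n_detected >= k` as predicted-positive and computes sensitivity and
#' specificity against a binary outcome (e.g. progression or death by end of
#' follow-up). The operating threshold is the smallest `k` maximizing
#' Youden's J = sensitivity + specificity - 1 (favoring sensitivity among
#' ties), and the AUC is the trapezoidal area under the resulting step
#' curve, closed at (0,0) and (1,1).
#'
#' @param n_detected integer marker counts per sample.
#' @param outcome binary outcome per sample (both classes required).
#' @param k_max largest threshold scanned (default: panel size as implied by
#'   `max(n_detected)`).
#' @return object of class `roc_result`: list with `thresholds` (data frame
#'   k, tp, fp, fn, tn, sensitivity, specificity, youden_j), `auc`,
#'   `chosen_k`.
#' @export
roc_threshold <- function(n_detected, outcome, k_max = max(n_detected)) {
  if (length(n_detected) != length(outcome))
    stop("'n_detected' and 'outcome' must be the same length")
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  ks <- 0:k_max
  tp <- vapply(ks, function(k) sum(n_detected >= k & outcome == 1), numeric(1))
  fp <- vapply(ks, function(k) sum(n_detected >= k & outcome == 0), numeric(1))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  sens <- tp / n1
  spec <- (n0 - fp) / n0
  j <- sens + spec - 1
  chosen_k <- ks[which.max(j)]  # which.max returns the first (smallest k)
  # step curve in (FPR, TPR), anchored at (1,1) for k=0 and (0,0) beyond k_max
  fpr <- c(1, fp / n0, 0)
  tpr <- c(1, sens, 0)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
  structure(list(thresholds = data.frame(k = ks, tp = tp, fp = fp,
                                         fn = n1 - tp, tn = n0 - fp,
                                         sensitivity = sens,
                                         specificity = spec, youden_j = j),
                 auc = auc, chosen_k = chosen_k),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC threshold analysis: AUC = ", format(x$auc, digits = 4),
      ", chosen k = ", x$chosen_k,
      " (Youden J = ", format(max(x$thresholds$youden_j), digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' Longitudinal marker-count trajectories
#'
#' Pairs each patient's baseline detected-marker count with the follow-up
#' count (pre-III for palliative patients, one-month post-surgery for
#' curative patients) and reports the direction of change, plus the
#' fraction of decreasing patients per treatment arm.
#'
#' @param statuses a `ctc_status` data frame covering both time points.
#' @param samples sample manifest (columns `sample_id, patient_id,
#'   timepoint`), with `timepoint` `"baseline"` vs `"preIII"`/`"postop"`.
#' @param patients optional patients data frame; when given, the summary is
#'   split by `treatment_arm`.
#' @return list with `trajectories` (patient_id, baseline_n, followup_n,
#'   direction) and `summary` (arm, n_pairs, n_decrease, frac_decrease).
#' @export
marker_trajectory <- function(statuses, samples, patients = NULL) {
  stopifnot(all(c("sample_id", "patient_id", "timepoint") %in% names(samples)))
  n_det <- stats::setNames(statuses$n_detected, statuses$sample_id)
  cs <- samples[samples$timepoint %in% c("baseline", "preIII", "postop") &
                  samples$sample_id %in% names(n_det), , drop = FALSE]
  base <- cs[cs$timepoint == "baseline", ]
  fup <- cs[cs$timepoint != "baseline", ]
  paired <- intersect(base$patient_id, fup$patient_id)
  unpaired <- setdiff(fup$patient_id, base$patient_id)
  if (length(unpaired))
    warning("skipping unpaired patient(s): ", paste(unpaired, collapse = ", "))
  if (!length(paired))
    return(list(trajectories = data.frame(), summary = data.frame()))
  b_n <- n_det[base$sample_id[match(paired, base$patient_id)]]
  f_n <- n_det[fup$sample_id[match(paired, fup$patient_id)]]
  dirn <- ifelse(f_n < b_n, "decrease",
                 ifelse(f_n > b_n, "increase", "unchanged"))
  traj <- data.frame(patient_id = paired, baseline_n = unname(b_n),
                     followup_n = unname(f_n), direction = unname(dirn),
                     stringsAsFactors = FALSE)
  arm <- if (!is.null(patients))
    patients$treatment_arm[match(traj$patient_id, patients$patient_id)]
  else rep("all", nrow(traj))
  summ <- do.call(rbind, lapply(split(traj, arm), function(d) {
    data.frame(arm = unique(arm[match(d$patient_id, traj$patient_id)]),
               n_pairs = nrow(d),
               n_decrease = sum(d$direction == "decrease"),
               frac_decrease = mean(d$direction == "decrease"),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(trajectories = traj, summary = summ)
}

#' Cohort-level CTC detection summary
#'
#' Rates of CTC-positive, CTC-high and hybrid-EMT at the sample level (all
#' case samples) and at the patient level (baseline samples only, mirroring
#' baseline-status analyses).
#'
#' @param statuses a `ctc_status` data frame.
#' @param samples sample manifest with `sample_id, patient_id, timepoint,
#'   role`.
#' @return list with `sample_level` and `patient_level` one-row data frames
#'   (`n`, `ctc_positive_rate`, `ctc_high_rate`, `hybrid_emt_rate`).
#' @export
summarize_cohort <- function(statuses, samples) {
  if (!nrow(statuses)) stop("empty status set")
  rate_block <- function(st) {
    data.frame(n = nrow(st),
               ctc_positive_rate = mean(st$ctc_positive),
               ctc_high_rate = mean(st$ctc_high),
               hybrid_emt_rate = mean(st$hybrid_emt))
  }
  case <- samples[samples$role == "case", , drop = FALSE]
  st_s <- statuses[statuses$sample_id %in% case$sample_id, , drop = FALSE]
  base <- case[case$timepoint == "baseline", , drop = FALSE]
  st_p <- statuses[statuses$sample_id %in% base$sample_id, , drop = FALSE]
  list(sample_level = rate_block(st_s), patient_level = rate_block(st_p))
}
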