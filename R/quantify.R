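#' Construct a Ct table
#'
#' A Ct table holds RT-qPCR quantification cycles (Ct) for a set of genes
#' (rows) measured in a set of samples (columns), together with the name of
#' the housekeeping reference gene used for normalization. Missing values
#' (`NA`) encode undetected transcripts ("Undetermined" on the instrument).
#'
#' @param ct numeric matrix of Ct values, genes in rows (rownames required),
#'   samples in columns (colnames required). Values must lie in `[0, 45]`
#'   or be `NA`.
#' @param reference_gene name of the reference gene; must be a row of `ct`.
#'   Defaults to `"GAPDH"`.
#' @return an object of class `ct_table`: a list with elements `ct` and
#'   `reference_gene`.
#' @examples
#' m <- rbind(GAPDH = c(s1 = 20, s2 = 21), MET = c(25, NA))
#' ct_table(m)
#' @export
ct_table <- function(ct, reference_gene = "GAPDH") {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicated gene names: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  bad <- !is.na(ct) & (ct < 0 | ct > 45)
  if (any(bad))
    stop("Ct values outside [0, 45] for: ",
         paste(rownames(ct)[row(ct)[bad]][1], collapse = ", "))
  if (!reference_gene %in% rownames(ct))
    stop("reference gene '", reference_gene, "' absent from the Ct table")
  structure(list(ct = ct, reference_gene = reference_gene),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("Ct table: ", nrow(x$ct), " genes x ", ncol(x$ct), " samples (reference ",
      x$reference_gene, ")\n", sep = "")
  invisible(x)
}

#' Normalize Ct values to the reference gene (delta Ct)
#'
#' Computes `dCt(g, s) = Ct(g, s) - Ct(ref, s)` for every gene and sample.
#' A missing gene Ct propagates as `NA` (not detected). A sample in which the
#' reference gene itself is undetected cannot be normalized: it is dropped
#' with a warning and recorded in the `invalid_samples` attribute, so a
#' reference-gene failure invalidates the sample, never the whole run.
#'
#' @param x a [ct_table].
#' @param reference_gene optional override of the table's reference gene.
#' @return numeric matrix of delta-Ct values (same genes, valid samples
#'   only), with attribute `invalid_samples`.
#' @export
delta_ct <- function(x, reference_gene = x$reference_gene) {
  stopifnot(inherits(x, "ct_table"))
  if (!reference_gene %in% rownames(x$ct))
    stop("reference gene '", reference_gene, "' absent from the Ct table")
  ref <- stats::setNames(as.vector(x$ct[reference_gene, , drop = FALSE]),
                         colnames(x$ct))
  invalid <- colnames(x$ct)[is.na(ref)]
  if (length(invalid))
    warning("reference gene undetected; dropping sample(s): ",
            paste(invalid, collapse = ", "))
  keep <- setdiff(colnames(x$ct), invalid)
  m <- x$ct[, keep, drop = FALSE]
  d <- sweep(m, 2, ref[keep], "-")
  attr(d, "invalid_samples") <- invalid
  attr(d, "reference_gene") <- reference_gene
  d
}

#' Calibrator delta-Ct from control samples
#'
#' The calibrator for the 2^-ddCt method is the per-gene mean delta-Ct over
#' a set of control samples (pooled healthy donors).
#'
#' @param dct delta-Ct matrix from [delta_ct()].
#' @param control_samples character vector of control sample names (columns
#'   of `dct`).
#' @return named numeric vector of calibrator delta-Ct values per gene, with
#'   attribute `calibrator_id` describing its provenance.
#' @export
calibrator_delta_ct <- function(dct, control_samples) {
  missing <- setdiff(control_samples, colnames(dct))
  if (length(missing))
    stop("control sample(s) absent from delta-Ct matrix: ",
         paste(missing, collapse = ", "))
  if (!length(control_samples)) stop("no control samples supplied")
  cal <- rowMeans(dct[, control_samples, drop = FALSE], na.rm = TRUE)
  cal[is.nan(cal)] <- NA_real_
  attr(cal, "calibrator_id") <-
    paste0("mean dCt over ", length(control_samples), " control sample(s)")
  cal
}

#' Fold changes by the 2^-ddCt method
#'
#' `fc(g, s) = 2^-(dCt(g, s) - calibrator(g))`. A missing sample delta-Ct
#' (transcript not detected) yields fold change 0 exactly; a missing
#' calibrator value for any gene present in `dct` is an error, since the
#' ratio is then undefined for that gene in every sample.
#'
#' @param dct delta-Ct matrix from [delta_ct()].
#' @param calibrator named numeric vector of per-gene calibrator delta-Ct
#'   values (see [calibrator_delta_ct()]); must cover every gene in `dct`.
#' @return numeric matrix of fold changes (>= 0), with attribute
#'   `calibrator_id`.
#' @export
fold_change <- function(dct, calibrator) {
  genes <- rownames(dct)
  miss <- genes[!genes %in% names(calibrator) | is.na(calibrator[genes])]
  if (length(miss))
    stop("no calibrator delta-Ct for gene(s): ", paste(miss, collapse = ", "))
  fc <- 2^(-(dct - calibrator[genes]))
  fc[is.na(dct)] <- 0
  attr(fc, "calibrator_id") <- attr(calibrator, "calibrator_id")
  fc
}

#' Three-level marker calls from fold changes
#'
#' Categorizes relative fold changes into `negative` (< `pos_fc`),
#' `positive` (>= `pos_fc` and < `high_fc`) and `high` (>= `high_fc`).
#' Both lower bounds are closed: a fold change of exactly 2 is positive and
#' exactly 5 is high.
#'
#' @param fc fold-change matrix from [fold_change()] (or any non-negative
#'   numeric matrix).
#' @param pos_fc fold-change threshold for a positive call (default 2).
#' @param high_fc fold-change threshold for a high call (default 5).
#' @return character matrix with entries in `c("negative","positive","high")`
#'   (`NA` where `fc` is `NA`).
#' @export
call_markers <- function(fc, pos_fc = 2, high_fc = 5) {
  if (!(pos_fc > 0 && high_fc >= pos_fc))
    stop("thresholds must satisfy 0 < pos_fc <= high_fc")
  call <- matrix(NA_character_, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  call[fc < pos_fc] <- "negative"
  call[fc >= pos_fc] <- "positive"
  call[fc >= high_fc] <- "high"
  call
}

#' Detection indicator from marker calls
#'
#' A marker counts as detected when its call is `positive` or `high`
#' (fold change >= 2 under the default thresholds).
#'
#' @param call character matrix (or vector) of calls from [call_markers()].
#' @return logical object of the same shape.
#' @export
is_detected <- function(call) {
  d <- call %in% c("positive", "high")
  if (is.matrix(call)) d <- matrix(d, nrow(call), dimnames = dimnames(call))
  d
}
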