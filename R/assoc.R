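#' Build a 2x2 contingency table from counts
#'
#' @param a,b,c,d non-negative integer counts; rows are the group dichotomy,
#'   columns the marker status (`a` = group 1 & positive, `b` = group 1 &
#'   negative, `c` = group 2 & positive, `d` = group 2 & negative).
#' @return 2x2 integer matrix.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  matrix(as.integer(x), 2, 2, byrow = TRUE,
         dimnames = list(group = c("g1", "g2"),
                         status = c("positive", "negative")))
}

#' Default clinicopathological dichotomizers
#'
#' Cutpoint rules splitting each clinical variable of the cohort schema into
#' the two groups used for contingency analysis: age at 68 years, TNM stage
#' 0--II vs III--IV, tumor size T0--T2 vs T3--T4, node stage N0--N1 vs
#' N2--N3, distant metastasis M0 vs M1, tumor location lower vs
#' upper/middle, and gender.
#'
#' @param age_cut age cutpoint in years (default 68; `<=` goes to group 1).
#' @return named list of functions; each maps a patients data frame to a
#'   two-level factor.
#' @export
default_dichotomizers <- function(age_cut = 68) {
  list(
    age = function(p) factor(ifelse(p$age <= age_cut, "le_cut", "gt_cut"),
                             levels = c("le_cut", "gt_cut")),
    gender = function(p) factor(p$gender, levels = c("F", "M")),
    location = function(p) factor(p$location,
                                  levels = c("lower", "upper/middle")),
    tnm_stage = function(p) factor(
      ifelse(p$tnm_stage %in% c("0", "I", "II"), "0-II", "III-IV"),
      levels = c("0-II", "III-IV")),
    tumor_size = function(p) factor(
      ifelse(p$t_stage %in% c("T0", "T1", "T2"), "T0-T2", "T3-T4"),
      levels = c("T0-T2", "T3-T4")),
    node_stage = function(p) factor(
      ifelse(p$n_stage %in% c("N0", "N1"), "N0-N1", "N2-N3"),
      levels = c("N0-N1", "N2-N3")),
    distant_metastasis = function(p) factor(
      ifelse(p$m_stage == "M0", "no", "yes"), levels = c("no", "yes"))
  )
}

#' Cross a clinical dichotomy with a marker status
#'
#' Tabulates a per-patient binary marker/CTC status against a dichotomized
#' clinical variable, yielding the 2x2 table fed to the association tests.
#'
#' @param patients patients data frame (cohort schema, see [read_cohort()]).
#' @param status logical vector, one entry per row of `patients` or a named
#'   vector indexed by `patient_id`.
#' @param variable name of the clinical variable rule to apply.
#' @param dichotomizers list of rules as from [default_dichotomizers()].
#' @return 2x2 matrix, rows = clinical dichotomy, columns = status
#'   (positive, negative).
#' @export
build_contingency <- function(patients, status, variable,
                              dichotomizers = default_dichotomizers()) {
  if (!variable %in% names(dichotomizers))
    stop("no dichotomizer rule for variable '", variable, "'")
  if (!is.null(names(status))) {
    miss <- setdiff(patients$patient_id, names(status))
    if (length(miss))
      stop("no status for patient(s): ", paste(miss, collapse = ", "))
    status <- status[patients$patient_id]
  }
  if (length(status) != nrow(patients))
    stop("'status' must have one entry per patient")
  grp <- dichotomizers[[variable]](patients)
  if (anyNA(grp)) {
    bad <- patients$patient_id[is.na(grp)]
    stop("variable '", variable, "' unmapped for record(s): ",
         paste(bad, collapse = ", "))
  }
  tab <- table(group = grp, status = factor(ifelse(status, "positive",
                                                   "negative"),
                                            levels = c("positive", "negative")))
  matrix(as.integer(tab), 2, 2,
         dimnames = list(group = levels(grp),
                         status = c("positive", "negative")))
}

new_test_result <- function(statistic, p_value, method) {
  structure(list(statistic = statistic, p_value = p_value, method = method),
            class = "ctc_test")
}

#' @export
print.ctc_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact test of independence by the probability-mass ("sum of small p")
#' criterion: conditioning on the observed margins, the p-value is the sum of
#' hypergeometric point probabilities of all tables whose probability does
#' not exceed that of the observed table (relative tolerance `tie_tol` so
#' exactly tied tables are never lost to floating point). The reported
#' statistic is the observed table's point probability.
#'
#' If any row or column margin is zero the table carries no information about
#' association and `p = 1` is returned with a warning.
#'
#' @param t 2x2 count matrix (see [contingency_2x2()]).
#' @param tie_tol relative tolerance for point-probability ties.
#' @return a `ctc_test` result with elements `statistic`, `p_value`,
#'   `method`.
#' @examples
#' fisher_exact_two_sided(contingency_2x2(1, 7, 4, 1))  # p ~ 0.032
#' @export
fisher_exact_two_sided <- function(t, tie_tol = 1e-7) {
  if (!is.matrix(t) || !all(dim(t) == 2)) stop("'t' must be a 2x2 matrix")
  if (any(is.na(t)) || any(t < 0)) stop("counts must be non-negative")
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  if (r1 == 0 || c + d == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate margin: p = 1 by convention")
    return(new_test_result(statistic = 1, p_value = 1,
                           method = "Fisher exact test, 2-sided"))
  }
  # support of A = count in cell (1,1) given the margins
  lo <- max(0, r1 - c2)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, m = c1, n = c2, k = r1)
  p_obs <- probs[a - lo + 1]
  included <- probs <= p_obs * (1 + tie_tol)
  res <- new_test_result(statistic = p_obs,
                         p_value = min(sum(probs[included]), 1),
                         method = "Fisher exact test, 2-sided")
  res$included_a <- (lo:hi)[included]  # cell-(1,1) values in the two-sided sum
  res
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic with 1 degree of freedom,
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`, optionally with the Yates continuity
#' correction; p-value from the chi-square distribution.
#'
#' @param t 2x2 count matrix.
#' @param continuity_correction apply the Yates correction (default FALSE).
#' @return a `ctc_test` result.
#' @export
chi_square_test <- function(t, continuity_correction = FALSE) {
  if (!is.matrix(t) || !all(dim(t) == 2)) stop("'t' must be a 2x2 matrix")
  if (any(is.na(t)) || any(t < 0)) stop("counts must be non-negative")
  rs <- rowSums(t); cs <- colSums(t); n <- sum(t)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin: expected counts not all > 0")
  dev <- abs(t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1])
  if (continuity_correction) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / (rs[1] * rs[2] * cs[1] * cs[2])
  new_test_result(statistic = unname(stat),
                  p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  method = if (continuity_correction)
                    "Pearson chi-square test (Yates)" else
                    "Pearson chi-square test")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical distribution
#' functions; the p-value comes from the asymptotic Kolmogorov distribution
#' evaluated at `sqrt(n_eff) * D` with effective size
#' `n_eff = n_x n_y / (n_x + n_y)`. Used to compare fold-change
#' distributions between healthy-donor and CTC sample groups.
#'
#' @param x,y numeric samples (non-empty).
#' @return a `ctc_test` result with the D statistic.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- sort(unique(c(x, y)))
  d <- max(abs(vapply(pooled, function(t) mean(x <= t) - mean(y <= t),
                      numeric(1))))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(n_eff) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  new_test_result(statistic = d, p_value = p,
                  method = "Two-sample Kolmogorov-Smirnov test (asymptotic)")
}

#' Association scan of marker statuses against clinical dichotomies
#'
#' Runs one 2x2 test per (status, variable) pair and collects the counts
#' and p-values in a long-format table, mirroring the clinicopathological
#' correlation analysis of a CTC cohort.
#'
#' @param patients patients data frame.
#' @param statuses named list of per-patient logical status vectors (e.g.
#'   CTC-positive, per-marker detection), each indexed like `patients`.
#' @param variables clinical variables to test (default: all rules).
#' @param method `"fisher"` (default) or `"chisq"`.
#' @param dichotomizers rules as from [default_dichotomizers()].
#' @return data frame with columns `marker, variable, a, b, c, d, method,
#'   statistic, p`.
#' @export
associate_markers <- function(patients, statuses,
                              variables = names(dichotomizers),
                              method = c("fisher", "chisq"),
                              dichotomizers = default_dichotomizers()) {
  method <- match.arg(method)
  rows <- list()
  for (st in names(statuses)) {
    for (v in variables) {
      tab <- build_contingency(patients, statuses[[st]], v, dichotomizers)
      res <- if (method == "fisher") {
        withCallingHandlers(fisher_exact_two_sided(tab),
                            warning = function(w) invokeRestart("muffleWarning"))
      } else chi_square_test(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = st, variable = v,
        a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
        method = res$method, statistic = res$statistic, p = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
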