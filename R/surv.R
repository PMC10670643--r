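#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored times by the
#' product-limit estimator. Events precede censorings at tied times (the
#' usual convention). The median is the smallest observed event time at
#' which the estimated survival drops to 0.5 or below, and is undefined
#' (`NA`) when the curve never reaches 0.5.
#'
#' @param time event/censoring times (days, > 0).
#' @param event event indicator: 1 = event (progression or death),
#'   0 = censored.
#' @return object of class `km_curve`: list with `table` (time, at_risk,
#'   events, censored, survival), `median` and `n`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("need at least one record")
  if (any(is.na(time)) || any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- data.frame(time = sf$time, at_risk = sf$n.risk,
                    events = sf$n.event, censored = sf$n.censor,
                    survival = sf$surv)
  ev <- tab[tab$events > 0, , drop = FALSE]
  med <- if (any(ev$survival <= 0.5 + 1e-12))
    min(ev$time[ev$survival <= 0.5 + 1e-12]) else NA_real_
  structure(list(table = tab, median = med, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n = ", x$n, ", events = ", sum(x$table$events),
      ", median = ", if (is.na(x$median)) "not reached" else x$median,
      "\n", sep = "")
  invisible(x)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @return median time in days, or `NA` if survival never reaches 0.5.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$median
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df for two groups): observed versus
#' expected events summed over the distinct event times.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (two non-empty groups).
#' @return a `ctc_test` result.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("need two non-empty groups")
  if (sum(event) == 0) stop("no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  new_test_result(statistic = sd$chisq,
                  p_value = stats::pchisq(sd$chisq, df = df,
                                          lower.tail = FALSE),
                  method = "Log-rank test")
}

#' Cox proportional-hazards regression
#'
#' Fits a Cox model by partial likelihood with Efron handling of tied event
#' times. Constant covariates are dropped with a warning (their coefficient
#' is not identifiable); suspiciously large coefficients or standard errors
#' raise a monotone-likelihood (separation) flag.
#'
#' @param time,event as in [km_estimate()].
#' @param covariates data frame of covariates (numeric, logical or factor),
#'   one row per record.
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: list with `coefficients` (data frame:
#'   term, beta, hr, se, z, p), `converged`, `separation`, `n`, `n_event`.
#' @export
cox_ph <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time))
    stop("'covariates' must have one row per record")
  if (sum(event) < 1) stop("need at least one event")
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2,
                  logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  if (!ncol(covariates))
    stop("no non-constant covariates left; null model not fit")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  s <- summary(fit)
  co <- data.frame(term = rownames(s$coefficients),
                   beta = s$coefficients[, "coef"],
                   hr = s$coefficients[, "exp(coef)"],
                   se = s$coefficients[, "se(coef)"],
                   z = s$coefficients[, "z"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = co,
                 converged = fit$iter < 25,
                 separation = any(abs(co$beta) > 10 | co$se > 100,
                                  na.rm = TRUE),
                 n = s$n, n_event = s$nevent, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  print(x$coefficients, digits = 4)
  if (x$separation) cat("warning: possible monotone likelihood (separation)\n")
  invisible(x)
}
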