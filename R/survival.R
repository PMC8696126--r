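#' Build survival records
#'
#' @param time Follow-up time in days (diagnosis to death or last
#'   follow-up); must be positive.
#' @param event Logical/0-1 death indicator.
#' @param cin_score Optional CIN score per patient.
#' @param sample_id Optional identifiers.
#' @param ... Additional covariate vectors (e.g. `tokuhashi_score`),
#'   recycled to length.
#' @return A data.frame of class `survival_records`.
#' @export
survival_records <- function(time, event, cin_score = NULL,
                             sample_id = NULL, ...) {
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("all follow-up times must be positive and finite")
  df <- data.frame(
    sample_id = sample_id %||% sprintf("P%03d", seq_along(time)),
    time = as.numeric(time), event = as.integer(as.logical(event)),
    stringsAsFactors = FALSE)
  if (!is.null(cin_score)) df$cin_score <- as.numeric(cin_score)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("survival_records", "data.frame")
  df
}

#' Read a clinical CSV into survival records
#'
#' Expects a header with at least `sample_id`, `time_days`, `event`;
#' other columns (cin_score, tokuhashi_score, ...) are carried through.
#'
#' @param path CSV path.
#' @return A `survival_records` data.frame.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% names(df)))
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  args <- c(list(time = df$time_days, event = df$event,
                 sample_id = df$sample_id),
            df[setdiff(names(df), need)])
  do.call(survival_records, args)
}

as_surv_df <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("time", "event") %in% names(records)))
    stopf("records need 'time' and 'event' columns")
  if (any(!is.finite(records$time)) || any(records$time <= 0))
    stopf("all follow-up times must be positive and finite")
  records
}

#' Kaplan-Meier estimate with Greenwood confidence bands
#'
#' Product-limit estimator with pointwise 95% confidence intervals on the
#' log(-log S) scale (Greenwood variance).  The median is the smallest time
#' with S(t) <= 0.5 and is NA ("unreached") when the curve never falls to
#' 0.5; its confidence interval is read off where the confidence bands
#' cross 0.5.
#'
#' @param records Data.frame with `time` and `event` columns.
#' @return A `km_estimate` list: `time`, `n_risk`, `n_event`, `surv`,
#'   `lower`, `upper`, `median`, `median_lcl`, `median_ucl`,
#'   `median_reached`, `n`, `n_events`.
#' @export
km_estimate <- function(records) {
  records <- as_surv_df(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log-log")
  cross <- function(s) {
    idx <- which(!is.na(s) & s <= 0.5)
    if (length(idx)) fit$time[idx[1]] else NA_real_
  }
  med <- cross(fit$surv)
  structure(list(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, std_err = fit$std.err,
    lower = fit$lower, upper = fit$upper,
    median = med, median_reached = !is.na(med),
    median_lcl = cross(fit$lower), median_ucl = cross(fit$upper),
    n = sum(fit$n), n_events = sum(fit$n.event)),
    class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  med <- if (x$median_reached) sprintf("%.4g (95%% CI %.4g-%.4g)", x$median,
                                       x$median_lcl, x$median_ucl)
         else "unreached"
  cat(sprintf("km_estimate: n = %d, events = %d, median %s\n",
              x$n, x$n_events, med))
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Runs the Kaplan-Meier estimator with the event indicator inverted —
#' censoring becomes the event, deaths are censored — so the resulting
#' median estimates the median potential follow-up of the cohort.
#'
#' @param records Data.frame with `time` and `event` columns.
#' @return A `km_estimate` of the follow-up distribution.
#' @export
reverse_km_followup <- function(records) {
  records <- as_surv_df(records)
  flipped <- records
  flipped$event <- 1L - as.integer(records$event)
  km_estimate(flipped)
}

#' Log-rank test between survival groups
#'
#' @param records Data.frame with `time` and `event` columns.
#' @param group Group labels (at least 2 non-empty groups).
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(records, group) {
  records <- as_surv_df(records)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stopf("need at least 2 non-empty groups")
  records$.group <- droplevels(group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group,
                           data = records)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling and Wald confidence
#' intervals and p-values, the conventional reporting choice.
#' Non-convergence or infinite coefficients are flagged, never silently
#' returned as a success.
#'
#' @param records Data.frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie-handling method ("efron" default, or "breslow").
#' @param conf_level Confidence level (default 0.95).
#' @return A `cox_result` list: `table` (one row per coefficient with
#'   `term`, `log_hr`, `hr`, `se`, `ci_lower`, `ci_upper`, `p`),
#'   `loglik`, `score_chi2`, `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates, ties = "efron",
                    conf_level = 0.95) {
  records <- as_surv_df(records)
  if (sum(records$event) < 1L) stopf("no events in the cohort")
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov))
    stopf("covariate(s) not in records: %s",
          paste(missing_cov, collapse = ", "))
  for (cv in covariates)
    if (length(unique(records[[cv]])) < 2L)
      stopf("covariate '%s' is constant", cv)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  converged <- !flagged && all(is.finite(beta)) && all(is.finite(se))
  tab <- data.frame(
    term = names(beta), log_hr = unname(beta), hr = exp(unname(beta)),
    se = unname(se),
    ci_lower = exp(unname(beta) - zq * unname(se)),
    ci_upper = exp(unname(beta) + zq * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 score_chi2 = unname(fit$score),
                 converged = converged, n = fit$n, n_events = fit$nevent),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("cox_result: n = %d, events = %d%s\n", x$n, x$n_events,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$table, digits = 4)
  invisible(x)
}
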