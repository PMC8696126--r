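#' Time-horizon survival ROC for a prognostic score
#'
#' Dichotomizes the cohort at a fixed horizon: cases are deaths at or
#' before `horizon_days`, controls are patients observed beyond the
#' horizon; patients censored before the horizon carry no outcome
#' information at that horizon and are excluded (their count is reported).
#' Sensitivity and specificity are swept over all observed score values
#' with "score >= threshold" predicting death; AUC is the trapezoid area,
#' equal to the pairwise concordance probability with ties counting 1/2.
#' The AUC confidence interval is a percentile bootstrap over patients.
#'
#' @param records Data.frame with `time`, `event` and the score column.
#' @param score_name Name of the score column (default "cin_score").
#' @param horizon_days Prediction horizon in days (e.g. 183 or 365).
#' @param n_boot Bootstrap draws for the AUC CI (default 2000; 0 skips).
#' @param conf_level CI level (default 0.95).
#' @return An `roc_result` list: `horizon_days`, `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `auc_ci`, `optimal_cutoff`,
#'   `n_used`, `n_cases`, `n_controls`, `n_excluded_censored`.
#' @export
survival_roc <- function(records, score_name = "cin_score", horizon_days,
                         n_boot = 2000L, conf_level = 0.95) {
  records <- as_surv_df(records)
  if (!score_name %in% names(records))
    stopf("no column '%s' in records", score_name)
  score <- records[[score_name]]
  case <- records$event == 1L & records$time <= horizon_days
  control <- records$time > horizon_days
  excluded <- !case & !control
  if (!any(case) || !any(control))
    stopf("no %s at horizon %g days after excluding censored records",
          if (!any(case)) "cases (deaths)" else "controls (survivors)",
          horizon_days)
  s_case <- score[case]
  s_ctrl <- score[control]

  curve <- function(s_case, s_ctrl) {
    thr <- sort(unique(c(s_case, s_ctrl)))
    sens <- vapply(thr, function(t) mean(s_case >= t), 0)
    spec <- vapply(thr, function(t) mean(s_ctrl < t), 0)
    # trapezoid over (FPR, TPR), endpoints (0,0) and (1,1)
    fpr <- c(1, 1 - spec, 0)
    tpr <- c(1, sens, 0)
    auc <- sum((tpr[-1] + tpr[-length(tpr)]) / 2 *
               (fpr[-length(fpr)] - fpr[-1]))
    list(thr = thr, sens = sens, spec = spec, auc = auc)
  }
  cv <- curve(s_case, s_ctrl)

  auc_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    sc <- c(s_case, s_ctrl)
    is_case <- c(rep(TRUE, length(s_case)), rep(FALSE, length(s_ctrl)))
    aucs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(sc), replace = TRUE)
      bc <- sc[idx][is_case[idx]]
      bk <- sc[idx][!is_case[idx]]
      if (!length(bc) || !length(bk)) return(NA_real_)
      curve(bc, bk)$auc
    }, 0)
    a <- (1 - conf_level) / 2
    auc_ci <- unname(quantile(aucs, c(a, 1 - a), na.rm = TRUE))
  }

  res <- structure(list(
    horizon_days = horizon_days, thresholds = cv$thr,
    sensitivity = cv$sens, specificity = cv$spec,
    auc = cv$auc, auc_ci = auc_ci,
    n_used = sum(case) + sum(control), n_cases = sum(case),
    n_controls = sum(control), n_excluded_censored = sum(excluded)),
    class = "roc_result")
  res$optimal_cutoff <- choose_cutoff(res)
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result: horizon %g d, AUC %.4f (95%% CI %.4f-%.4f), cutoff %.4g\n",
    x$horizon_days, x$auc, x$auc_ci[1], x$auc_ci[2], x$optimal_cutoff))
  cat(sprintf("  %d cases / %d controls (%d censored before horizon excluded)\n",
              x$n_cases, x$n_controls, x$n_excluded_censored))
  invisible(x)
}

#' Optimal score cutoff by Youden's J
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC thresholds;
#' on a plateau of equal J the smallest threshold is returned.
#'
#' @param roc An `roc_result`.
#' @return The cutoff value.
#' @export
choose_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  roc$thresholds[min(best)]
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p by the probability-mass method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one.
#'
#' @param table 2x2 integer matrix of counts.
#' @return List with `p` and the odds-ratio estimate `or`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stopf("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("a margin of the table is zero")
  ft <- fisher.test(table)
  list(p = ft$p.value, or = unname(ft$estimate))
}
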