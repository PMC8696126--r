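#' Pipeline run configuration
#'
#' Reads a flat `key=value` configuration file (or takes values directly)
#' and validates it.  Recognized keys: `panel`, `cytoband`, `outdir`,
#' `bin_size`, `min_mapq`, `alpha`, `nperm`, `min_width`, `undo_sd`,
#' `z_threshold`, `cin_cutoff`, `horizons` (comma-separated days),
#' `seed`.  Referenced input paths must exist at validation time.
#'
#' @param path Optional configuration file.
#' @param ... Overrides (same names as the keys).
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(panel = NULL, cytoband = NULL, outdir = "cfcin_out",
              bin_size = 200000, min_mapq = 20, alpha = 0.01,
              nperm = 10000, min_width = 2, undo_sd = 3,
              z_threshold = 2, cin_cutoff = 12, horizons = c(183, 365),
              seed = 1)
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE,
                  value = TRUE)
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stopf("malformed config line: %s", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      cfg[[key]] <- if (key %in% c("panel", "cytoband", "outdir")) val
                    else as.numeric(strsplit(val, ",")[[1]])
    }
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  numeric_keys <- c("bin_size", "min_mapq", "alpha", "nperm", "min_width",
                    "undo_sd", "z_threshold", "cin_cutoff", "seed")
  for (key in numeric_keys) cfg[[key]] <- as.numeric(cfg[[key]])
  cfg$horizons <- as.numeric(cfg$horizons)
  if (any(cfg$horizons <= 0)) stopf("ROC horizons must be positive")
  for (key in c("panel", "cytoband"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stopf("%s path does not exist: %s", key, cfg[[key]])
  structure(cfg, class = "run_config")
}

log_line <- function(outdir, fmt, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(fmt, ...))
  cat(msg, "\n", sep = "", file = file.path(outdir, "run.log"),
      append = TRUE)
  message(msg)
}

#' Run the per-sample pipeline: bin, normalize, segment, score
#'
#' Executes the full single-sample chain against a stored control panel
#' and writes the Z-profile (bedGraph), the segment table (TSV) and the
#' CIN score row (TSV) under `outdir/<sample_id>/`.  All writes are
#' atomic, and the run is deterministic given the configuration seed.
#'
#' @param cfg A `run_config` with a `panel` path set.
#' @param sample_input Path to a per-bin counts TSV or an indexed BAM.
#' @param sample_id Sample identifier (default: file basename).
#' @return Invisibly, a list with `zprofile`, `segments` and `cin`
#'   (the `cin_result`), plus the written paths.
#' @export
run_sample <- function(cfg, sample_input, sample_id = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$panel)) stopf("run_sample requires a panel path")
  if (!file.exists(sample_input))
    stopf("sample input not found: %s", sample_input)
  panel <- read_control_panel(cfg$panel)
  sample_id <- sample_id %||% sub("\\.(counts\\.)?(bam|tsv|txt)$", "",
                                  basename(sample_input))
  raw <- if (grepl("\\.bam$", sample_input))
    bin_coverage(sample_input, panel$grid, min_mapq = cfg$min_mapq,
                 sample_id = sample_id)
  else read_bin_counts(sample_input, panel$grid, sample_id)
  zp <- normalize_profile(raw, panel)
  segs <- cbs_segment(zp, alpha = cfg$alpha, nperm = cfg$nperm,
                      min_width = cfg$min_width, undo_sd = cfg$undo_sd,
                      seed = cfg$seed)
  cin <- compute_cin_score(select_altered_segments(segs, cfg$z_threshold),
                           cutoff = cfg$cin_cutoff)
  sdir <- file.path(cfg$outdir, sample_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(zprofile = file.path(sdir, "zprofile.bedGraph"),
                segments = file.path(sdir, "segments.tsv"),
                cin = file.path(sdir, "cin.tsv"))
  write_bedgraph(zp, paths$zprofile)
  write_segments(segs, paths$segments)
  write_tsv_atomic(
    data.frame(sample_id = sample_id, cin_score = cin$cin_score,
               sum_term = cin$sum_term,
               n_altered_segments = nrow(cin$altered_segments),
               cin_class = cin$cin_class), paths$cin)
  log_line(cfg$outdir,
           "run_sample %s: seed=%d alpha=%g z_threshold=%g cutoff=%g score=%.4f (%s)",
           sample_id, as.integer(cfg$seed), cfg$alpha, cfg$z_threshold,
           cfg$cin_cutoff, cin$cin_score, cin$cin_class)
  invisible(list(zprofile = zp, segments = segs, cin = cin, paths = paths))
}

tier_of <- function(cin_high, tok_low) {
  ifelse(cin_high, "high_risk",
         ifelse(tok_low, "medium_risk", "low_risk"))
}

#' Cohort survival report
#'
#' Joins per-sample CIN scores with the clinical table and emits the
#' validation analyses: KM by CIN class with medians and CIs, log-rank p,
#' univariate Cox per covariate, the two-parameter (CIN class +
#' Tokuhashi) and full multivariate Cox models, a survival ROC with
#' Youden cutoff per horizon, stratified CIN analyses within the
#' Tokuhashi <= 8 and > 8 subgroups, and the three-tier risk table
#' (high: CIN >= cutoff; medium: Tokuhashi <= 8 & CIN < cutoff; low:
#' Tokuhashi > 8 & CIN < cutoff) with <6 / 6-12 / >=12-month outcome
#' counts.  The JSON report is deterministic given the seed.
#'
#' @param cfg A `run_config`.
#' @param cin_table Data.frame with `sample_id` and `cin_score` (e.g. the
#'   concatenation of run_sample cin.tsv rows).
#' @param clinical Path to a clinical CSV, or a `survival_records`
#'   data.frame, with `sample_id`, time and event.
#' @param covariates Extra clinical covariate names for the univariate and
#'   multivariate Cox models (must exist in the clinical table).
#' @return Invisibly, the report list (also written to
#'   `outdir/cohort/report.json` plus TSV summaries).
#' @export
run_cohort_report <- function(cfg, cin_table, clinical,
                              covariates = "tokuhashi_score") {
  stopifnot(inherits(cfg, "run_config"))
  clin <- if (is.character(clinical)) read_clinical_csv(clinical)
          else as_surv_df(clinical)
  missing_ids <- setdiff(clin$sample_id, cin_table$sample_id)
  if (length(missing_ids))
    stopf("clinical sample(s) missing from the CIN table: %s",
          paste(missing_ids, collapse = ", "))
  df <- merge(clin[setdiff(names(clin), "cin_score")],
              cin_table[, c("sample_id", "cin_score")], by = "sample_id")
  if (sum(df$event) < 1L) stopf("cohort has no events")
  df$cin_class <- classify_cin(df$cin_score, cfg$cin_cutoff)
  covariates <- intersect(covariates, names(df))

  km_by_class <- lapply(split(df, df$cin_class), km_estimate)
  lr <- if (length(unique(df$cin_class)) > 1L)
    logrank_test(df, df$cin_class) else NULL

  df$cin_low <- as.numeric(df$cin_score < cfg$cin_cutoff)
  uni_terms <- c("cin_low", covariates)
  uni <- lapply(uni_terms, function(v)
    tryCatch(cox_fit(df, v)$table, error = function(e) NULL))
  names(uni) <- uni_terms

  two_param <- multi <- NULL
  if ("tokuhashi_score" %in% names(df)) {
    df$tok_low <- as.numeric(df$tokuhashi_score <= 8)
    two_param <- tryCatch(cox_fit(df, c("cin_low", "tok_low"))$table,
                          error = function(e) NULL)
  }
  multi_terms <- c("cin_low", covariates)
  if (length(multi_terms) > 1L)
    multi <- tryCatch(cox_fit(df, multi_terms)$table,
                      error = function(e) NULL)

  roc <- lapply(cfg$horizons, function(h) {
    r <- tryCatch(
      with_seed(as.integer(cfg$seed) + as.integer(h),
                survival_roc(df, "cin_score", h)),
      error = function(e) list(error = conditionMessage(e)))
    r
  })
  names(roc) <- sprintf("horizon_%d", as.integer(cfg$horizons))

  strata <- NULL
  tiers <- NULL
  if ("tokuhashi_score" %in% names(df)) {
    strata <- lapply(split(df, df$tokuhashi_score <= 8), function(sub) {
      if (length(unique(sub$cin_class)) < 2L || sum(sub$event) < 1L)
        return(list(n = nrow(sub), logrank_p = NA_real_))
      list(n = nrow(sub), logrank_p = logrank_test(sub, sub$cin_class)$p)
    })
    names(strata) <- ifelse(names(strata) == "TRUE", "tokuhashi_le8",
                            "tokuhashi_gt8")
    df$tier <- tier_of(df$cin_class == "high", df$tokuhashi_score <= 8)
    bucket <- cut(df$time, c(0, 183, 365, Inf), right = FALSE,
                  labels = c("lt6mo", "6to12mo", "ge12mo"))
    tiers <- lapply(c("high_risk", "medium_risk", "low_risk"),
                    function(tr) {
      sub <- df[df$tier == tr, , drop = FALSE]
      if (!nrow(sub)) return(list(n = 0L, empty = TRUE))
      counts <- table(bucket[df$tier == tr])
      list(n = nrow(sub), empty = FALSE,
           counts = as.list(setNames(as.integer(counts), names(counts))),
           pct = as.list(setNames(
             round(100 * as.integer(counts) / nrow(sub), 1),
             names(counts))))
    })
    names(tiers) <- c("high_risk", "medium_risk", "low_risk")
  }

  km_entry <- function(km)
    list(n = km$n, events = km$n_events,
         median = if (km$median_reached) km$median else "unreached",
         median_lcl = km$median_lcl, median_ucl = km$median_ucl)
  report <- list(
    schema_version = "1.0",
    parameters = list(cin_cutoff = cfg$cin_cutoff,
                      z_threshold = cfg$z_threshold,
                      horizons = cfg$horizons, seed = cfg$seed),
    n = nrow(df), n_events = sum(df$event),
    followup = km_entry(reverse_km_followup(df)),
    km_by_class = lapply(km_by_class, km_entry),
    logrank = lr,
    cox_univariate = uni,
    cox_two_parameter = two_param,
    cox_multivariate = multi,
    roc = lapply(roc, function(r) {
      if (!is.null(r$error)) return(r)
      list(horizon_days = r$horizon_days, auc = r$auc,
           auc_ci = r$auc_ci, optimal_cutoff = r$optimal_cutoff,
           n_cases = r$n_cases, n_controls = r$n_controls,
           n_excluded_censored = r$n_excluded_censored)
    }),
    strata = strata,
    risk_tiers = tiers)

  cdir <- file.path(cfg$outdir, "cohort")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = cdir, fileext = ".tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = 10,
                       null = "null", na = "null", pretty = TRUE)
  file.rename(tmp, file.path(cdir, "report.json"))
  write_tsv_atomic(df[, c("sample_id", "time", "event", "cin_score",
                          "cin_class")],
                   file.path(cdir, "cohort_table.tsv"))
  if (!is.null(multi))
    write_tsv_atomic(multi, file.path(cdir, "cox_multivariate.tsv"))
  log_line(cfg$outdir, "run_cohort_report: n=%d events=%d seed=%d",
           nrow(df), sum(df$event), as.integer(cfg$seed))
  invisible(report)
}
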