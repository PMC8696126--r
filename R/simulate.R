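#' Simulation configuration
#'
#' Bundles everything the generators need: a desk-scale genome, a
#' panel-of-normals design, a coverage noise model, and a
#' proportional-hazards survival model.  Coverage is modelled as
#' negative-binomial read counts per bin around `reads_per_bin` times a
#' lognormal per-bin bias (drawn once per genome and shared by all
#' samples, emulating mappability/GC structure), converted to mean depth
#' with `read_length`.
#'
#' @param seed Mandatory integer seed; every generator is a pure function
#'   of the configuration including the seed.
#' @param chrom_sizes Named chromosome lengths in bp.  The default 4
#'   synthetic chromosomes (30/24/16/10 Mb) give 400 bins at 200 kb.
#' @param bin_size Bin width in bp.
#' @param n_controls Number of healthy controls in the panel.
#' @param reads_per_bin Expected read count per unit-bias bin.
#' @param read_length Read length in bp used to convert counts to depth.
#' @param bias_sdlog Lognormal sdlog of the shared per-bin bias.
#' @param dispersion Negative-binomial excess dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson noise, and `noise = "none"`
#'   switches noise off entirely.
#' @param noise "nb" (default) or "none".
#' @param baseline_hazard Baseline death hazard per day (default: median
#'   survival of 600 days at covariate 0).
#' @param beta_class Planted log hazard ratio of the high-CIN class (the
#'   default log(1/0.314) matches a cohort where low CIN carries HR
#'   0.314).
#' @param censoring_rate Exponential censoring hazard per day.
#' @param survival_covariate "class" (indicator of CIN score >= 12) or
#'   "score" (continuous CIN).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_sizes = c(chrS1 = 3e7, chrS2 = 2.4e7,
                                       chrS3 = 1.6e7, chrS4 = 1e7),
                       bin_size = 200000L,
                       n_controls = 20L,
                       reads_per_bin = 1300,
                       read_length = 100,
                       bias_sdlog = 0.1,
                       dispersion = 0.002,
                       noise = c("nb", "none"),
                       baseline_hazard = log(2) / 600,
                       beta_class = log(1 / 0.314),
                       censoring_rate = log(2) / 1500,
                       survival_covariate = c("class", "score")) {
  if (missing(seed)) stopf("sim_config requires a seed")
  structure(list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
                 bin_size = as.integer(bin_size),
                 n_controls = as.integer(n_controls),
                 reads_per_bin = reads_per_bin, read_length = read_length,
                 bias_sdlog = bias_sdlog, dispersion = dispersion,
                 noise = match.arg(noise),
                 baseline_hazard = baseline_hazard,
                 beta_class = beta_class,
                 censoring_rate = censoring_rate,
                 survival_covariate = match.arg(survival_covariate)),
            class = "sim_config")
}

#' Per-bin bias vector of a simulated genome
#'
#' Drawn once per configuration (lognormal, mean-normalized to 1) and
#' shared by controls and tumor samples, so panel normalization can cancel
#' it exactly in expectation.
#'
#' @param cfg A `sim_config`.
#' @return List with the `bin_grid` and the numeric `bias` vector.
#' @export
simulate_bias <- function(cfg) {
  grid <- make_bins(cfg$chrom_sizes, cfg$bin_size)
  bias <- with_seed(cfg$seed, rlnorm(nrow(grid), 0, cfg$bias_sdlog))
  list(grid = grid, bias = bias / mean(bias))
}

sim_counts <- function(mu, cfg) {
  if (cfg$noise == "none") return(mu)
  if (cfg$dispersion <= 0) return(rpois(length(mu), mu))
  rnbinom(length(mu), size = 1 / cfg$dispersion, mu = mu)
}

#' Simulate a panel of healthy-control coverage profiles
#'
#' Per-bin expectation is `reads_per_bin * bias_b`; counts are
#' negative-binomial and converted to mean depth.  Fully reproducible
#' from the configuration seed.
#'
#' @param cfg A `sim_config` with `n_controls >= 2`.
#' @return List of `raw_coverage` objects.
#' @export
simulate_controls <- function(cfg) {
  if (cfg$n_controls < 2L) stopf("n_controls must be >= 2")
  sim <- simulate_bias(cfg)
  depth_per_read <- cfg$read_length / cfg$bin_size
  with_seed(cfg$seed + 1L, {
    lapply(seq_len(cfg$n_controls), function(k) {
      counts <- sim_counts(cfg$reads_per_bin * sim$bias, cfg)
      raw_coverage(sim$grid, counts * depth_per_read,
                   sprintf("control_%02d", k),
                   total_read_pairs = sum(counts) / 2)
    })
  })
}

#' Specify planted copy-number events
#'
#' @param chrom,start_bp,end_bp Event intervals (non-overlapping within a
#'   chromosome).
#' @param copy_number Integer tumor copy number per event (never 2).
#' @param tumor_fraction Fraction of plasma DNA of tumor origin, in [0,1].
#' @return A `cnv_spec` list.
#' @export
cnv_spec <- function(chrom, start_bp, end_bp, copy_number, tumor_fraction) {
  events <- data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                       copy_number = as.integer(copy_number),
                       stringsAsFactors = FALSE)
  if (any(events$copy_number == 2L))
    stopf("copy_number 2 is the neutral state; list only altered events")
  if (any(events$copy_number < 0L)) stopf("copy_number must be >= 0")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stopf("tumor_fraction must be in [0, 1]")
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start_bp), , drop = FALSE]
    if (nrow(ev) > 1L && any(ev$start_bp[-1L] < ev$end_bp[-nrow(ev)]))
      stopf("overlapping events on %s", ch)
  }
  structure(list(events = events, tumor_fraction = tumor_fraction),
            class = "cnv_spec")
}

#' Simulate a tumor cfDNA coverage profile with planted CNVs
#'
#' cfDNA is a mixture of normal and tumor fragments: inside an event of
#' copy number c at tumor fraction tf, the expected coverage multiplier
#' is 1 + tf * (c/2 - 1); elsewhere 1.  A bin belongs to an event when its
#' midpoint falls inside the event interval.
#'
#' @param cfg A `sim_config`.
#' @param cnv A `cnv_spec`.
#' @param sample_id Sample identifier.
#' @param seed_offset Offset added to the configuration seed so several
#'   tumor replicates can be drawn from one configuration.
#' @return A `raw_coverage`.
#' @export
simulate_tumor_profile <- function(cfg, cnv, sample_id = "tumor",
                                   seed_offset = 1000L) {
  stopifnot(inherits(cnv, "cnv_spec"))
  sim <- simulate_bias(cfg)
  grid <- sim$grid
  mult <- rep(1, nrow(grid))
  mid <- (grid$start + grid$end) / 2
  for (k in seq_len(nrow(cnv$events))) {
    ev <- cnv$events[k, ]
    if (!ev$chrom %in% grid$chrom ||
        ev$end_bp > cfg$chrom_sizes[[ev$chrom]] || ev$start_bp < 0)
      stopf("event %s:%g-%g outside the grid", ev$chrom, ev$start_bp,
            ev$end_bp)
    hit <- grid$chrom == ev$chrom & mid >= ev$start_bp & mid < ev$end_bp
    mult[hit] <- 1 + cnv$tumor_fraction * (ev$copy_number / 2 - 1)
  }
  depth_per_read <- cfg$read_length / cfg$bin_size
  with_seed(cfg$seed + seed_offset, {
    counts <- sim_counts(cfg$reads_per_bin * sim$bias * mult, cfg)
    raw_coverage(grid, counts * depth_per_read, sample_id,
                 total_read_pairs = sum(counts) / 2)
  })
}

#' Simulate a survival cohort with a planted CIN-hazard relationship
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(beta_class * x)` where x is either the high-CIN
#' indicator (score >= 12) or the continuous score, per
#' `cfg$survival_covariate`; censoring is an independent exponential at
#' `censoring_rate`.
#'
#' @param cin_scores Numeric CIN scores, one per patient.
#' @param cfg A `sim_config`.
#' @param cutoff High-CIN cutoff for the class covariate.
#' @param seed_offset Offset added to the configuration seed.
#' @param ... Extra covariate columns passed to [survival_records()]
#'   (e.g. `tokuhashi_score`).
#' @return A `survival_records` data.frame with `cin_score` and
#'   `cin_class` columns.
#' @export
simulate_survival_cohort <- function(cin_scores, cfg, cutoff = 12,
                                     seed_offset = 2000L, ...) {
  if (any(!is.finite(cin_scores))) stopf("cin_scores must be finite")
  x <- if (cfg$survival_covariate == "class")
    as.numeric(cin_scores >= cutoff) else cin_scores
  with_seed(cfg$seed + seed_offset, {
    n <- length(cin_scores)
    t_death <- rexp(n, rate = cfg$baseline_hazard * exp(cfg$beta_class * x))
    t_cens <- if (cfg$censoring_rate > 0) rexp(n, rate = cfg$censoring_rate)
              else rep(Inf, n)
    time <- pmin(t_death, t_cens)
    survival_records(time = pmax(time, 1e-8), event = t_death <= t_cens,
                     cin_score = cin_scores,
                     cin_class = classify_cin(cin_scores, cutoff), ...)
  })
}

#' Censoring hazard achieving a target censoring fraction
#'
#' For exponential event hazards `hazards` and exponential censoring at
#' rate c, each patient is censored with probability c / (c + h); this
#' solves for the c whose cohort average hits `target`.
#'
#' @param target Desired censoring fraction in (0, 1).
#' @param hazards Per-patient event hazards.
#' @return The censoring rate.
#' @export
censoring_rate_for <- function(target, hazards) {
  if (target <= 0) return(0)
  if (target >= 1) stopf("target must be < 1")
  f <- function(c) mean(c / (c + hazards)) - target
  uniroot(f, c(1e-12, 1e6 * max(hazards)))$root
}

#' Write a complete synthetic fixture set
#'
#' Materializes a panel TSV, per-sample bin-count TSVs, a clinical CSV and
#' a truth JSON (planted breakpoints, tumor fraction, survival effect) so
#' the whole pipeline can be run from files.
#'
#' @param dir Output directory.
#' @param cfg A `sim_config`.
#' @param cnv A `cnv_spec` used for every tumor sample.
#' @param n_tumors Number of tumor samples.
#' @return The directory path, invisibly.
#' @export
write_fixture_set <- function(dir, cfg, cnv, n_tumors = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  controls <- simulate_controls(cfg)
  panel <- build_control_panel(controls)
  write_control_panel(panel, file.path(dir, "panel.tsv"))
  grid <- panel$grid
  write_tsv_atomic(
    data.frame(chrom = names(cfg$chrom_sizes),
               size = as.numeric(cfg$chrom_sizes)),
    file.path(dir, "chrom.sizes"), col.names = FALSE)
  cins <- numeric(n_tumors)
  ids <- sprintf("tumor_%02d", seq_len(n_tumors))
  for (k in seq_len(n_tumors)) {
    tp <- simulate_tumor_profile(cfg, cnv, ids[k],
                                 seed_offset = 1000L + k)
    df <- data.frame(chrom = grid$chrom, start = grid$start,
                     end = grid$end, value = tp$values)
    write_tsv_atomic(df, file.path(dir, paste0(ids[k], ".counts.tsv")))
    zp <- normalize_profile(tp, panel)
    segs <- cbs_segment(zp, seed = cfg$seed + k)
    cins[k] <- compute_cin_score(select_altered_segments(segs))$cin_score
  }
  clin <- simulate_survival_cohort(cins, cfg, sample_id = ids)
  utils::write.csv(
    data.frame(sample_id = clin$sample_id, time_days = clin$time,
               event = clin$event, cin_score = clin$cin_score),
    file.path(dir, "clinical.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, tumor_fraction = cnv$tumor_fraction,
         events = cnv$events, beta_class = cfg$beta_class,
         cin_scores = setNames(as.list(cins), ids)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
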