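#' Select copy-number-changed segments
#'
#' Keeps segments whose mean normalized coverage deviates from the diploid
#' baseline by at least `z_threshold` in absolute value; only these enter
#' the CIN score.
#'
#' @param segset A `segment_set`.
#' @param z_threshold Absolute mean-z threshold (default 2).
#' @return The filtered `segment_set`, order preserved.
#' @export
select_altered_segments <- function(segset, z_threshold = 2) {
  stopifnot(inherits(segset, "segment_set"))
  keep <- abs(segset$mean_z) >= z_threshold
  out <- as.data.frame(segset)[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("sample_id", "params", "bin_size"))
    attr(out, a) <- attr(segset, a)
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("segment_set", "data.frame")
  out
}

#' Compute the CIN score of a sample
#'
#' The chromosome-instability score is
#' \deqn{\mathrm{CIN} = \log_2 \sum_s V_s \times L_s}
#' over the copy-number-changed segments, where \eqn{V_s} is the absolute
#' mean Z of segment \eqn{s} and \eqn{L_s} its length in units of 200 kb
#' (so a 400-kb-binned segment of n bins contributes 2n units, and the
#' score is comparable across bin sizes).  When the sum is below 1 the
#' score is floored at 0, keeping it defined and non-negative for
#' near-flat genomes.
#'
#' @param altered A `segment_set`, normally from
#'   [select_altered_segments()].
#' @param bin_size Bin width in bp of the grid the segments were called on
#'   (default: taken from the `segment_set`).
#' @param cutoff Classification cutoff on the score (default 12, the
#'   high-CIN boundary, score >= cutoff inclusive).
#' @param sample_id Sample identifier (default: from the `segment_set`).
#' @return A `cin_result` list: `sample_id`, `cin_score`, `sum_term`,
#'   `altered_segments`, `z_threshold`, `cutoff`, `cin_class`.
#' @examples
#' # one segment with |mean z| = 2 spanning 8 x 200 kb: log2(16) = 4
#' @export
compute_cin_score <- function(altered, bin_size = attr(altered, "bin_size"),
                              cutoff = 12, sample_id = NULL) {
  stopifnot(inherits(altered, "segment_set"))
  if (is.null(bin_size) || !is.finite(bin_size) || bin_size <= 0)
    stopf("bin_size must be a positive number")
  Vs <- abs(altered$mean_z)
  Ls <- altered$n_bins * (bin_size / 200000)
  sum_term <- sum(Vs * Ls)
  cin_score <- if (sum_term >= 1) log2(sum_term) else 0
  structure(list(
    sample_id = sample_id %||% attr(altered, "sample_id") %||% NA_character_,
    cin_score = cin_score,
    sum_term = sum_term,
    altered_segments = altered,
    z_threshold = attr(altered, "z_threshold") %||% NA_real_,
    cutoff = cutoff,
    cin_class = classify_cin(cin_score, cutoff)),
    class = "cin_result")
}

#' @export
print.cin_result <- function(x, ...) {
  cat(sprintf("cin_result '%s': score %.3f (%s at cutoff %.4g), %d altered segment(s)\n",
              x$sample_id, x$cin_score, x$cin_class, x$cutoff,
              nrow(x$altered_segments)))
  invisible(x)
}

#' Classify a CIN score
#'
#' Samples at or above the cutoff are high-CIN; the boundary is inclusive
#' (a score of exactly 12 is "high" at the default cutoff).
#'
#' @param score Finite numeric CIN score(s).
#' @param cutoff Cutoff (default 12.0).
#' @return Character vector, "high" or "low".
#' @export
classify_cin <- function(score, cutoff = 12) {
  if (any(!is.finite(score))) stopf("score must be finite")
  ifelse(score >= cutoff, "high", "low")
}

#' Read a UCSC cytoBand table into an arm map
#'
#' @param path cytoBand.txt-style file: chrom, start, end, band name
#'   (e.g. "q22.1"), stain; no header.
#' @return A `cytoband_map` data.frame with one row per chromosome arm
#'   (`chrom`, `arm` = "p"/"q", `start`, `end` in bp).
#' @export
read_cytoband <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "band", "stain"),
                   stringsAsFactors = FALSE)
  arm_map(df)
}

#' @rdname read_cytoband
#' @param bands Data.frame with columns chrom, start, end, band.
#' @export
arm_map <- function(bands) {
  bands$arm <- substr(bands$band, 1L, 1L)
  bands <- bands[bands$arm %in% c("p", "q"), , drop = FALSE]
  agg_lo <- stats::aggregate(start ~ chrom + arm, bands, min)
  agg_hi <- stats::aggregate(end ~ chrom + arm, bands, max)
  arms <- merge(agg_lo, agg_hi, by = c("chrom", "arm"))
  arms <- arms[order(arms$chrom, arms$arm), c("chrom", "arm", "start", "end")]
  rownames(arms) <- NULL
  structure(arms, class = c("cytoband_map", "data.frame"))
}

#' Cohort arm-level gain/loss frequencies
#'
#' A sample counts as arm-gained (arm-lost) when its altered segments with
#' mean z at or above +`z_threshold` (at or below -`z_threshold`) cover at
#' least `min_arm_fraction` of the arm's length; frequencies are
#' percentages of the cohort, rounded to 2 decimal places.
#'
#' @param cohort List of `segment_set` objects, one per sample.
#' @param arms A `cytoband_map`.
#' @param z_threshold Absolute mean-z threshold for an altered segment.
#' @param min_arm_fraction Minimum covered fraction of the arm.
#' @return Data.frame with columns `chrom`, `arm`, `gain_pct`, `loss_pct`.
#' @export
arm_alteration_frequencies <- function(cohort, arms, z_threshold = 2,
                                       min_arm_fraction = 0.5) {
  if (!length(cohort)) stopf("cohort is empty")
  stopifnot(inherits(arms, "cytoband_map"))
  for (segset in cohort) {
    unknown <- setdiff(unique(segset$chrom), unique(arms$chrom))
    if (length(unknown))
      stopf("segments on chromosome(s) %s not covered by the arm map",
            paste(unknown, collapse = ", "))
  }
  covered <- function(segset, arm_row, sign) {
    segs <- if (sign > 0) segset[segset$mean_z >= z_threshold, , drop = FALSE]
            else segset[segset$mean_z <= -z_threshold, , drop = FALSE]
    segs <- segs[segs$chrom == arm_row$chrom, , drop = FALSE]
    if (!nrow(segs)) return(0)
    sum(pmax(0, pmin(segs$end_bp, arm_row$end) -
                pmax(segs$start_bp, arm_row$start)))
  }
  res <- arms
  res$gain_pct <- NA_real_
  res$loss_pct <- NA_real_
  for (k in seq_len(nrow(arms))) {
    arm_row <- arms[k, ]
    arm_len <- arm_row$end - arm_row$start
    gains <- vapply(cohort, function(s)
      covered(s, arm_row, +1) >= min_arm_fraction * arm_len, NA)
    losses <- vapply(cohort, function(s)
      covered(s, arm_row, -1) >= min_arm_fraction * arm_len, NA)
    res$gain_pct[k] <- round(100 * mean(gains), 2)
    res$loss_pct[k] <- round(100 * mean(losses), 2)
  }
  res
}
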