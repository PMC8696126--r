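#' Construct a segment set from a segment table
#'
#' Builds a `segment_set` directly from a data.frame of segments, for
#' externally produced or hand-specified segmentations.  Required columns:
#' `chrom`, `mean_z`, `n_bins`; `start_bp`/`end_bp`/`p_value` are carried
#' through when present.
#'
#' @param df Segment table.
#' @param sample_id Sample identifier.
#' @param bin_size Bin width in bp the segments were called on.
#' @return A `segment_set`.
#' @export
segment_set <- function(df, sample_id = NA_character_, bin_size = 200000) {
  need <- c("chrom", "mean_z", "n_bins")
  if (!all(need %in% names(df)))
    stopf("segment table needs columns %s", paste(need, collapse = ", "))
  df <- as.data.frame(df)
  for (col in c("start_bp", "end_bp", "p_value"))
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nrow(df))
  if (is.null(df$sum_z)) df$sum_z <- df$mean_z * df$n_bins
  if (is.null(df$sumsq_z)) df$sumsq_z <- df$mean_z^2 * df$n_bins
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, bin_size = bin_size,
            params = list(), class = c("segment_set", "data.frame"))
}

#' Best circular split of a series
#'
#' Scans every arc (i, j] of the circularized series (0 <= i < j <= n,
#' both the arc and its complement at least `min_width` long) and returns
#' the arc maximizing the pooled-variance two-sample t statistic comparing
#' the mean inside the arc against the mean outside.  Ties are broken
#' toward the lexicographically smallest (i, j).
#'
#' @param series Numeric vector of finite values.
#' @param min_width Minimum piece width in bins.
#' @return List with breakpoint positions `i`, `j` (counts of bins before
#'   the breakpoint, so the arc is `series[(i+1):j]`) and the statistic
#'   `t_max`.  For series shorter than `2 * min_width`, or with no
#'   informative arc (constant series), `i` and `j` are NA and `t_max` 0.
#' @export
best_split_scan <- function(series, min_width = 2L) {
  series <- as.numeric(series)
  if (anyNA(series) || any(!is.finite(series)))
    stopf("series must be finite")
  if (length(series) < 2L * min_width)
    return(list(i = NA_integer_, j = NA_integer_, t_max = 0))
  res <- .cbs_arc_scan(series, as.integer(min_width))
  if (res$i < 0) return(list(i = NA_integer_, j = NA_integer_, t_max = 0))
  list(i = res$i, j = res$j, t_max = res$t_max)
}

# Recursive CBS on one chromosome's unmasked values.  Returns a data.frame
# of (lo, hi, p) index ranges (1-based, inclusive, unmasked space).
cbs_recurse <- function(vals, alpha, nperm, min_width, lo, hi,
                        parent_p = NA_real_) {
  n <- hi - lo + 1L
  if (n < 2L * min_width)
    return(data.frame(lo = lo, hi = hi, p = parent_p))
  res <- .cbs_split_test(vals[lo:hi], as.integer(min_width), alpha,
                         as.integer(nperm), 7)
  # a terminal interval keeps the p of the accepted split that carved it
  if (is.na(res$i) || res$p >= alpha)
    return(data.frame(lo = lo, hi = hi, p = parent_p))
  cuts <- sort(unique(c(0L, res$i, res$j, n)))
  pieces <- lapply(seq_len(length(cuts) - 1L), function(k) {
    cbs_recurse(vals, alpha, nperm, min_width,
                lo + cuts[k], lo + cuts[k + 1L] - 1L, parent_p = res$p)
  })
  do.call(rbind, pieces)
}

#' Segment a Z-profile by circular binary segmentation
#'
#' Per chromosome, the best circular split of the unmasked Z values is
#' tested by permutation (within-chromosome shuffles, seeded); splits with
#' p < `alpha` are accepted and both parts are segmented recursively.
#' Adjacent segments whose means are closer than `undo_sd` pooled
#' within-segment standard deviations are then re-merged
#' (see [merge_undo()]).  Masked bins are excluded from all statistics;
#' segment bp spans include interior masked gaps but `n_bins` counts
#' unmasked bins only.
#'
#' @param profile A `z_profile`.
#' @param alpha Permutation significance level for accepting a split.
#' @param nperm Maximum permutations per test (stopped adaptively as soon
#'   as the decision at `alpha` is settled).
#' @param min_width Minimum segment width in (unmasked) bins.
#' @param undo_sd Merge threshold in pooled-SD units; 0 disables merging.
#' @param seed Seed for the permutation stream, recorded in the result.
#' @return A `segment_set`: a data.frame with one row per segment
#'   (`chrom`, `start_bin`, `end_bin` 0-based half-open grid indices,
#'   `start_bp`, `end_bp`, `mean_z`, `n_bins`, `p_value`) plus internal
#'   bookkeeping columns, with the run parameters attached as attributes.
#' @export
cbs_segment <- function(profile, alpha = 0.01, nperm = 10000L,
                        min_width = 2L, undo_sd = 3, seed = 1L) {
  stopifnot(inherits(profile, "z_profile"))
  grid <- profile$grid
  chroms <- unique(grid$chrom)
  with_seed(seed, {
    out <- list()
    for (chrom in chroms) {
      rows <- which(grid$chrom == chrom)
      um <- rows[!profile$mask[rows]]
      if (!length(um)) {
        message(sprintf("cbs_segment: chromosome %s entirely masked; skipped",
                        chrom))
        next
      }
      vals <- profile$z[um]
      segs <- cbs_recurse(vals, alpha, nperm, min_width, 1L, length(um))
      seg_df <- data.frame(
        chrom = chrom,
        start_bin = um[segs$lo] - 1L,
        end_bin = um[segs$hi],
        start_bp = grid$start[um[segs$lo]],
        end_bp = grid$end[um[segs$hi]],
        mean_z = vapply(seq_len(nrow(segs)), function(k)
          mean(vals[segs$lo[k]:segs$hi[k]]), 0),
        n_bins = segs$hi - segs$lo + 1L,
        p_value = segs$p,
        sum_z = vapply(seq_len(nrow(segs)), function(k)
          sum(vals[segs$lo[k]:segs$hi[k]]), 0),
        sumsq_z = vapply(seq_len(nrow(segs)), function(k)
          sum(vals[segs$lo[k]:segs$hi[k]]^2), 0),
        stringsAsFactors = FALSE)
      out[[chrom]] <- seg_df
    }
    segset <- do.call(rbind, out)
    rownames(segset) <- NULL
    segset <- structure(segset,
                        sample_id = profile$sample_id,
                        params = list(alpha = alpha, nperm = nperm,
                                      min_width = min_width,
                                      undo_sd = undo_sd, seed = seed),
                        bin_size = bin_size_of(grid),
                        class = c("segment_set", "data.frame"))
    if (undo_sd > 0) segset <- merge_undo(segset, undo_sd)
    segset
  })
}

#' Merge adjacent segments with close means
#'
#' Iteratively merges the adjacent same-chromosome segment pair whose mean
#' difference is smallest relative to its standard error (the pooled
#' within-segment SD scaled by sqrt(1/n1 + 1/n2)), as long as that ratio
#' is below `undo_sd`; stops when no pair qualifies.  This is the
#' conventional CBS pruning step for splits that are statistically
#' detectable but negligible in effect size.
#'
#' @param segset A `segment_set` from [cbs_segment()].
#' @param undo_sd Threshold in pooled-SD units.
#' @return The pruned `segment_set`.
#' @export
merge_undo <- function(segset, undo_sd = 3) {
  stopifnot(inherits(segset, "segment_set"))
  atts <- attributes(segset)
  df <- as.data.frame(segset)
  repeat {
    if (nrow(df) < 2L) break
    adj <- which(df$chrom[-nrow(df)] == df$chrom[-1L])
    if (!length(adj)) break
    ratio <- vapply(adj, function(k) {
      n1 <- df$n_bins[k]; n2 <- df$n_bins[k + 1L]
      ss1 <- df$sumsq_z[k] - df$sum_z[k]^2 / n1
      ss2 <- df$sumsq_z[k + 1L] - df$sum_z[k + 1L]^2 / n2
      sp <- sqrt(max(ss1 + ss2, 0) / max(n1 + n2 - 2L, 1L))
      se <- sp * sqrt(1 / n1 + 1 / n2)
      d <- abs(df$mean_z[k] - df$mean_z[k + 1L])
      if (se == 0) { if (d == 0) 0 else Inf } else d / se
    }, 0)
    best <- which.min(ratio)
    if (ratio[best] >= undo_sd) break
    k <- adj[best]
    df$end_bin[k] <- df$end_bin[k + 1L]
    df$end_bp[k] <- df$end_bp[k + 1L]
    df$n_bins[k] <- df$n_bins[k] + df$n_bins[k + 1L]
    df$sum_z[k] <- df$sum_z[k] + df$sum_z[k + 1L]
    df$sumsq_z[k] <- df$sumsq_z[k] + df$sumsq_z[k + 1L]
    df$mean_z[k] <- df$sum_z[k] / df$n_bins[k]
    pv <- c(df$p_value[k], df$p_value[k + 1L])
    pv <- pv[!is.na(pv)]
    df$p_value[k] <- if (length(pv)) max(pv) else NA_real_
    df <- df[-(k + 1L), , drop = FALSE]
    rownames(df) <- NULL
  }
  attributes(df) <- c(attributes(df)[c("names", "row.names")],
                      atts[setdiff(names(atts), c("names", "row.names"))])
  df
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set '%s': %d segment(s) on %d chromosome(s)\n",
              attr(x, "sample_id") %||% "?", nrow(x),
              length(unique(x$chrom))))
  print(as.data.frame(x)[, c("chrom", "start_bp", "end_bp", "mean_z",
                             "n_bins", "p_value")], ...)
  invisible(x)
}

#' Write segments as BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, mean_z, n_bins, p_value
#' (0-based half-open).
#' @param segset A `segment_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_segments <- function(segset, path) {
  df <- as.data.frame(segset)[, c("chrom", "start_bp", "end_bp", "mean_z",
                                  "n_bins", "p_value")]
  write_tsv_atomic(df, path)
}
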