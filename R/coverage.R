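#' Per-bin coverage profile constructor
#'
#' @param grid A `bin_grid`.
#' @param values Numeric vector, one mean-depth value per bin (bases aligned
#'   in the bin divided by bin width).
#' @param sample_id Sample identifier.
#' @param total_read_pairs Number of passing read pairs, if known.
#' @param low_depth Logical QC flag.
#' @return A `raw_coverage` object.
#' @export
raw_coverage <- function(grid, values, sample_id,
                         total_read_pairs = NA_real_, low_depth = FALSE) {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(values) != nrow(grid))
    stopf("coverage has %d values for a grid of %d bins",
          length(values), nrow(grid))
  if (any(values < 0, na.rm = TRUE)) stopf("coverage values must be >= 0")
  structure(list(grid = grid, values = as.numeric(values),
                 sample_id = as.character(sample_id),
                 total_read_pairs = total_read_pairs,
                 low_depth = isTRUE(low_depth)),
            class = "raw_coverage")
}

#' @export
print.raw_coverage <- function(x, ...) {
  cat(sprintf("raw_coverage '%s': %d bins, median depth %.4g%s\n",
              x$sample_id, length(x$values),
              median(x$values, na.rm = TRUE),
              if (x$low_depth) " [low_depth]" else ""))
  invisible(x)
}

#' Count binned coverage from a BAM file
#'
#' Each passing alignment contributes its full read length to exactly one
#' bin, chosen by the leftmost aligned position; the bin value is the sum of
#' assigned read lengths divided by bin width.  Alignments are filtered on
#' mapping quality and on duplicate / secondary / supplementary flags.
#' Grid chromosomes absent from the BAM header are zero-filled with a
#' warning.  Samples with fewer than `qc_min_pairs` passing pairs complete
#' normally but carry a QC warning, mirroring the sequencing-depth intake
#' rule of at least 10M read pairs.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM.
#' @param grid A `bin_grid`.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param drop_duplicates,drop_secondary Drop flagged duplicate and
#'   secondary/supplementary alignments (default TRUE).
#' @param sample_id Sample identifier (default: BAM basename).
#' @param qc_min_pairs Read-pair count below which a QC warning is emitted.
#' @return A `raw_coverage`.
#' @export
bin_coverage <- function(bam_path, grid, min_mapq = 20L,
                         drop_duplicates = TRUE, drop_secondary = TRUE,
                         sample_id = NULL, qc_min_pairs = 1e7) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!file.exists(bam_path)) stopf("BAM not found: %s", bam_path)
  sample_id <- sample_id %||% sub("\\.bam$", "", basename(bam_path))
  bf <- Rsamtools::BamFile(bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  chroms <- unique(grid$chrom)
  missing <- setdiff(chroms, names(hdr))
  if (length(missing))
    warnf("chromosome(s) %s absent from BAM header; zero-filled",
          paste(missing, collapse = ", "))

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA,
    isSecondaryAlignment = if (drop_secondary) FALSE else NA,
    isSupplementaryAlignment = if (drop_secondary) FALSE else NA)

  values <- numeric(nrow(grid))
  n_records <- 0L
  any_paired <- FALSE
  bsize <- bin_size_of(grid)
  for (chrom in setdiff(chroms, missing)) {
    rows <- which(grid$chrom == chrom)
    param <- Rsamtools::ScanBamParam(
      flag = flag, mapqFilter = min_mapq,
      what = c("pos", "qwidth", "flag"),
      which = GenomicRanges::GRanges(chrom,
        IRanges::IRanges(1, hdr[[chrom]])))
    rec <- Rsamtools::scanBam(bf, param = param)[[1]]
    keep <- !is.na(rec$pos)
    pos <- rec$pos[keep]       # 1-based leftmost
    qw <- rec$qwidth[keep]
    if (!length(pos)) next
    n_records <- n_records + length(pos)
    any_paired <- any_paired || any(bitwAnd(rec$flag[keep], 1L) > 0L)
    bin_local <- pmin((pos - 1L) %/% bsize + 1L, length(rows))
    sums <- tapply(as.numeric(qw), bin_local, sum)
    idx <- rows[as.integer(names(sums))]
    values[idx] <- values[idx] + as.numeric(sums) /
      (grid$end[idx] - grid$start[idx])
  }
  pairs <- if (any_paired) n_records / 2 else n_records
  low_depth <- n_records == 0L
  if (low_depth) warnf("no passing alignments in %s; all-zero profile",
                       bam_path)
  else if (pairs < qc_min_pairs)
    warnf("QC: only %.3g passing read pairs in %s (expected >= %.3g)",
          pairs, sample_id, qc_min_pairs)
  raw_coverage(grid, values, sample_id, total_read_pairs = pairs,
               low_depth = low_depth)
}

#' Read a per-bin counts TSV as a coverage profile
#'
#' Alternative entry point bypassing alignment I/O.  The file must have
#' columns chrom, start, end, value (0-based half-open) matching the grid
#' exactly; with `grid = NULL` the grid is reconstructed from the file,
#' taking the modal bin width as bin size.
#'
#' @param path TSV path (header required).
#' @param grid A `bin_grid`, or NULL to infer one.
#' @param sample_id Sample identifier (default: file basename).
#' @return A `raw_coverage`.
#' @export
read_bin_counts <- function(path, grid = NULL, sample_id = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(df)))
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  if (is.null(grid)) {
    widths <- df$end - df$start
    bsize <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
    sizes <- tapply(df$end, df$chrom, max)
    chrom_order <- unique(df$chrom)
    grid <- make_bins(setNames(as.numeric(sizes[chrom_order]), chrom_order),
                      bsize)
  }
  if (nrow(df) != nrow(grid) || !all(df$chrom == grid$chrom) ||
      !all(df$start == grid$start))
    stopf("bins in %s do not match the grid", path)
  raw_coverage(grid, df$value, sample_id %||% sub("\\.[^.]*$", "",
                                                  basename(path)))
}

#' Write a per-bin track as bedGraph
#'
#' @param x A `raw_coverage` or `z_profile`.
#' @param path Output path.
#' @param na Sentinel written for masked/NA bins.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(x, path, na = "NA") {
  vals <- if (inherits(x, "z_profile")) x$z else x$values
  df <- data.frame(chrom = x$grid$chrom, start = x$grid$start,
                   end = x$grid$end, value = vals)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = na)
  file.rename(tmp, path)
  invisible(path)
}
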