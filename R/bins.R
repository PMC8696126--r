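#' Build a fixed-width genome bin grid
#'
#' Tiles each chromosome with adjacent, non-overlapping bins of `bin_size`
#' base pairs; the terminal bin of a chromosome is truncated at the
#' chromosome end.  Coordinates are 0-based half-open, and chromosomes keep
#' the order in which they are supplied.
#'
#' @param chrom_sizes Named integer vector (or named list) of chromosome
#'   lengths in bp.
#' @param bin_size Bin width in bp (the default 200 kb matches the CIN-score
#'   length unit; 100 kb and 400 kb are the usual alternatives).
#' @return A `bin_grid`: a data.frame with columns `chrom`, `start`, `end`
#'   and attributes `bin_size` and `chrom_sizes`.
#' @examples
#' g <- make_bins(c(chrA = 450000), 200000)
#' nrow(g)  # 3 bins, the last one 50 kb
#' @export
make_bins <- function(chrom_sizes, bin_size = 200000L) {
  chrom_sizes <- unlist(chrom_sizes)
  if (length(chrom_sizes) == 0L) stopf("chrom_sizes is empty")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stopf("chrom_sizes must be named by chromosome")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stopf("bin_size must be a single positive number")
  if (any(chrom_sizes <= 0)) stopf("chromosome lengths must be positive")
  bin_size <- as.integer(bin_size)

  pieces <- lapply(names(chrom_sizes), function(chrom) {
    len <- as.numeric(chrom_sizes[[chrom]])
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  structure(grid, bin_size = bin_size, chrom_sizes = chrom_sizes,
            class = c("bin_grid", "data.frame"))
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %d bp across %d chromosome(s)\n",
              nrow(x), attr(x, "bin_size"),
              length(unique(x$chrom))))
  invisible(x)
}

bin_size_of <- function(grid) attr(grid, "bin_size")

grids_identical <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$start, b$start) &&
    identical(a$end, b$end)
}

#' Read a chrom.sizes file
#'
#' Two-column TSV (chromosome name, length in bp), as distributed by UCSC.
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  setNames(df$size, df$chrom)
}
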