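#' Build a panel of normals from control coverage profiles
#'
#' Each control is first brought to a common depth by dividing its values by
#' its own median bin value, then the per-bin sample mean and sample
#' standard deviation (n-1 denominator) are taken across controls.  Bins
#' where the normal panel is uninformative — zero spread, or mean depth
#' below `min_mean` on the median-scaled scale — are masked and excluded
#' from all downstream statistics.
#'
#' @param controls List of `raw_coverage` objects on the identical grid
#'   (at least 2).
#' @param min_mean Minimum scaled mean depth for an informative bin.  The
#'   default 0.01 is 1% of the median-scaled depth (which is 1 by
#'   construction).
#' @return A `control_panel` with per-bin `mean`, `std`, logical `mask`
#'   (TRUE = masked) and `n_controls`.
#' @export
build_control_panel <- function(controls, min_mean = 0.01) {
  if (length(controls) < 2L) stopf("need at least 2 controls, got %d",
                                   length(controls))
  grid <- controls[[1]]$grid
  for (ctl in controls) {
    stopifnot(inherits(ctl, "raw_coverage"))
    if (!grids_identical(ctl$grid, grid))
      stopf("control '%s' is on a different grid", ctl$sample_id)
  }
  scaled <- vapply(controls, function(ctl) {
    med <- median(ctl$values, na.rm = TRUE)
    if (!is.finite(med) || med <= 0)
      stopf("control '%s' has non-positive median depth", ctl$sample_id)
    ctl$values / med
  }, numeric(nrow(grid)))
  mu <- rowMeans(scaled, na.rm = TRUE)
  sdv <- apply(scaled, 1L, sd, na.rm = TRUE)
  mask <- !is.finite(sdv) | sdv == 0 | !is.finite(mu) | mu < min_mean
  structure(list(grid = grid, mean = mu, std = sdv, mask = mask,
                 n_controls = length(controls), min_mean = min_mean),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat(sprintf("control_panel: %d controls, %d bins (%d masked)\n",
              x$n_controls, length(x$mean), sum(x$mask)))
  invisible(x)
}

#' Z-normalize a coverage profile against a control panel
#'
#' The per-bin normalized coverage is
#' \deqn{z_b = (x_b - \mu_b) / \sigma_b}
#' where \eqn{\mu_b} and \eqn{\sigma_b} are the panel's per-bin mean and
#' standard deviation of control coverage.  The sample is median-scaled
#' first (over panel-unmasked bins), the same depth convention used when
#' the panel was built, so the Z-profile is invariant to sequencing depth.
#' Masked panel bins propagate as NA.
#'
#' @param raw A `raw_coverage` on the panel's grid.
#' @param panel A `control_panel`.
#' @return A `z_profile` with fields `grid`, `z`, `mask`, `sample_id`.
#' @export
normalize_profile <- function(raw, panel) {
  stopifnot(inherits(raw, "raw_coverage"), inherits(panel, "control_panel"))
  if (!grids_identical(raw$grid, panel$grid))
    stopf("sample '%s' is on a different grid than the panel", raw$sample_id)
  med <- median(raw$values[!panel$mask], na.rm = TRUE)
  if (!is.finite(med) || med <= 0)
    stopf("sample '%s' has non-positive median depth on unmasked bins",
          raw$sample_id)
  z <- (raw$values / med - panel$mean) / panel$std
  z[panel$mask] <- NA_real_
  structure(list(grid = raw$grid, z = z, mask = panel$mask,
                 sample_id = raw$sample_id),
            class = "z_profile")
}

#' Construct a Z-profile directly
#'
#' For normalized profiles produced outside [normalize_profile()] (or in
#' simulations that work directly on the Z scale).  Masked bins must carry
#' NA in `z`.
#'
#' @param grid A `bin_grid`.
#' @param z Per-bin normalized coverage; NA on masked bins.
#' @param mask Logical mask (default: `is.na(z)`).
#' @param sample_id Sample identifier.
#' @return A `z_profile`.
#' @export
z_profile <- function(grid, z, mask = is.na(z), sample_id = "sample") {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(z) != nrow(grid))
    stopf("z has %d values for a grid of %d bins", length(z), nrow(grid))
  z <- as.numeric(z)
  z[mask] <- NA_real_
  if (any(!is.finite(z[!mask])))
    stopf("z must be finite on unmasked bins")
  structure(list(grid = grid, z = z, mask = mask,
                 sample_id = as.character(sample_id)),
            class = "z_profile")
}

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf("z_profile '%s': %d bins (%d masked), mean z %.3f\n",
              x$sample_id, length(x$z), sum(x$mask),
              mean(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Write / read a control panel as TSV
#'
#' Columns: chrom, start, end, mean, std, mask (0/1).
#' @param panel A `control_panel`.
#' @param path File path.
#' @return `write_control_panel`: the path, invisibly.
#'   `read_control_panel`: a `control_panel`.
#' @export
write_control_panel <- function(panel, path) {
  df <- data.frame(chrom = panel$grid$chrom, start = panel$grid$start,
                   end = panel$grid$end, mean = panel$mean, std = panel$std,
                   mask = as.integer(panel$mask),
                   n_controls = panel$n_controls)
  write_tsv_atomic(df, path)
}

#' @rdname write_control_panel
#' @param grid Optional `bin_grid`; inferred from the file when NULL.
#' @export
read_control_panel <- function(path, grid = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (is.null(grid)) {
    widths <- df$end - df$start
    bsize <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
    sizes <- tapply(df$end, df$chrom, max)
    chrom_order <- unique(df$chrom)
    grid <- make_bins(setNames(as.numeric(sizes[chrom_order]), chrom_order),
                      bsize)
  }
  if (nrow(df) != nrow(grid)) stopf("panel %s does not match grid", path)
  structure(list(grid = grid, mean = df$mean, std = df$std,
                 mask = df$mask > 0, n_controls = df$n_controls[1],
                 min_mean = NA_real_),
            class = "control_panel")
}
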