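test_that("make_bins tiles chromosomes with a truncated terminal bin", {
  g <- make_bins(c(chrA = 450000), 200000)
  expect_equal(nrow(g), 3L)
  expect_equal(g$start, c(0, 200000, 400000))
  expect_equal(g$end, c(200000, 400000, 450000))

  expect_equal(nrow(make_bins(c(chr21 = 48129895), 200000)), 241L)
  expect_equal(nrow(make_bins(c(chrA = 450000), 100000)), 5L)

  # chromosome order preserved, multi-chromosome
  g2 <- make_bins(c(b = 250000, a = 100000), 100000)
  expect_equal(unique(g2$chrom), c("b", "a"))
  expect_equal(nrow(g2), 4L)

  expect_error(make_bins(c(chrA = 1e6), 0), "positive")
  expect_error(make_bins(setNames(numeric(0), character(0))), "empty")
})

test_that("bin_coverage assigns reads by leftmost position and applies filters", {
  reads <- c(vapply(1:100, function(k)
    sam_read(sprintf("r%03d", k), pos = k * 100), ""),
    sam_read("edge", pos = 199951))  # 1-based start in bin 0, spans boundary
  bam <- write_test_bam(reads, chrom_len = 400000L)
  grid <- make_bins(c(chrA = 400000), 200000)
  # below the 10M-pair intake rule: completes with a QC warning
  expect_warning(cov <- bin_coverage(bam, grid), "QC")
  # 100 + 1 reads of length 100 all assigned to bin 0 by start position
  expect_equal(cov$values, c(101 * 100 / 200000, 0))
  expect_false(cov$low_depth)

  # duplicates, secondary and low-MAPQ reads are dropped
  reads2 <- c(sam_read("ok", 100),
              sam_read("dup", 200, flag = 1024L),
              sam_read("sec", 300, flag = 256L),
              sam_read("badq", 400, mapq = 5L))
  suppressWarnings(
    cov2 <- bin_coverage(write_test_bam(reads2, chrom_len = 400000L), grid))
  expect_equal(cov2$values[1], 100 / 200000)
})

test_that("bin_coverage handles empty sources and missing chromosomes", {
  bam <- write_test_bam(character(0), chrom_len = 400000L)
  grid <- make_bins(c(chrA = 400000), 200000)
  expect_warning(cov <- bin_coverage(bam, grid), "no passing alignments")
  expect_true(cov$low_depth)
  expect_equal(cov$values, c(0, 0))

  grid2 <- make_bins(c(chrA = 400000, chrB = 200000), 200000)
  bam2 <- write_test_bam(sam_read("r1", 100), chrom_len = 400000L)
  expect_warning(expect_warning(cov2 <- bin_coverage(bam2, grid2), "chrB"),
                 "QC")
  expect_equal(cov2$values[3], 0)
})

test_that("read_bin_counts round-trips a counts TSV", {
  grid <- make_bins(c(chrA = 600000), 200000)
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   value = c(0.1, 0.2, 0.3))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- read_bin_counts(path, grid)
  expect_equal(cov$values, df$value)
  cov_nogrid <- read_bin_counts(path)
  expect_equal(cov_nogrid$values, df$value)
  expect_equal(attr(cov_nogrid$grid, "bin_size"), 200000L)
})

test_that("build_control_panel computes sample stats and masks degenerate bins", {
  grid <- make_bins(c(chrA = 1e6), 200000)
  # every control has median 1, so median scaling is the identity
  mk <- function(v, id) raw_coverage(grid, v, id)
  panel <- build_control_panel(list(mk(c(1, 2, 1, 1, 1), "c1"),
                                    mk(c(2, 1, 1, 1, 1), "c2"),
                                    mk(c(3, 3, 1, 1, 1), "c3")),
                               min_mean = 0.01)
  expect_equal(panel$mean[1:2], c(2, 2))     # bins with values {1,2,3},{2,1,3}
  expect_equal(panel$std[1:2], c(1, 1))      # sample std, n-1 denominator
  expect_equal(panel$mask, c(FALSE, FALSE, TRUE, TRUE, TRUE))  # std 0 masked

  # two identical controls: std 0 everywhere -> all masked
  p2 <- build_control_panel(list(mk(1:5, "a"), mk(1:5, "b")))
  expect_true(all(p2$mask))

  # a bin with mean below min_mean is masked regardless of std
  p3 <- build_control_panel(list(mk(c(1, 1, 1, 1, 0.001), "a"),
                                 mk(c(1, 1, 1, 1, 0.004), "b")))
  expect_true(p3$mask[5])

  expect_error(build_control_panel(list(mk(1:5, "a"))), "at least 2")
  g2 <- make_bins(c(chrA = 400000), 200000)
  expect_error(build_control_panel(list(mk(1:5, "a"),
                                        raw_coverage(g2, c(1, 2), "b"))),
               "different grid")
})

test_that("normalize_profile applies the panel Z formula", {
  grid <- make_bins(c(chrA = 1e6), 200000)
  mk <- function(v, id) raw_coverage(grid, v, id)
  # all controls have median 1, so panel stats are hand-computable
  panel <- build_control_panel(list(mk(c(1, 1.2, 0.8, 1, 1.4), "c1"),
                                    mk(c(1, 0.8, 1.2, 1, 0.6), "c2"),
                                    mk(c(1, 1.0, 1.0, 1, 1.1), "c3")))
  expect_equal(panel$mask, c(TRUE, FALSE, FALSE, TRUE, FALSE))  # std 0
  expect_equal(panel$mean[2:3], c(1, 1))
  expect_equal(panel$std[2:3], c(0.2, 0.2))
  # sample with unmasked median exactly 1: bin 2 sits at mean + 2 std,
  # bin 3 exactly at the panel mean
  zp <- normalize_profile(mk(c(9, 1.4, 1.0, 9, 0.9), "s"), panel)
  expect_equal(zp$z[2], 2)
  expect_equal(zp$z[3], 0)
  expect_true(all(is.na(zp$z[c(1, 4)])))
  # grid mismatch is an error
  g2 <- make_bins(c(chrA = 400000), 200000)
  expect_error(normalize_profile(raw_coverage(g2, c(1, 1), "s"), panel),
               "different grid")
})

test_that("Z-profiles are invariant to sequencing depth", {
  cfg <- sim_config(seed = 21, n_controls = 8)
  panel <- build_control_panel(simulate_controls(cfg))
  cnv <- cnv_spec("chrS1", 2e6, 8e6, 3L, 0.3)
  tumor <- simulate_tumor_profile(cfg, cnv)
  z1 <- normalize_profile(tumor, panel)
  scaled <- raw_coverage(tumor$grid, tumor$values * 7.3, tumor$sample_id)
  z2 <- normalize_profile(scaled, panel)
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
  # mask conservation: unmasked bin count identical between panel and profile
  expect_identical(sum(!z1$mask), sum(!panel$mask))
})

test_that("leave-one-out control normalization is calibrated", {
  # Gaussian simulation with known sigma: a held-out control normalized
  # against the panel should give z ~ N(0, ~(n+1)/n); tail mass beyond
  # |z| > 3 stays small and the per-sample mean shrinks toward 0.
  set.seed(77)
  n_bins <- 5000
  n_ctl <- 20
  grid <- make_bins(c(chrZ = n_bins * 200000), 200000)
  mu_b <- rlnorm(n_bins, 0, 0.05)
  mk <- function(k) raw_coverage(grid, mu_b * (1 + rnorm(n_bins, 0, 0.05)),
                                 paste0("c", k))
  controls <- lapply(seq_len(n_ctl + 1), mk)
  panel <- build_control_panel(controls[seq_len(n_ctl)])
  z <- normalize_profile(controls[[n_ctl + 1]], panel)
  zv <- z$z[!z$mask]
  expect_lt(mean(abs(zv) > 3), 0.015)
  expect_lt(abs(mean(zv)), 0.2)
  expect_gt(var(zv), 0.9)
  expect_lt(var(zv), 1.25)
})
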