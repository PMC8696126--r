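# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive arc scan computing the two-sample t statistic directly from
# means and sums of squares (no prefix sums), same tie rule: first
# (i, j) in lexicographic order wins on strict improvement.
oracle_best_split <- function(x, min_width = 2L) {
  n <- length(x)
  best <- list(i = NA_integer_, j = NA_integer_, t_max = -Inf)
  # arcs with j = n duplicate the (0, i] split and are excluded, matching
  # the canonical enumeration of circular splits
  for (i in 0:(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      k <- j - i
      if (k < min_width || n - k < min_width) next
      inside <- x[(i + 1L):j]
      outside <- x[-((i + 1L):j)]
      ss <- sum((inside - mean(inside))^2) +
        sum((outside - mean(outside))^2)
      sp2 <- ss / (n - 2)
      if (sp2 < 1e-300) next
      t <- abs(mean(inside) - mean(outside)) /
        sqrt(sp2 * (1 / k + 1 / (n - k)))
      if (t > best$t_max) best <- list(i = i, j = j, t_max = t)
    }
  }
  best
}

# Pairwise concordance AUC: P(score_case > score_control) + 0.5 P(equal).
oracle_auc <- function(s_case, s_ctrl) {
  tot <- 0
  for (a in s_case) for (b in s_ctrl)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s_case) * length(s_ctrl))
}

# Two-sided Fisher p by full hypergeometric enumeration over the observed
# margins (probability-mass method).
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_vals, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-chromosome grid + Z-profile fixture builders.
toy_grid <- function(n_bins, bin_size = 200000L, chrom = "chrT") {
  make_bins(setNames(n_bins * bin_size, chrom), bin_size)
}

toy_zprofile <- function(z, bin_size = 200000L, chrom = "chrT", ...) {
  z_profile(toy_grid(length(z), bin_size, chrom), z, ...)
}
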