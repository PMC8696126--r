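---
title: "Chromosomal instability scoring from low-coverage cfDNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosomal instability scoring from low-coverage cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcin)
```

## The problem and the model

Plasma cell-free DNA (cfDNA) from cancer patients is a mixture of fragments
shed by normal tissue and by the tumor. Copy-number variation (CNV) in the
tumor genome shifts the local abundance of tumor-derived fragments, so even
very shallow whole-genome sequencing (a fraction of 1x) carries a readable
copy-number signal once coverage is aggregated into large genomic bins.
`cfcin` turns that signal into a single scalar — a chromosomal-instability
(CIN) score — suitable as a prognostic biomarker, and implements the
survival statistics used to evaluate such a biomarker against clinical
outcome.

The pipeline has four stages.

**1. Binned coverage.** The genome is tiled with fixed bins (200 kb by
default; 100 kb and 400 kb are the usual alternatives, and the score is
defined so its length unit does not change with bin size). Each passing
alignment is assigned to exactly one bin by its leftmost aligned position —
a convention that avoids double counting at bin boundaries — and the bin
value is the summed read length divided by bin width, i.e. a mean depth.
Default filters are MAPQ >= 20 with duplicates and secondary/supplementary
alignments dropped. A sample with fewer than 10 million read pairs
completes with a QC warning rather than a hard failure, mirroring the
usual intake rule for this assay class.

**2. Panel-of-normals Z-normalization.** Binned coverage has strong
bin-specific biases (mappability, GC, copy-number polymorphism) that are
stable across samples. A panel of healthy controls captures them: after
each control is scaled by its own median bin value (bringing all samples
to a common depth scale), the panel stores the per-bin sample mean
$\mu_b$ and sample standard deviation $\sigma_b$ (n−1 denominator). A
sample's normalized coverage is

$$ z_b = \frac{x_b - \mu_b}{\sigma_b}, $$

with the sample median-scaled the same way first. Whether any depth
normalization or GC correction precedes this step is not standardized in
the assay literature; median scaling is our documented choice (it makes
the Z-profile exactly invariant to sequencing depth), and no GC or
mappability correction is applied beyond what the panel absorbs. Bins
where the panel is uninformative — $\sigma_b = 0$, or scaled mean below
`min_mean` (default 0.01, i.e. 1% of the median depth) — are masked and
excluded from everything downstream.

**3. Circular binary segmentation.** Each chromosome's unmasked Z series
is segmented by CBS: the best "arc" of the circularized series is the pair
of breakpoints $(i, j]$ maximizing the pooled-variance two-sample t
statistic between the arc and its complement, and the split is accepted
when a within-chromosome permutation test gives p below `alpha` (default
0.01); accepted splits are recursed. Defaults `nperm = 10000`,
`min_width = 2` and `undo_sd = 3` are the conventional CBS settings —
the method's published description names the algorithm but no parameters,
so all of these are exposed in the configuration.

Numerical details that matter:

* *Canonical arc enumeration.* Arcs $(i, n]$ describe the same circular
  split as $(0, i]$; only one representative is enumerated, so the
  lexicographic tie-break (smallest $i$, then $j$) is well defined rather
  than left to floating-point noise.
* *Monotone-transform scan.* For a fixed series multiset, the t statistic
  is a strictly increasing function of
  $c = u^2 \, n / (k(n-k))$ with $u$ the centered arc sum, and the total
  sum of squares is permutation-invariant. The scan therefore maximizes
  $c$ (a few flops per arc), and a permuted series is known to exceed the
  observed statistic as soon as any arc reaches the observed $c$.
* *Sequentially stopped permutations.* Each split test stops early when
  its decision at `alpha` is settled: accepted once 0 exceedances have
  been seen in ceil(7/alpha) permutations (the exact p is then bounded
  well under `alpha`), rejected as soon as the exceedance count makes
  p >= alpha certain or a normal lower confidence bound on p clears
  `alpha`. The reported p is the conservative (exceed + 1)/(m + 1).
* *Pruning.* Adjacent segments are re-merged while their mean difference
  is below `undo_sd` times its standard error (the pooled within-segment
  SD scaled by $\sqrt{1/n_1 + 1/n_2}$). We use the standard-error form
  deliberately: a raw-SD rule at `undo_sd = 3` would erase every
  realistic cfDNA signal, since tumor-fraction-scaled shifts rarely
  exceed 2–3 Z units.
* *Masked bins* are excluded from all statistics; segment bp spans include
  interior masked gaps, while `n_bins` counts unmasked bins only. A
  segment's recorded `p_value` is the significance of the accepted split
  that defined it (NA for a never-split chromosome).

**4. The CIN score.** Segments whose $|\bar z|$ reaches `z_threshold`
(default 2) are the copy-number-changed set, and

$$ \mathrm{CIN} = \log_2 \sum_{s} V_s \times L_s, $$

with $V_s = |\bar z_s|$ and $L_s$ the segment length in 200-kb units
(`n_bins` rescaled when another bin size is used). Two definitional gaps
are resolved as follows and flagged here: $V_s$ is the *absolute* mean Z —
gains and losses both add instability, and a signed sum could cancel and
make the logarithm undefined — and sums below 1 are floored to a score of
0, keeping the score defined and non-negative for near-flat genomes.
Samples at or above the cutoff (default 12, boundary inclusive) are
high-CIN. Cohort arm-level gain/loss frequencies call an arm altered when
qualifying segments cover at least `min_arm_fraction` (default 0.5) of
the arm.

## Survival statistics

The clinical validation toolkit wraps the standard estimators behind the
pipeline's interfaces: Kaplan–Meier curves with Greenwood variance and
log(−log) confidence bands, the median defined as the smallest time with
$S(t) \le 0.5$ (reported explicitly as "unreached" when the curve never
gets there, with its CI read off where the bands cross 0.5); reverse
Kaplan–Meier median follow-up (censoring treated as the event); the
log-rank test; and Cox proportional-hazards models with Efron tie
handling and Wald intervals — the conventional reporting choices.

The time-horizon survival ROC is the "naive" estimator, labelled as such:
at horizon $h$ (183 and 365 days by default, standing in for 6 and 12
months), cases are deaths at or before $h$, controls are patients observed
beyond $h$, and patients censored before $h$ are excluded and counted in
the output — the simplest defensible convention when the estimator behind
a published survival ROC is unstated; KM-weighted estimators are out of
scope. AUC is the trapezoid area (equal to pairwise concordance with ties
at 1/2), its CI a 2000-draw percentile bootstrap, and the operating cutoff
maximizes Youden's J with ties resolved to the smallest threshold.
Two-sided Fisher exact tests use the probability-mass definition. In the
two-parameter and multivariate Cox models the CIN covariate is entered as
the below-cutoff indicator; the univariate helpers accept either the
indicator or the continuous score.

## The synthetic-data generator

Every stage is testable without any sequencing download. The generator
emulates:

* a desk-scale genome — 4 chromosomes of 30/24/16/10 Mb, i.e. 400 bins at
  200 kb — small enough that a full panel + tumor + segmentation cycle
  runs in well under a second;
* shared bin bias: one lognormal draw per bin (sdlog 0.1), common to all
  samples, which panel normalization must cancel;
* sequencing noise: negative-binomial read counts with mean
  `reads_per_bin * bias`. The default `reads_per_bin = 1300` reflects the
  10M-read-pair intake over a ~15,500-bin genome; the default excess
  dispersion 0.002 puts the per-bin coefficient of variation near 5%,
  typical of this assay after duplicate removal. With these defaults a
  flat genome scores CIN well below 5, a sanity floor for the score's
  specificity;
* planted CNVs: inside an event of copy number $c$ at tumor fraction
  $\mathit{tf}$, expected coverage is multiplied by
  $1 + \mathit{tf}\,(c/2 - 1)$ — the standard cfDNA mixture model — so a
  single-copy gain at tf 0.3 shifts coverage by 15%, about 2.9 Z at the
  default noise;
* survival: exponential event times under a proportional-hazards model on
  the CIN score or the high-CIN indicator (default log-HR
  $\log(1/0.314)$ for the high class, baseline median survival 600 days),
  with independent exponential censoring; `censoring_rate_for()` solves
  for the rate hitting a target censoring fraction.

What it deliberately does *not* emulate: GC/mappability structure beyond a
static per-bin bias (so passing tests say nothing about GC correction),
fragmentomics, subclonal mixtures, read-level data, or the cancer-type
mixture of a real bone-metastasis cohort. Passing the planted-CNV and
planted-hazard suites demonstrates that the estimators recover what the
generative model puts in — not that the score's clinical performance on
real cohorts is reproduced, which would require the deposited sequencing
data.

A note on calibration: a held-out control normalized against an n-control
panel is t-like, with variance $((n+1)/n)\,((n-1)/(n-3)) \approx 1.17$ at
n = 20 — the tests assert that value rather than exactly 1.

## Problem sizes used by the test and acceptance suites

Simulation-backed checks run at sizes chosen to make Monte-Carlo verdicts
stable while keeping a full run in minutes: 100 random series (length
<= 60) for the exhaustive-oracle comparison, 100 seeded runs for the
planted 50-bin z = 4 recovery, 50 seeds x 4 tumor fractions for the
dose–response curve, 10,000 null simulations for log-rank calibration,
200 replicates at n = 2000 for Cox recovery at the published design point
(HR 0.314), and 50 seeds at n = 400 for Youden-cutoff recovery.

## Known limitations

* Integer copy-number calling, purity/ploidy fitting and tumor-fraction
  estimation are out of scope (that is a job for dedicated tools); the
  score operates purely on normalized coverage.
* Segmentation is per chromosome, not per arm.
* The ROC estimator excludes early-censored patients rather than
  reweighting them; with heavy early censoring it can be biased.
* No GC correction hook is enabled by default; panels and samples should
  come from the same library protocol.
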