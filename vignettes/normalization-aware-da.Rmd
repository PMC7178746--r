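---
title: "Normalization-aware differential accessibility analysis with danorm"
author: "danorm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization-aware differential accessibility analysis with danorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(danorm)
```

# The problem

ATAC-seq measures chromatin accessibility through the Tn5 transposase, an
enzymatic reaction whose efficiency varies between libraries with input
amount, nuclei quality and PCR depth.  When two cellular conditions are
compared region by region ("differential accessibility", DA), the choice of
count normalization decides which differences survive: methods anchored to
sequencing depth preserve global accessibility shifts (treating them as
biology), while methods that force a symmetric or identical signal
distribution remove them (treating them as technical bias).  On the same
data these choices can flip the apparent direction of chromatin change.
`danorm` implements the full fragment-to-DA-calls workflow with the
normalization step exposed as an interchangeable component, so an analyst
can run the whole grid of approaches and see how far the calls depend on
the anchor chosen.

# Data model and preprocessing

Fragments enter as 10-column BEDPE (`readBedpe()`, a validating parser:
mates on one chromosome, opposite strands, 0-based half-open coordinates).
Preprocessing follows the standard ATAC conventions:

* **Tn5 shift** (`tn5Shift()`): the transposase duplicates 9 bp at the
  insertion point, so plus-strand 5' ends are moved +4 bp and minus-strand
  5' ends −5 bp.  The `FragmentSet` carries a `shifted` flag and refuses a
  second application.
* **Minimal fragments** (`minimalFragments()`): each pair collapses to its
  outermost span; shifting precedes conversion.
* **Blacklist filtering** (`filterBlacklist()`): any record overlapping a
  blacklist interval by ≥ 1 bp is removed — the strictest reading, applied
  identically to peaks and fragments.

Internally intervals live in `GenomicRanges`; file interfaces are 0-based
half-open (BED family).

# Region definition

Two routes provide the tested regions:

* **Naive-overlap consensus** (`naiveOverlap()`): pooled-replicate peaks
  kept only if every individual replicate reproduces them at ≥ 50% overlap.
  The 50% is measured against the *shorter* of the two peaks
  (`bedtools -e -f 0.5 -F 0.5` semantics); `rule = "pooled"` restricts it
  to the pooled peak.
* **Sliding windows** (`makeWindows()`, default 300 bp, spacing = width)
  filtered by local enrichment (`localEnrichmentFilter()`): a window is kept
  when its fragment density exceeds threefold the density of the
  surrounding 2 kb neighborhood (own counts excluded).  The neighborhood
  count is rescaled to window-width equivalents *before* the 0.5 continuity
  correction is added to both sides; this makes the empty-over-empty case
  exactly 1 (dropped) and prevents empty windows from ever passing — a
  correction on raw counts would instead hand empty windows a spurious
  width-ratio enrichment.  Tested windows closer than 100 bp merge into
  regions (`mergeWindows()`), each scored by the Simes combination
  min_i k·p(i)/i of its member p-values, which keeps type-I error control
  for the merged test; BH runs across merged regions.

Low-abundance regions are removed by `abundanceFilter()`; the default
cutoff is the average log2-CPM of a hypothetical region holding 5 fragments
at the mean library size — small enough to keep genuine peaks, large enough
to drop noise-dominated windows — and is an explicit knob.

# Library complexity

Unequal molecular complexity (distinct sequenced molecules) confounds count
comparisons even at matched depth.  `danorm` estimates complexity from the
duplicate-frequency histogram with the Lander–Waterman saturation model
C = N(1 − exp(−R/N)), solved for N by bisection on [C, 1e12·C] at 1e-6
relative tolerance.  The model is transparent and testable by simulation
(the estimator recovers a planted N = 10,000 from R = 50,000 uniform reads
to well under 5% median error); the histogram is retained so a
rational-function extrapolation estimator could be added behind the same
interface.  `equalizeComplexity()` takes as target the *observed distinct
count* of the least complex library (an operationally checkable quantity,
rather than the model's N̂ itself), solves each library's binomial thinning
rate so its expected distinct count matches the target (the expectation
Σ n_j (1 − (1−p)^j) is strictly increasing in p), and subsamples reads with
one seeded stream per library (`seed + index`, so adding a library never
perturbs the others).  At least one library always keeps p = 1.
Deduplication, when requested, follows thinning.

# Quantification and the six normalizations

`countFragments()` counts a fragment into every region it overlaps by
≥ 1 bp (a midpoint mode is available); `binGenomeCounts()` tiles 10-kb bins
for background-driven scale factors; library sizes are full post-filter
totals, not matrix column sums.  The log2-CPM transform is
log2((y + 0.5)/(L + 1) × 1e6).

The six normalization strategies all produce a `NormalizationResult`:

| method | output | assumption |
|---|---|---|
| `libsize` | factors ∝ L | global differences may be real |
| `reads_in_peaks` | factors ∝ in-peak sums | efficiency differs, enrichment should match |
| `tmm` | trimmed weighted-mean factors | most bins unchanged |
| `loess` | per-observation log2 offsets | symmetric distribution, no true global change |
| `log2cpm_only` | identity on log2-CPM | as libsize |
| `quantile` | transformed matrix | identical distributions |

TMM details: reference = sample whose upper-quartile CPM is closest to the
mean; bins with a zero in either compared sample excluded pairwise; the top
and bottom 15% by log-ratio M and 2.5% by abundance A are discarded (rank
ties broken by position so the trim is exactly reproducible by a sort-based
oracle); the factor is 2 to the precision-weighted mean of surviving M
values with delta-method binomial weights, and factors renormalize to unit
geometric mean.  Fewer than 10 surviving bins triggers a warning and the
untrimmed weighted mean.

Loess details: on log2(count + 0.5), each sample's deviation from the row
mean is regressed on the row mean with a robust (bisquare, 3 iterations)
local *linear* fit at span 0.5 — stable for the 2,000–25,000-region
matrices this workflow produces — and the fitted values, row-centred,
become offsets.  The offsets are subtracted from log2(count + 0.5) itself
(they already absorb depth); a single common constant then places the
matrix on the log2-CPM scale.  Subtracting them from per-sample log2-CPM
would remove depth twice.  Degenerate inputs (all abundances equal, or a
constant deviation as with duplicated samples) bypass the smoother and
return the constant directly.

Quantile normalization maps each column's order statistics onto their
across-column means; within-column ties receive the mean of their target
quantiles.  Sorted columns are bit-identical afterwards for tie-free input;
with integer counts, tie-averaging leaves sub-0.02 log2 discrepancies
between sorted columns, which is inherent to tie handling and not an
implementation artifact (the implementation agrees with
`limma::normalizeQuantiles(ties = TRUE)` to machine precision).

# Testing engines

The primary engine (`fitModerated()`, optionally with `voomWeights()`) is a
weighted linear model on the normalized log2 matrix with empirical-Bayes
variance moderation: per-region residual variances are shrunk toward a
prior estimated by moment matching on log s², using the closed-form
digamma/trigamma system (zero-variance regions are excluded from the
hyperparameter fit; the trigamma inverse is a Newton iteration).  The
moderated t uses d0 + d degrees of freedom; d0 = 0 recovers the ordinary
t-test and d0 = ∞ a common-variance z-like test.  One engine across all
normalizations isolates the normalization effect — the package's point —
instead of confounding it with differences between count-model machineries.
The observation weights follow the mean–variance idea: lowess of √(residual
sd) on mean log2 count, weights = trend(fitted log-count)^-4, clipped to
[1e-6, 1e6].

A second, count-scale engine (`nbExactTest()`) serves factor
normalizations: counts rescale to a common effective library size, a common
NB dispersion comes from the method of moments φ = mean(max(0,
(s² − μ)/μ²)) — with the *pooled within-group* variance and grand mean, so
genuine group differences do not inflate φ — and each region is tested
conditionally on its total (group sums are NB(n_k μ, φ/n_k)); the
two-sided p doubles the smaller tail (capped at 1; a smallest-likelihood
summation mode is a flag).  φ = 0 falls back to the Poisson/binomial
branch.  Offset and transform normalizations cannot feed this engine and
are rejected.  Multiplicity control is BH throughout (`bhFdr()`), with
FDR < 0.10 as the working threshold and FDR < 0.05 for negative controls.

# Diagnostics

`maData()` attaches a robust loess trend to the (A, M) scatter — an upward
shift flags a global effect or bias, curvature flags a trended bias that
linear factors cannot remove.  `fdrAtRejectionRate()` reports the FDR
cutoff at which a given fraction of tested regions is rejected (fraction of
*tested* regions; approaches can differ by orders of magnitude here).
`annotatePromoters()` classifies regions against strand-oriented TSS
windows (±3 kb default; −2000/+200 for compact genomes like yeast), keeps
every overlapped gene link, and reports the per-gene minimum promoter FDR.
`prCurve()` sweeps genes by 1 − FDR with ties grouped and integrates
precision over recall increments; `enrichment()` is the upper-tail
cumulative hypergeometric with an observed/expected ratio;
`compareApproaches()` and `classMeanLogfc()` reproduce the cross-approach
and time-course summaries.

# The simulators and what they do (not) show

`simulateCounts()` draws NB counts (variance μ + φμ²) with a log2-normal
baseline and plants three controllable distortions in condition B: true log
fold changes on a chosen fraction of regions, a global efficiency
multiplier, and an M-distortion linear in abundance — the minimal trended
shape that loess corrects and linear factors cannot.  Defaults (m = 10,000;
n = 3 vs 3; baseline log2 mean ~ N(5, 2) at L = 1e6, i.e. typical peak
counts of a few tens; φ = 0.05, a biological CV of ~22% as seen between
well-matched replicates; |lfc| ~ N(2, 0.5), the magnitude range of clear
chromatin remodelling events) were fixed as the package's study conditions
and are not tuned per analysis.  `simulateFragments()` generates BEDPE
libraries molecule-first: N distinct molecules placed peak-weighted, then R
reads drawn *with replacement*, so the duplicate histogram — and therefore
estimable complexity — is controlled by R/N.

The simulators emulate count statistics, composition, efficiency bias and
duplication; they do not emulate sequence content, GC or Tn5 sequence
preference, fragment-length structure beyond a clipped normal, or
correlated biological heterogeneity.  Passing tests therefore demonstrate
the statistical machinery, not robustness to sequence-level artifacts.

A caution the simulations make concrete: with *genuinely* asymmetric
biology (20% of regions truly up), depth-anchored normalization reports the
planted majority-up signal, while loess and quantile redistribute part of
it into induced down-calls on null regions.  The calls move toward sign
balance but do not reach an exact 50/50 split: detection power for the
large planted effects and for the small induced shifts would have to
coincide exactly.  Symmetry-forcing methods are conservative against bias
precisely because they spend true global signal — both directions of that
trade-off are visible in the package's own diagnostics.  Relatedly, *where*
TMM is computed matters: factors from 10-kb background bins absorb depth
only and leave within-peak composition bias untouched, while TMM on the
peak matrix itself recenters the null peaks — the anchor decides the
result.

# Problem sizes and numerical choices

The shipped checks run at desk scale by design: oracle comparisons on
≤ 1,000-bin matrices; trend removal and direction composition at m =
8,000–10,000; null calibration with 200 replicates of m = 1,000 across all
six normalizations; complexity recovery over 100 seeds; the fragment
pipeline on 200 peaks (20 planted, 3 vs 3, ~60k read pairs/library) and the
two-seed reproducibility scenario on 400 peaks (100 planted).  Bisection
tolerances are 1e-6 (relative, complexity) and 1e-9 (thinning rate); the
loess smoother uses `surface = "interpolate"`; weights clip at [1e-6,
1e6]; the continuity prior is 0.5 throughout.  Trend summaries are
evaluated over the central 90% abundance range, where local regression is
supported by data.

# Known limitations

* The NB exact test uses a single common dispersion; per-region shrinkage
  of dispersions is out of scope, and the moderated engine is the primary
  route.
* Naive-overlap requires explicit replicate peak sets; peak calling itself
  (Poisson local-background models) is upstream of this package.
* Complexity equalization assumes equal-propensity molecules; a strongly
  skewed molecule distribution biases the saturation estimator downward.
* Promoter windows anchor on the TSS base; under strand flips the
  half-open convention moves window edges by one base, so boundary regions
  can change class.
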