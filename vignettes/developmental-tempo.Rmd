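---
title: "Methods: inferring developmental tempo from chimeric time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring developmental tempo from chimeric time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterochron)
```

# The problem and the model

Two species' cells differentiating in one dish follow their own
transcriptional programs, but the *tempo* of those programs can respond
to the chimeric environment. The observable is a bulk RNA-seq time course
of the mixed culture, quantified against a joint two-species reference so
that every expected count is attributed to a species-tagged gene. The
quantity of interest is the per-condition acceleration factor
$a(t) > 1$: how much faster a test condition (say, 10% human cells among
mouse, "H10") traverses the same program than a reference condition
(pure human, "H100").

The package models each gene's expression over time as a continuous
piecewise-linear trend on the normalized-count scale. Tempo differences
are read off *event times* of those trends — the start of the first
qualifying up-trend and the first peak — rather than from expression
levels, which makes the estimate robust to level differences between
conditions. The time warp connecting conditions is
$w(t) = \int_0^t a(s)\,ds$ with $\mu_{\text{test}}(t) =
\mu_{\text{ref}}(w(t))$: an event occurring at reference time $\tau$
appears in the test condition at $w^{-1}(\tau)$, so per-gene ratios
$t_{\text{ref}} / t_{\text{test}}$ estimate $a$ at the test event time.

# Stage by stage

## Species separation and misalignment

Gene ids are `tag_SYMBOL` with an underscore separator and a configurable
tag list (default `hg19`, `mm10`). Mitochondrial genes (symbols beginning
`MT-`/`mt-`, overridable with an explicit list, since the original gene
set is not enumerated anywhere) are removed before any analysis: their
abundance is inconsistent across samples. In pure-species samples, counts
on the other species' genes are alignment errors; `misalignment_rate()`
reports that fraction per sample, with zero-depth samples flagged rather
than failing. The rate is scale invariant by construction.

One quantile convention is used everywhere: linear interpolation between
order statistics (R type 7). Under it, the activity rule "0.8 quantile of
counts ≥ 20" includes a gene whose quantile is exactly 20, while the
trend-fitting eligibility rule ("above 20 in at least one mixture") is
strict.

## Quality control

*Depth filter.* Samples below median − 1.5·IQR of log10 total expected
counts are removed; an all-zero sample counts as below any threshold.
Low depth predicts high misalignment, so this filter is also the
misalignment guard. Note that under any untruncated symmetric depth
distribution this rule removes a fixed ~2% of samples; it presumes (as
in depth-balanced pooled libraries) that routine variation is bounded
and extremes indicate failure.

*Replicate filter.* Per mixture: the 1000 highest-variance genes are
reduced to 10 centered principal components; each component's loadings
are regressed on day with a degree-4 polynomial spline (no interior
knots); the per-sample statistic is the maximum absolute externally
studentized residual over components, referred to a t distribution with
n − 6 degrees of freedom and BH-adjusted across samples. Backward
elimination removes the smallest adjusted p below 1e−05 (refitting each
round, and never removing a time point's last sample); forward selection
then re-admits removed samples whose adjusted p rises above the
threshold. Two conventions deserve comment:

* The maximum of 10 |t| statistics is not itself t distributed; the
  single-t reference is kept deliberately (it only makes the test more
  conservative after BH at 1e−05, and it is the procedure as described).
  The degrees of freedom and the component count are parameters.
* Variance ranking and PCA run on `log2(x + 1)` expression
  (`log_transform = TRUE`, recorded in the report). On the raw scale,
  loading noise grows with expression magnitude over the course, so
  late-day samples of a clean cohort are flagged for heteroscedasticity
  rather than outlierness; the log scale removes that artifact.

## Normalization

Per species, two stages: size factors within each (mixture, day)
replicate group, then size factors across the arithmetic means of the
stage-1-normalized replicate profiles of *all* groups — days and
mixtures together — applied back to each group's samples. Factors come
from scran's pooled deconvolution estimator for any group size; for
groups too small to pool (triplicates), scran degrades to robust
library-size factors, which in particular are immune to a corrupted
replicate (a scrambled sample preserves its depth). A median-of-ratios
estimate against a geometric-mean pseudo-reference is retained as the
error fallback. All factor sets are rescaled to mean 1, so normalized
values are defined up to a cohort-level scalar.

## Segmented trend regression

For each gene, expression is fit against time by a connected
piecewise-linear curve (`fit_segmented()`):

* Breakpoint candidates are the observed days — matching the resolution
  at which leads ("2 days earlier") are interpreted downstream.
* Every segment must contain at least `min_points` observations
  (default 5; the sorted-sample preset uses 2). Replicates count
  individually, and observations lying exactly on a breakpoint count for
  both adjacent segments.
* For k = 0, 1, 2 breakpoints the least-squares optimum is found
  exhaustively (vectorized over genes via shared QR factorizations); for
  k = 3, 4 a greedy insertion from the best k−1 solution is followed by
  one pass of neighbor refinement. The exhaustive property is asserted
  by an independent enumeration oracle in the test suite.
* The breakpoint count is chosen by BIC, $n\log(\mathrm{RSS}/n) +
  (2+2k)\log n$, with RSS floored at 1e−10 so that perfect fits compare
  finitely; exact ties resolve toward fewer segments.
* Segment directions come from t-tests on the segment slopes at
  α = 0.1 ("flat" when not rejected). For numerically perfect fits the
  t-test is meaningless; slopes below 1e−8 of the data scale are then
  flat, all others certain.

Degenerate inputs are defined: constant expression gives one flat
segment; when no breakpoint placement is feasible the line fit (k = 0)
is returned.

## Events, classification, acceleration

`extract_events()` takes the first increasing segment not preceded by any
decreasing segment (up-start) and the first increasing→flat/decreasing
breakpoint (peak). Classification against a reference condition:

* **Early-Up**: lead ≥ 2 days *and* test up-slope ≥ 5× the slope of the
  reference segment containing the test start time — the guard removes
  genes whose reference segment is labeled flat but fitted with an
  appreciable rise. When the test start falls exactly on a reference
  breakpoint, the segment *ending* there is used. Genes up-trending from
  day 0 in both conditions are excluded. Late-Up is the role-reversed
  rule, and the whole calculus is antisymmetric under swapping test and
  reference (a property test checks 1000 random fit pairs).
* **Early/Late-Peak**: a pure ≥ 2-day lead on first peaks.
* **DE-Up/Down**: max fitted + 1 at least 3× the other side's; the +1
  bias keeps low expressors from looking DE.

Acceleration point estimates are per-gene time ratios with peaks
preferred over up-starts (breakpoint interior placement makes peaks the
sharper marker); genes whose up-trend starts at day 0 in either condition
are discarded (also the division guard). The continuous curve is a
cubic basis-spline least-squares fit (df = 4) of ratio against test
event time, after winsorizing ratios at the 1st/99th percentiles — ratio
estimators explode for events near day 0. The summary statistic is the
median of the *fitted* curve on a uniform grid over test-event days
0–16, the literal reading of a "median fitted acceleration factor".
Smoothing is a conditional-mean estimate, so at strong warps (≳2.5×),
where event times compress into a few grid days, it attenuates the
median a little below the raw point-estimate median; the dose *ordering*
across conditions is unaffected, and that is what the validation
asserts.

## Correlation-based acceleration

An independent estimate aligns the two conditions' day axes directly:
Spearman correlations between replicate-averaged day profiles over the
2000 most dynamic genes (highest CV of fitted values across mixtures;
rank correlation makes normalization unnecessary, so raw expected counts
are used). The two-piece line through the origin with a fixed breakpoint
at test day 16 and slopes in [1/10, 10] is fit by minimizing
$\sum_{ij} \mathrm{cor}^2(t_i,t_j)\,d_\perp^2((t_j,t_i))$ with L-BFGS-B
from slopes (1, 1); undefined correlations are dropped; gene bootstrap
(default 200 draws) gives slope standard errors. The first-segment slope,
in reference days per test day, is the acceleration factor.

One refinement: when a condition's program has cumulatively run past the
span the other condition covers (with $a = 1.7$ over 16 days the test
course ends ~11 reference-days beyond day 42), its late days all
correlate best with the boundary day of the other axis. Those saturated
pairs carry high weight but no tempo information and demonstrably bias
the fit. `censor_saturated = TRUE` (default) drops day pairs whose
correlation ridge peaks at the opposite axis boundary — a data-driven
rule that uses no ground truth and leaves maps without saturation
essentially untouched.

## Reference comparison

External reference profiles are compared on the union of the top 1500
most dynamic in vitro genes and the top 1500 reference genes by CV
across reference samples, with an error when less than half the union
maps into both identifier spaces. Staging uses Euclidean distances in a
6-dimensional count-model reduction: the default path computes
negative-binomial deviance residuals (per-gene moment dispersions) on
size-factor-normalized counts and takes principal components.
Normalizing *before* forming residuals makes coordinates exactly
invariant to depth changes matched by the size factors, which raw-scale
residuals are not. A generalized NB-PCA (Fisher-scoring alternation,
ridge penalty 10, ≥ 400 iterations) is available behind
`method = "glmpca"` and falls back to the residual path on failure.
Distances are smoothed per mixture with a basis spline in day; the
minimizing day is the staging estimate. All mixtures and the reference
enter one joint reduction — distances are only comparable within a
single reduction. When a reference panel is in FPKM-like units, in vitro
counts are the best available analog and the mismatch is a declared
caveat of that comparison.

## Enrichment

Over-representation is a one-sided hypergeometric test against the
background of all fitted genes, BH-corrected; flat set lists only (no
ontology traversal). The continuous analysis scores each set by the mean
per-gene timing difference (reference minus test event time, peaks
preferred, 0 without a shared event) and compares it to size-matched
random gene draws without replacement: two directional p-values
(acceleration / deceleration), each BH-adjusted. Draws depend only on
the seed and the set sizes, so negating every statistic swaps the two
directions exactly. The desk default is 1e5 permutations; the full-scale
setting (4e6) is a parameter.

# The synthetic generator

`simulation_config()` defaults encode the emulated study design: a
42-day course sampled daily for two weeks and every second day after,
three replicates, a pure-human reference plus a 10%-human mixture whose
human genes run at 1.7× tempo until day 16; negative-binomial counts at
dispersion 0.02 (BCV ≈ 0.14 — isogenic culture triplicates processed
together, not population-level variation); per-sample depth log-normal
around 1e6 with CV 0.3, truncated at ±2 sd (routine depth variation in
depth-balanced pooled libraries is bounded; extremes are the
injected-outlier failure mode); 0.5% cross-species bleed-through applied
binomially per count and reassigned to the other species' genes in
proportion to their means — so bleed is the *only* cross-species
contamination, matching the reading of misalignment as error. Mixed
cultures drift in composition logistically (0.183 logit units/day, so a
10% seed reaches ~50% human by day 12). Gene programs are drawn from
five archetypes (flat, rise, rise-then-flat, peak, fall) with
breakpoints ≥ 5 days apart at the default course length and amplitudes
chosen so trends stay non-negative. The default mix is majority-stable
(45% flat): size-factor normalization presumes that most genes do not
change, and a generator violating its own pipeline's central assumption
would measure normalization failure, not tempo recovery — even so,
total simulated abundance rises over the course, leaving a small
residual drift on flat genes that mimics real compositional bias.
Trends are piecewise linear in normalized-expression units — the same
space the regression fits, which is what makes noise-free breakpoint
recovery a meaningful oracle.

What the generator does *not* emulate: isoform-level quantification
noise, batch effects, gene–gene correlation beyond the shared warp,
mouse-side tempo responses (available via `mouse_warp_rate` but not a
default), or FACS-sorted designs. Passing validation on this generator
therefore demonstrates the estimators' correctness under the stated
noise model, not robustness to every artifact of real data.

Injectable failures: low-depth outliers rescale a sample's counts;
scrambled replicates permute a sample's counts across genes (depth
preserved — which is exactly why library-size stage-1 factors keep the
scrambled sample from dragging its siblings down).

# Validation protocol and problem sizes

The acceptance suite (one test per operating characteristic) runs, as
the package's chosen validation sizes: exhaustive-oracle equality and
±1-grid-step breakpoint recovery on 200 noise-free grid-aligned trends
over a 22-point grid; 1.7× warp recovery on ten 500-gene cohorts (each
window median within 1.7 ± 0.15) plus the exact identity null;
dose-ordering of 2.7/1.7/1.35 warps over 20 seeds; event-vs-correlation
agreement within 10% with 200 bootstrap draws; QC operating
characteristics over 50 cohorts (100% low-depth sensitivity, ≥ 99%
clean retention, singleton protection); the classification truth tables
and 1000-pair antisymmetry; enrichment against exact hypergeometric and
exhaustive permutation nulls at 1e5 permutations; bleed-rate recovery
within its binomial interval on 1000 pure samples; and dissimilarity
staging order over 10 seeds. `scripts/acceptance.R` recomputes the same
quantities from scratch at a given seed.

# Known limitations

* Breakpoints are confined to observed days; true change points between
  sampling days appear as the nearest day or as a bracketing pair, and
  event-time quantization attenuates strong warps (see above).
* The max-of-components t reference in QC is intentionally naive;
  its role is ranking samples for elimination under a very small
  threshold, not calibrated inference.
* The correlation-acceleration model is a two-piece line with a fixed
  breakpoint; continuously varying warps are summarized, not tracked
  (no dynamic-time-warping).
* The timing-difference enrichment uses the mean set statistic only.
* Ratio-based acceleration is undefined for genes whose events sit at
  day 0; such genes are excluded, which slightly biases the panel toward
  later-activating programs.
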