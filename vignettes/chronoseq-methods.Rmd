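---
title: "chronoseq: methods and design notes"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{chronoseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chronoseq` analyzes densely sampled bulk RNA-seq time courses of the kind
produced by immune-stimulation experiments in *Drosophila*: a baseline at
0 h, twenty post-stimulation time points out to five days (dense over the
first 24 h), and two replicates per time point. This vignette explains the
statistical machinery stage by stage, the synthetic-data generator that the
test suite and the analysis scripts are built on, and the design decisions
taken where more than one reasonable choice existed. Everything stated here
about performance is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The synthetic experiment

The generator (`simulate_experiment()`) is the answer key for every
recovery study. Each gene belongs to one of six temporal classes, expressed
as a log2-fold-change deviation from a gene-specific baseline:

* **immediate-sustained** — linear rise to the peak (default 5 log2FC at
  1.5 h), then slow exponential relaxation toward a sustained level
  (default 70% of peak, time constant 48 h). These emulate antimicrobial
  peptide genes that stay induced through day five.
* **transient** — a gamma-shaped impulse `(t/p)^k exp(k(1 - t/p))` peaking
  at 5–7 h (default 3 log2FC) and resolving to baseline by 2–5 days, the
  shape of Toll-responsive effectors.
* **dip-then-peak** — a negative bump at 1.5 h followed by a positive peak
  near 10 h, returning by 48 h (stress-family genes).
* **metabolic dip** — a negative bump bottoming at 6 h and recovered by
  24 h (carbohydrate/lipid metabolism genes during the trade-off phase).
* **cyclic** — a cosine with 24 h period and amplitude 1 log2 (circadian
  genes).
* **flat** — constant; housekeeping background.

Baselines are drawn from `N(8, 1.8^2)` on the log2 scale and library sizes
log-normally around 2×10⁷, so that the matrix spans the realistic range
from noisy tens-of-counts genes to deep thousands-of-counts genes. Counts
are negative binomial with a gene-shared dispersion of 0.05 (the Poisson
limit is used at dispersion zero). The default fixture has 2,000 genes
(85% flat) — large enough for empirical-Bayes pooling and BH families to
behave as they would genome-wide, small enough that the full pipeline runs
in seconds.

**Couplings.** Directed lag couplings plant lead-lag structure: a `direct`
coupling adds `coefficient ×` the source's deviation at grid step *t* to
the target at step *t + lag*, per replicate, processed in time order so
chains propagate. Lags count index positions, not hours, mirroring how the
sliding-window analysis treats consecutive samples. The default fixture
plants 20: five negative couplings from transient drivers (the
immune-up/metabolism-down trade-off motif), three negative couplings among
cyclic genes (which the network filter must exclude), ten positive
couplings, and two hidden-driver confounded pairs in which a latent impulse
feeds two genes at lags differing by one step with no direct link — the
canonical trap for bivariate lead-lag testing. Coupling coefficients are
±1.5 (amplifying), putting target swings around 4.5 log2, within the range
the strong responders themselves span.

Two focused systems support the network studies. The
`confounded_triplet_system()` uses a sharp early impulse driver (peak 4 h,
shape exponent 3): a *slow* driver is locally linear inside a 6-point
window, which makes the lag-2 copy affinely predictable from the lag-1 copy
and dissolves the very confounding the study measures; a sharp impulse
preserves it. The `gc_recovery_system()` staggers five negative-coupling
drivers at peaks 4–12 h with 5 log2FC amplitude: distinct shapes keep each
driver–target pair identifiable against the others, and the amplitude (the
upper range of observed immune impulses) gives each 10-transition window
enough power that three-consecutive-window runs are attainable at all. Both
were fixed by pilot power analysis at design time and then frozen.

`simulate_gc_system()` generates directly on the normalized log2 scale
(deviations plus Gaussian noise, default sd 0.15 — typical replicate
scatter for moderately expressed genes) for studies where the count layer
would only add an irrelevant transform.

What the generator does **not** emulate: batch effects beyond an optional
replicate offset, gene-length and GC biases, isoform structure, outlier
samples, or correlated biological noise across genes. Passing recovery
tests here demonstrates that the inference machinery is correct and
calibrated under its own assumptions, not that those assumptions hold in
any particular real data set.

## Preprocessing

Filtering is two-stage: drop genes with all-zero counts, then keep genes
whose *library-size-normalized* count exceeds 5 in at least two samples
(strictly greater; applied before the log transform, since a threshold of
5 on log2 values would be an implausible cutoff). Normalization is
`log2(count × (mean library size / sample library size) + 1)`; the +1
keeps zeros finite and stabilizes the low-expression end.

TMM scale factors follow the trimmed-mean-of-M-values recipe: gene-wise
log-ratios of relative proportions against a reference sample (the one
whose upper-quartile proportion is closest to the mean of those quartiles),
doubly trimmed — 30% on M, 5% on A, each side — and averaged with
inverse-delta-method-variance weights; factors are rescaled to geometric
mean one. The implementation matches `edgeR::calcNormFactors` to 1e-10 on
test matrices, and a longhand oracle to the same tolerance.

One pipeline-level choice matters: `preprocess_counts()` feeds
**TMM-effective library sizes** (library size × factor) into the log2
normalization. With sixty genes induced 5–6 log2FC, the induced mass
inflates the column totals of stimulated samples by severalfold; plain
library-size normalization then drags every unchanged gene down, which the
per-timepoint tests happily "detect". Compositional correction is exactly
TMM's job, so the pipeline applies it at the normalization step.
`normalize_log2()` itself keeps the plain library-size contract for callers
who want it. PCA runs on the top-500-variance genes of the log2 matrix,
gene-centered; this is a descriptive display, not an inferential step.

## Spline and per-timepoint differential expression

Counts are made amenable to weighted least squares by precision weights in
the voom style: log2-CPM with a 0.5 offset on TMM-effective library sizes,
gene-wise least squares on the design, a lowess trend (span 0.5) of the
square-root residual standard deviation against average log2 count, and
per-observation weights equal to the trend value at the fitted log2 count
raised to the −4 (i.e., inverse predicted variance).

The time-dependence test fits an intercept plus a natural cubic spline with
3 degrees of freedom (interior knots at quantiles of the restricted sample
times, boundary knots at the extremes) by weighted least squares per gene,
restricted to either the first 8 h or the first 48 h. Replicates enter as
independent samples sharing the time covariate. Gene-wise residual
variances are squeezed by an empirical-Bayes scaled-inverse-chi-square
prior whose degrees of freedom and scale are estimated by moment matching
on the log variances (digamma/trigamma identities, Newton inversion of the
trigamma function); the moderated F tests the three spline coefficients,
never the intercept, and BH runs across genes. The two horizons are
complementary: the 48 h fit resolves slow dip-and-recover trajectories
(sensitivity ≥ 0.9 on the metabolic-dip class in the test suite), while an
early impulse that resolves by 8 h is partially smoothed away at 48 h — the
property study measures detection 0.998 vs 0.954 at the default impulse
(2.5 log2FC peaking at 1.5 h), pooled over 20 fixtures.

The cubic-polynomial alternative is ordinary least squares on
`1, t, t², t³` over 48 h with an overall regression F, BH, and a selection
gate requiring both q < 0.05 and R² ≥ 0.6 — a deliberate composite of
statistical and practical significance.

Per-timepoint contrasts test each post-baseline time point (≤ 48 h) against
0 h with a moderated t. With two replicates per group an unmoderated t is
hopeless, so the gene variance comes from a one-way (time-point groups) fit
over the full matrix and is squeezed across genes; BH is applied across
genes *within* each time point, not across the gene × time grid. Tiered
selection follows the stated thresholds: tier A (q < 0.05, |log2FC| ≥ 1,
≥ 1 time point), tier B (≥ 2 log2FC), and the core tier (q < 0.01,
|log2FC| > 2 — strictly — at ≥ 2 time points); the differing strictness of
the fold-change inequality mirrors the differing phrasings of the tier
definitions, and nesting core ⊆ B ⊆ A holds by construction. The
predominant set unions spline detections with tier B; the master set for
network inference keeps predominant genes that carry a functional
annotation and at least 2 log2FC somewhere (the synthetic truth's class
labels stand in for annotation).

## Profile clustering

Trajectories are replicate-averaged and z-scored per gene; constant genes
go to a sentinel cluster with a warning. Hierarchical clustering is
average-linkage on Pearson distance (1 − r) or Euclidean distance, with
the tree cut at k = 4; genes are ordered by identifier before clustering
so assignments cannot depend on input order. On the four non-cyclic signal
classes the adjusted Rand index against the planted labels is 1.0 in the
recovery study. Average linkage is the package default (the linkage in the
reference workflow is not fixed; the choice is exposed).

The autocorrelation distance between two series is the Euclidean distance
between their first `n_lags` (default 10) simple autocorrelation
coefficients with uniform lag weights. Replicates are handled as segments:
lagged products never cross the replicate boundary, while centering and
normalization use the pooled series. The estimate matches `stats::acf` on
single segments to machine precision and the AR(1) closed form
`sqrt(sum((phi1^i - phi2^i)^2))` within 0.05 at length 10⁴. The similarity
network keeps the top 1% most-similar pairs as edges and reports connected
components; no significance test is attached to these distances — a
defensible test statistic for ACF distances is not established, so the
percentile rule stands alone.

## Rhythm detection

The dense grid is resampled to nine regular 6 h points (0–48 h); the
unsampled 18 h value is the mean of the 16 h and 20 h values (for a 24 h
cosine, the interpolation error is bounded by the curvature term at 18 h,
which the unit tests check). Each gene is compared against a lattice of
cosine templates — periods 18, 24, 30 h, phases stepped by the 6 h
sampling interval, twelve templates in all — via Kendall's S, with both
replicates entering as duplicated template ranks. The stated period range
"18 to 30 h" spans 3–5 sampling intervals; the accompanying "4 to 6 time
points" phrasing cannot be reconciled with 6 h spacing, so the three-period
lattice is used and the discrepancy noted rather than guessed around.

Because the templates are tied (a cosine on a 6 h grid takes few distinct
values), S is a linear function of a Jonckheere–Terpstra count over the
template's tie groups, whose exact null is the convolution of exact
Mann–Whitney U distributions. The convolution is done by exact polynomial
multiplication (an FFT would break the perfect symmetry of the null at the
last few ulps, and with it deterministic tie-breaking between a phase and
its anti-phase); group sizes are sorted first so templates with the same
tie structure get bit-identical nulls. Two-sided exact p-values are
Bonferroni-corrected within gene over the twelve templates; on exact ties
the positively correlated template wins. The suite verifies the null
against full permutation enumeration at n = 6 and the p-value's invariance
under monotone transformations. BH runs across genes, and selection
requires Q < 0.05 and fitted cosine amplitude strictly above 0.5 log2
(least-squares fit at the winning period and phase; the amplitude estimator
of the original rhythm detector is not pinned down anywhere, so the
package fixes this transparent one).

**Known limitation.** On the 2,000-gene rhythm fixture the selection is
93% sensitive with ~0.1 flat false positives per fixture; about 10% of
fixtures contain one. The mechanism is always the same: a gene expressed
around 2⁵ counts has log-scale noise near 0.45, occasionally ranks
concordant with a 30 h template (the exact p-values are honest — this is
the uniform null doing what uniform nulls do), and its fitted amplitude,
inflated by selection, clears 0.5. The amplitude gate has no power against
high-noise genes; an amplitude criterion expressed relative to a gene's
own noise level would, but is not part of the reference procedure, so the
behavior is documented rather than papered over.

## Gene-set scoring

For each time point, the paired statistic per gene is the mean of the
within-replicate (time − baseline) log2 differences divided by the standard
deviation of those differences plus an exchangeability constant s₀, taken
as the median of the per-gene difference standard deviations (at two
replicate pairs, a raw paired t would be dominated by its denominator).
The maxmean set score takes the larger of the mean positive part and the
mean negative part of the member statistics, signed accordingly, ties
broken positive; it is restandardized by the mean and standard deviation of
the same functional over random same-size gene sets. With only four
distinct paired label flips available, the permutation null augments label
flips with gene-row randomization (both components of the published
gene-set-analysis algorithm); p-values use the add-one convention and so
are never exactly zero. A consequence: the null has no finite enumeration,
so there is no "exact enumeration" mode — calibration is demonstrated
empirically (flat-set p-values uniform across fixtures; planted
immediate-sustained sets score "up" with p < 0.05 in ≥ 9 of 10 fixtures).

## Lead-lag network inference

Windows are six consecutive grid positions (16 windows on the 21-point
design), overlapping by five, indexed from 1; a window is "within the
first 24 h" iff its last time point is ≤ 24 h, which on the design grid is
windows 1–9. Within each window and replicate every gene is centered and
unit-scaled, and the five within-replicate lag-1 transitions are stacked —
ten transitions in total; no transition crosses the replicate boundary.
(A sample-size accounting of "12" for such windows double-counts the
endpoints; ten is what six time points per replicate realize.)

**Bivariate.** For the ordered pair x → y, ordinary least squares of
`y_{t+1}` on an intercept, `y_t`, and `x_t`, with a two-sided t-test on the
`x_t` coefficient. The intercept follows `lm()`'s default formula — the
centered series still leave the response's window mean nonzero, and
omitting the intercept measurably degrades both calibration and power.
Per-window standardization makes the coefficient sign the sign of the
lead-lag correlation and makes all p-values scale-equivariant. Degenerate
windows (zero-variance genes, collinear pairs) are flagged with p = 1.

**Multivariate.** Each target's next step is regressed on the current
values of all p genes jointly: a LASSO at the universal penalty
`λ = 1.1 σ̂ sqrt(2 log p / n)` with the noise level from the scaled-lasso
iteration, then coefficient-wise de-biasing
`β̂_d = β̂ + M X'(y − Xβ̂)/n` with M from either the node-wise-lasso
relaxed inverse ("nodewise") or a coordinate-descent convex program
("jm") whose stationarity conditions bound `|Σ̂m − e_j|_∞`. Standard
errors use `σ̂ sqrt([MΣ̂M']_jj / n)` and two-sided normal p-values. Two
finite-sample choices matter at n = 10: the reported σ̂ is the
degrees-of-freedom-corrected `sqrt(RSS/(n − s − 1))` over the selected
support size s (the plain RSS/n scaled-lasso value leaves null z-scores
visibly over-dispersed), and `λ = 0` with p < n short-circuits to exact
least squares, which both de-biasing variants then reproduce to 1e-8 (the
suite's oracle check). Even so, the normal approximation at ten
transitions is an approximation: null z-scores are slightly platykurtic,
so a Kolmogorov–Smirnov test on a large enough pool of null p-values will
eventually flag a small systematic deviation that single-window samples
usually cannot. The calibration study therefore tests uniformity at the
single-system, single-window scale, alongside the BH edge-yield bound that
the far tail (which is conservative) controls.

**Edges and filtering.** BH runs within each window across all tested
coefficients; an edge's strength is its maximal run of consecutive
significant windows with consistent coefficient sign (a sign flip restarts
the run; the overall sign is defined only when every significant window
agrees). The high-confidence network keeps edges with a negative-sign
qualifying run of at least three consecutive windows ending by 24 h whose
endpoints are not cyclic genes (cyclic calls come from the package's own
rhythm scan), then reports connected components ignoring direction. The
"FDR < 0.05%" phrasing that appears alongside this filter in the source
workflow is read as 5%, consistent with its Methods; the threshold is a
parameter. On the recovery system the filter attains recall ≈ 0.9 of the
five planted negative couplings over 20 fixtures with zero cyclic-endpoint
edges retained. On the confounded triplet, the bivariate test calls the
spurious A → B edge in ~70% of systems (windows 1–2, per-window BH
q < 0.05) while both de-biased variants call it in ≈ 0% — the quantitative
version of the argument for multivariate conditioning.

Per-window BH (rather than pooling across windows) was chosen because
windows are the unit at which the persistence filter operates; it is
configurable. Lag order is fixed at 1 throughout, matching the regression
equations the pipeline implements; co-integration or longer lags are out
of scope.

## Problem sizes and determinism

The suite and the acceptance script use: 1,000–2,000-gene fixtures for
expression-level studies, 2,000 independent pure-pair windows for the
bivariate null, one 30-gene all-null system for the multivariate null and
BH-yield checks, 100 confounded-triplet systems, 20 recovery fixtures each
for edges and rhythms, and 5–10 fixtures for clustering; these sizes put
every Monte-Carlo estimate's uncertainty well below the margins being
tested while keeping the full run in minutes on one core. All randomness
flows from a single integer seed through one deriving function;
`run_pipeline()` writes only plain-text artifacts and reproduces its
checksums under a repeated seed.
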