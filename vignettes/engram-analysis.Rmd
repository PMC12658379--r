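---
title: "Quantifying engram reactivation, recognition memory, and spine morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying engram reactivation, recognition memory, and spine morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engramtools)
```

# The analysis problem

Chemogenetic engram experiments tag the neurons active during a learning
episode (activity-dependent, tamoxifen-gated mCherry expression) and ask, at
recall, three quantitative questions:

1. **Did the animal remember?** Manually scored exploration bouts of a novel
   versus a familiar object are reduced to a *discrimination index* (DI),
   \deqn{DI = \frac{t_{novel} - t_{familiar}}{t_{novel} + t_{familiar}},}
   and each group's mean DI is tested against the chance value 0 with a
   one-sample t test (animals as the unit).
2. **Was the tagged ensemble reactivated above chance?** Per brain slice,
   counts of DAPI+, c-Fos+, mCherry+ and double-positive cells give the
   *chance-corrected overlap*
   \deqn{\text{enrichment} = \frac{O/D}{(C/D)\,(M/D)},}
   where \eqn{O, C, M, D} are the overlap, c-Fos, mCherry and DAPI counts.
   Under independent labeling its expectation is 1; values above 1 indicate
   preferential reactivation of the tagged population. Slice values are
   averaged within animal, and animals are the statistical unit.
3. **Did reactivation remodel synapses?** Spines exported from 3-D filament
   reconstructions are refined, measured geometrically, classified into five
   morphological categories, and clustered without supervision
   (z-score, PCA, k-means) to cross-check the threshold taxonomy.

The package implements each stage plus a synthetic-data module whose
ground-truth parameters close the testing loop: every estimator can be checked
against the value it should recover.

# Behavioral scoring

`read_event_log()` parses per-bout CSV records (label, start, stop in
seconds). Manual scoring can produce overlapping bouts; these are summed as
recorded with a warning, because the DI uses raw summed times. A trial with
zero total exploration has an *undefined* DI (`NA`), never 0: a zero would
feign indifference where there is no evidence. Zero-duration bouts are
scoring no-ops and change neither times nor interaction counts.

`di_vs_chance()` delegates to `stats::t.test` except in the zero-variance
case, which `t.test` refuses: an all-zero sample is reported as t = 0 and a
constant non-zero sample as signed infinity, both flagged `degenerate` with
`p = NA`, so calibration simulations can account for them explicitly.

Occupancy maps (`occupancy_heatmap()`) are plain 2-D histograms of the nose
track normalized to sum to exactly 100 (percent of total time); out-of-arena
samples are clipped to the boundary with a warning rather than silently
discarded.

# Ensemble reactivation statistics

All reactivation statistics are per-slice ratios of counts, so ROI geometry
enters only through densities (`cell_density()`, cells/mm^2). The chance
level \eqn{(C/D)(M/D)} is computed *per slice* with that slice's own DAPI
count, matching the convention of averaging four to five sections per animal
with equal weights; area-weighted within-animal averaging is available behind
`area_weighted = TRUE` for unusually heterogeneous ROIs. Slices where a
statistic is undefined (no mCherry+ cells for the co-localization percentage,
zero chance level for the enrichment) are excluded with a warning instead of
imputed; an animal with no valid slice is dropped and reported.

Home-cage normalization (`fold_change_vs_homecage()`) divides each
behaviorally stimulated animal's c-Fos density by the *scalar mean* of its
genotype- and region-matched home-cage group, so the home-cage group itself
normalizes to exactly 1 and the encoding group's mean fold change equals the
ratio of the two group means.

Single-cell intensities are treated as already background-comparable
arbitrary units and averaged per cell, then per slice, then per animal,
separately for the total, mCherry+ and mCherry- partitions of the c-Fos+
population. No normalization reference is imposed because none is defined for
these data; by convexity the total mean always lies between the two partition
means, which is asserted in the tests.

## The generative twin

`simulate_slice_counts()` draws, per slice, \eqn{M \sim Bin(N, f)} tagged
cells, \eqn{O \sim Bin(M, p_t)} reactivated tagged cells and
\eqn{Bin(N - M, p_u)} active untagged cells. The implied population
enrichment is
\deqn{\lambda = \frac{p_t}{f\,p_t + (1-f)\,p_u},}
exposed as `implied_enrichment()`. With the tagged fraction fixed at 5% of
DAPI, conditional activation probabilities of 0.42/0.08275, 0.15/0.09517,
0.25/0.08514 and 0.10/0.097133 give \eqn{\lambda} = 4.216, 1.532, 2.677 and
1.028 — the strongly enriched, weakly enriched, moderately enriched and
at-chance regimes spanned by the estimator's operating range. The per-slice
estimator is a ratio of binomial proportions, so it carries a small
finite-sample (Jensen) bias; at 30 slices of 2000 cells the relative bias is
under 1%, which is why the recovery tests run at that size. Counts are
generated at slice level only: every downstream statistic is a count ratio,
so spatial point patterns would add cost without adding testable structure.

# Spine morphometry

## Refinement

Automated filament tracing produces artifacts. `refine_spines()` removes
records that lack a spine neck (absent neck diameter), have a head max
diameter below the 0.4 µm reconstruction minimum, or sit on a dendrite
outside the 1–5 µm diameter range used during tracing (checked only when a
dendrite diameter column is present), and reports removals per rule.

## Geometry

The spine solid is a conical frustum from the attachment point (radius
\eqn{r_a}) to the head (radius \eqn{r_t}) capped by a terminal hemisphere,
with the attachment-point hemisphere subtracted:
\deqn{V = \frac{\pi h}{3}(r_a^2 + r_a r_t + r_t^2)
      + \frac{2}{3}\pi r_t^3 - \frac{2}{3}\pi r_a^3}
\deqn{A = \pi (r_a + r_t)\sqrt{h^2 + (r_a - r_t)^2}
      + 2\pi r_t^2 - 2\pi r_a^2}
The parameterization from exported features is a declared choice:
\eqn{r_a} = attachment diameter / 2, \eqn{r_t} = head max diameter / 2, and
frustum height \eqn{h = \max(\text{length} - r_t,\ 10^{-6}\,\mu m)} so the
terminal hemisphere sits on top of the frustum. When \eqn{r_a = r_t} both
formulas reduce exactly to the cylinder, which anchors the unit tests; the
general case is verified against numerical solid-of-revolution integration to
0.1%. When \eqn{r_a > r_t} the literal subtraction can drive the area
negative; it is floored at 0 with a warning rather than silently re-modelled.

## Threshold classification

The raw class criteria (mushroom: head ≥ 0.6 µm; stubby: LWR ≤ 1; filopodia:
length > 2 µm; long thin: 1 < length ≤ 2 µm; thin: length ≤ 1 µm) overlap — a
short wide-headed spine satisfies both the stubby and the mushroom rule — so
`classify_spines()` applies them in the fixed precedence
**mushroom → stubby → filopodia → long thin → thin**, which makes the rule
set exhaustive and mutually exclusive. Head-size dominance reflects that the
mushroom category is defined by its head; the boundary at exactly 0.6 µm
belongs to mushroom. The LWR width convention is the head **max** diameter by
default (`width = "head_mean"` is available). Spine length is measured
attachment-to-tip.

Per-20-µm class counts (`per_segment_counts()`) rescale each segment's counts
by `20 / traced length`, so the class counts sum to the total density exactly
— an identity, not an approximation — and can be aggregated per segment, per
neuron, or per animal (the count figures in this literature are reported
under both neuron- and animal-level n, so both are exposed).

## Unsupervised clustering

`spine_feature_matrix()` assembles a fixed, documented roster of 16 features
(`spine_feature_names()`): the nine raw reconstruction exports and seven
derived quantities (LWR, frustum height, surface area, volume, head/neck
ratio, neck length fraction, area/volume ratio). The roster is a package
declaration — feature lists of this kind are rarely enumerated in
publications — and is deliberately redundant (areas and ratios correlate with
their inputs), which PCA absorbs.

`cluster_spines()` z-scores each feature over the fitted set, applies PCA,
and runs k-means on the scores with 10 restarts under a fixed seed
(`iter.max = 100`). All principal components are retained for clustering —
discarding components would silently change distances — and the first two are
used only for plotting. The default in the pipeline is k = 5, mirroring the
five-category taxonomy; when k is unset the elbow method picks the k in 2..10
maximizing the discrete curvature \eqn{W(k-1) - 2W(k) + W(k+1)} of the
within-cluster inertia curve, ties toward smaller k. Degenerate input (all
rows identical) collapses to a single cluster with zero inertia rather than
erroring.

# Synthetic data: what it does and does not emulate

The generators reproduce the *statistical* structure the estimators assume —
Bernoulli object choice with identically distributed (log-normal) bout
durations, hence \eqn{E[DI] = 2p - 1}; binomial labeling hierarchies with
exact count-ordering invariants; truncated-normal class-conditional feature
distributions centered at least ~2.5 sd inside each class's decision region,
so the classifier recovers the generating class with probability ≥ 0.95 by
construction. Default spine mixture proportions (0.268, 0.335, 0.207, 0.033,
0.157) follow the per-20-µm class proportions of an amyloid-model control
group; bout-duration parameters (mean 2 s, log-sd 0.6) are plausible for
10-minute object-recognition trials but uncalibrated, since bout-level
statistics are not published.

They do **not** emulate image noise, segmentation error, z-plane
co-localization ambiguity, within-animal slice correlations, or tracing bias
— passing recovery tests therefore demonstrates that the estimators are
correct *given* correct counts and features, not that upstream imaging is
robust. Ground-truth labels ride along in sidecar columns (`true_class`) so
recovery tests never re-derive them.

All generators take a single integer seed and are bit-reproducible;
`simulate_study()` derives per-animal substream seeds deterministically from
the study seed.

# Numerical and design choices

* Problem sizes in the test suite (30 slices × 2000 cells × 50 seeds for
  estimator recovery; 100 synthetic animals for the independence null;
  10^4 replicates for t-test calibration; 10^5 feature vectors for classifier
  totality) were chosen so Monte-Carlo error sits well below the asserted
  tolerances while each check runs in seconds.
* Exclusion, not imputation, for undefined per-slice statistics; every
  exclusion is warned and counted.
* Group tables report mean ± SEM with animals as the unit; every group mean is
  traceable to a per-animal audit CSV, and the run manifest lists each output
  file with its MD5 hash.
* The pipeline's pairwise/omnibus comparisons are deliberately thin wrappers
  over standard routines (`t.test`); multi-way ANOVA machinery is out of
  scope.

# Known limitations

* The enrichment estimator's ratio bias grows as cell counts shrink; below a
  few hundred DAPI cells per slice the per-slice estimate should be treated
  with caution (the per-animal mean inherits the bias).
* The frustum geometry is a two-radius idealization; necked spines with
  pronounced head overhang are under-modelled, and the negative-area floor is
  a guard, not a geometry.
* The elbow selector uses a local curvature criterion; on inertia curves
  without a pronounced bend (heavily overlapping clusters) it will pick small
  k. The five-cluster default exists precisely so the taxonomy comparison
  does not depend on the selector.
* The classifier recovery guarantee holds for the generator's in-region
  distributions; real spines near class boundaries are intrinsically
  ambiguous and the threshold taxonomy inherits that ambiguity.
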