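---
title: "Spatial proximity and consistency of tumor-infiltrating CD8 T cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial proximity and consistency of tumor-infiltrating CD8 T cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilprox)
```

## The problem

Tumor-infiltrating lymphocyte (TIL) counts are prognostic in highly
infiltrated breast cancers, but most breast cancers are estrogen-receptor
positive and only moderately infiltrated, where a raw lymphocyte count can
miss whether the lymphocytes that *are* present actually sit next to tumor
cells. Since a cytotoxic CD8 T cell must contact a tumor cell to kill it,
the spatial arrangement of CD8 cells relative to tumor cells is a natural
quantity to measure. `tilprox` implements a distance-based characterization
of that arrangement for multiplex-immunofluorescence tissue-microarray
(TMA) data, where each participant contributes up to four (occasionally
eight) 1 mm tissue cores, each yielding a table of segmented cells with
centroid coordinates and mean channel intensities for Hoechst (nuclei),
cytokeratin (CK; tumor), CD8 and FoxP3.

## The biomarkers

Within a core, let $d_i$ be the Euclidean distance from tumor cell $i$ to
the nearest CD8$^{+}$FoxP3$^{-}$ T cell (the *nearest-neighbor distance*,
NND). Distances are computed strictly within cores — cores are physically
separate pieces of tissue — and truncated at 1000 µm, the upper bound a
1 mm core geometry permits. Raw NNDs are strongly right-skewed, so the
analysis works with $\log_{10} d_i$. Pooling the log distances over all of
a participant's QC-passed cores into one sample $L$ gives two
per-participant biomarkers:

* **proximity** $= 3 - \mathrm{mean}(L)$, in $[0, 3]$ when all distances
  lie in $[1, 1000]$ µm; high proximity means CD8 cells are, on average,
  close to tumor cells;
* **consistency** $= 1 - \mathrm{var}(L)$, at most 1; high consistency
  means uniform tumor–CD8 spacing.

The **lymphocyte count** (CD8 + Treg cells over passed cores) is computed
alongside as the conventional count-based comparator.

Two conventions are fixed for exact testability where the verbal
definitions are ambiguous:

* *variance* is the sample variance ($n-1$ denominator). With thousands
  of distances per participant the choice is numerically immaterial, but
  it must be fixed for tests to assert exact values (pooled log values
  $\{1, 2\}$ give consistency exactly $1 - 0.5 = 0.5$).
* pooling concatenates per-core log distances before taking moments
  (not a per-core-moment average); the two differ when core sizes differ,
  and concatenation matches the aggregate-then-summarize definition of
  the metric. The choice is recorded in the metrics output attributes.

### Cores with no CD8 cells

A core can contain zero CD8 targets. The default policy assigns every
tumor cell the 1000 µm cap, which sends that participant's proximity
toward 0 — a substantive statement that an uninfiltrated tumor has the
worst possible proximity — rather than silently deleting them. The
alternative `drop-core` policy excludes such cores. The number of capped
distances is carried through to the output so users can audit how much of
a participant's sample is censored at the cap.

### The double-positive sensitivity toggle

CD8$^{+}$FoxP3$^{+}$ double-positive cells are classified as regulatory
T cells (Tregs) and excluded from the CD8 target set by default. The
`include_double_positive` toggle adds them to the target set, reproducing
the sensitivity analysis in which "CD8 lymphocyte" is read inclusively.
Adding targets can only shrink nearest-neighbor distances, so proximity
is monotone nondecreasing under the toggle — a property the test suite
checks participant by participant. The toggle lives in the metrics stage,
not the classifier, because it changes which cells count as *targets*,
not what the cells *are*.

## Cell classification and quality control

Cells are classified by thresholding mean channel intensities
("exceeds" is `>=` everywhere):

| class | rule |
|---|---|
| treg | CD8 ≥ t and FoxP3 ≥ t |
| cd8 | CD8 ≥ t and FoxP3 < t |
| foxp3_only | FoxP3 ≥ t and CD8 < t |
| tumor | CK ≥ t and no lymphocyte marker at threshold |
| unclassified | otherwise |

A cell can never be both tumor and lymphocyte: lymphocyte assignment
takes priority over CK. FoxP3-only cells get their own class — they are
visible in stained images and belong in the total cell count — but do
not enter the lymphocyte count, which is defined as CD8 + Treg.
Thresholds are a per-staining-batch calibration and are deliberately
*required* configuration with no numeric defaults; for simulated data
`suggested_thresholds()` derives them from the generator's intensity
model.

Core-level QC removes cores with fewer than 1000 tumor cells *and* fewer
than 3000 total cells. Read literally this is a conjunction, and
`mode = "and"` implements it; because QC rules are more conventionally
disjunctive ("fail either bound and you are out"), `mode = "or"` is also
provided. The default follows the literal conjunction. Removed cores are
flagged, never deleted, and participants whose cores all fail are listed
in an exclusions table with reasons.

## Binarization and cutpoint exploration

Each biomarker is dichotomized at a cohort cutpoint (computed after
exclusions, linear-interpolation quantiles, value ≥ cutpoint ⇒ high).
The analysis defaults are the 1st quartile for proximity and the median
for consistency and lymphocyte count. These defaults came from a
quartile-collapse exploration, which `explore_cutpoints()` reproduces:

1. split participants into four groups at the biomarker quartiles;
2. fit a Cox model with group indicators (top quartile referent);
3. agglomeratively merge adjacent groups whose event-weighted mean log
   hazard ratios differ by less than `epsilon` (default
   $\log 1.5 \approx 0.405$ — groups whose hazards differ by less than
   1.5-fold are "similar");
4. report the boundary between the final two blocks as the suggested
   cutpoint.

If all groups merge, the metric carries no hazard signal and no cutpoint
is suggested. If more than two blocks survive, the boundary at the
largest adjacent log-HR gap is reported — the definition only specifies
the two-block case, and the largest-gap boundary is the natural
extension. A quartile group with zero events cannot support a hazard
ratio and is merged toward the referent with a warning before fitting.
The explorer is advisory: pipeline defaults remain the fixed quartile
rules. With $n = 1500$ and a twofold hazard step, the explorer recovers
a step at Q1 or at the median in well over 90% of replicates (the
acceptance suite measures this).

## Survival and association inference

The survival estimators are the standard ones, delegated to the
`survival` package behind a stable module surface: Kaplan-Meier curves
with Greenwood variance and log-log 95% bounds, the unweighted log-rank
test, Cox proportional-hazards fits (Efron ties by default, Breslow
available; Wald CIs on the log-HR scale; Newton-Raphson with coefficient
tolerance $10^{-9}$ and at most 100 iterations), nested likelihood-ratio
tests, and the Grambsch-Therneau proportionality test on
Kaplan-Meier-transformed time. Non-convergence and monotone likelihood
(complete separation) raise explicit errors rather than returning huge
hazard ratios. The binding contract is the test suite's hand-computed
fixtures: a four-subject log-rank example with chi-square exactly
$8/13$, the classical identity between the Cox score test and the
log-rank statistic on tie-free data (checked to $10^{-8}$), and
Breslow = Efron on tie-free data.

Group comparisons use Kruskal-Wallis with the midrank ties correction
(checked at $n = 8$ against an exhaustive 70-permutation oracle),
Spearman correlation with the t-approximation, and 2×2 odds ratios. The
default odds ratio is the sample estimate $(ad)/(bc)$ with a Woolf
log-normal CI, which reproduces the reported one-decimal point estimates
from the packaged contingency fixture (4.9, 2.4, 6.0 against the
adaptive-enriched immune class; 1.3, 1.4, 2.6 against genomic
instability). An exact conditional-MLE estimator (with exact CI, via the
noncentral hypergeometric likelihood) is provided as
`method = "conditional_mle"`; the interval reported alongside the
fixture's 4.9 estimate is wider at the top than the Woolf interval
computed from the same counts, consistent with an exact conditional
method whose precise variant is not documented, so confidence bounds
are treated as method-dependent and only point estimates are asserted. A zero cell
under the sample method is an error that recommends the conditional
estimator — no silent 0.5 continuity correction.

## The synthetic cohort generator

No public cell-level dataset accompanies the analysis, so the package
ships a seeded generator whose defaults are the study conditions the
pipeline assumes:

| parameter | default | rationale |
|---|---|---|
| cores per participant | 4 | up to four 1 mm cores per participant |
| core radius | 500 µm | 1 mm TMA core |
| tumor cells / core | 1500 | comfortably above the 1000-tumor QC bound |
| lymphocytes / core | 150 | moderate infiltration; count varies by mode |
| stromal cells / core | 2000 | total ≈ 3650 clears the 3000-total bound |
| Treg fraction | 0.2 | minority double-positive population |
| intensity model | log-normal, medians 10 (positive) / 1 (negative), sdlog 0.35 | threshold at the geometric midpoint misclassifies < 1% of cells |
| baseline hazard | 0.05 / unit time | with censoring 0.2 gives ≈ 20% events |
| survival effect | HR 2 for low proximity | the magnitude the power/coverage checks target |

Tumor cells follow a Thomas (parent-offspring Gaussian) cluster process —
the simplest point process producing realistically clumped epithelium.
Real TMA data come with no generative model, so this is a modeling
choice, not a reconstruction of any particular tissue. Lymphocytes are homogeneous Poisson
(`diffuse`), Gaussian clusters (`hotspot`), or radially increasing
(`peripheral`, density $\propto r^2$). Marker intensities are log-normal
per class per channel with tunable overlap, so the threshold
classifier's error rate is controllable; at the defaults it recovers
≥ 99% of true classes. Survival times are exponential with hazard
$h_0 \exp(\sum_m \beta_m 1[\text{metric } m \text{ low}])$ and
independent exponential censoring; class labels follow a logistic model
on the binarized metrics with an intercept that balances the margins by
default.

One global seed expands into per-core and per-stage substreams through a
documented multiplicative-congruential mixing rule
(`substream_seed()`), so a single core can be regenerated in isolation
and the whole cohort is bit-identical under the same config and seed.
The generator exposes `treg_fraction` as the single double-positive
control — Tregs *are* the CD8/FoxP3 double positives, so a separate
double-positive proportion would be redundant.

### What the generator does and does not emulate

It emulates: multi-core participants, clustered tumor with variably
infiltrated lymphocytes, class-separable marker intensities,
proportional-hazards recurrence with ~20% events, and label-biomarker
associations with configurable odds ratios. It does **not** emulate
staining artifacts, intensity drift across slides, segmentation errors,
spatially correlated marker expression, non-proportional hazards, or 3D
tissue. Passing tests on synthetic cohorts therefore demonstrate that
the estimators recover known truth under the stated generating model —
not that real staining batches are free of the calibration problems the
thresholds exist to absorb.

## Numerical choices and degenerate inputs

* Threshold comparisons, binarization and quartile-group assignment all
  use `>=` on the boundary.
* Quantiles use R's type-7 (linear interpolation) convention.
* The NND engine is an exact chunked vectorized computation using direct
  coordinate differences, bit-identical to the naive per-pair formula
  (the inner-product expansion is avoided because it differs in the last
  ulp); it is tested for exact equality against a brute-force oracle on
  100 random cores.
* A participant with a single pooled distance has undefined consistency
  (flagged `single_distance`); with no distances, both metrics are `NA`
  (`no_distances`); consistency below 0 is possible and flagged, never
  clamped.
* A metric whose cohort values are all identical (e.g. proximity when no
  core has any CD8 cell) cannot be binarized; the pipeline drops it from
  the binarized analysis and records it in the manifest rather than
  failing, while `binarize()` itself errors on degenerate input.
* Zero or negative distances are an error: coincident centroids of
  different cell classes indicate a corrupt upstream table.
* A model that fails on a degenerate cohort (separation in a tiny Cox
  fit) is recorded in the run manifest; earlier stage outputs are kept.

## Problem sizes

The test suite and acceptance script use cohorts scaled to the property
being checked: full-size per-core cell counts (1500 tumor / 3650 total)
where QC and classification accuracy are at stake, reduced cores
(~250 tumor cells) for end-to-end pipeline runs, and $n = 1500$
participants with 200 replicates for the Cox coverage check — the size
at which a twofold hazard is comfortably estimable and the Wald CI's
nominal 95% coverage can be distinguished from failure at the 93%
acceptance bound. Null calibrations use 500 replicates, enough to
resolve a type-I error of 0.05 to ±0.02.

## Limitations

* Proximity conflates "no lymphocytes" with "distant lymphocytes" once
  distances hit the cap; the capped-count column is the audit trail.
* The lymphocyte count is not area-normalized and scales with the number
  of cores a participant contributed; `n_cores_passed` is reported
  alongside so users can normalize if desired.
* Cutpoints are cohort-relative quantities; biomarker classes are not
  transferable across cohorts without recalibration.
* The exact conditional odds-ratio CI depends on the chosen exact
  method; only point estimates should be compared across
  implementations.
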