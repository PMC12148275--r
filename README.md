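# tilprox

Spatial **proximity** and **consistency** biomarkers for tumor-infiltrating
CD8 T cells in multiplex-immunofluorescence tissue-microarray (TMA) data,
with the survival and association inference to evaluate them.

## The problem

Tumor-infiltrating lymphocyte (TIL) counts predict outcome in highly
infiltrated breast cancers but say little in the moderately infiltrated
ER-positive majority, where *where* the lymphocytes sit matters as much as
how many there are. A cytotoxic CD8 T cell has to touch a tumor cell to
kill it, so the distances between tumor cells and their nearest CD8
neighbors carry prognostic information a count ignores.

`tilprox` is for analysts with QuPath-style per-cell exports (centroid
coordinates plus mean Hoechst/CK/CD8/FoxP3 intensities per segmented cell)
and per-participant follow-up data. It classifies cells by intensity
thresholds, applies core-level QC, and computes, per participant:

- **NND**: Euclidean distance from each tumor cell to the nearest
  CD8⁺FoxP3⁻ T cell in the same core, truncated at 1000 µm;
- **proximity** = 3 − mean(log₁₀ NND), in [0, 3] — high means CD8 cells
  hug the tumor;
- **consistency** = 1 − var(log₁₀ NND), ≤ 1 — high means uniform
  tumor–CD8 spacing;
- **lymphocyte count** = CD8 + Treg cells over QC-passed cores,

then binarizes them at cohort cutpoints (1st quartile for proximity,
median for the others), and runs Kaplan-Meier / log-rank / Cox
proportional-hazards survival analysis, nested likelihood-ratio tests, the
Grambsch-Therneau proportionality check, Kruskal-Wallis and Spearman
comparisons, and 2×2 odds ratios against molecular class labels. A seeded
synthetic TMA cohort generator (clustered tumor point patterns, three
lymphocyte infiltration modes, proportional-hazards outcomes) makes the
whole pipeline testable without patient data.

## Worked example

Simulate a 120-participant cohort (two 1 mm cores each, a true twofold
recurrence hazard for low-proximity participants) and run the full
pipeline:

```r
library(tilprox)

cfg <- simulation_config(n_participants = 120, cores_per_participant = 2,
                         tumor_intensity = 300, lymphocyte_intensity = 60,
                         stromal_intensity = 250,
                         survival_betas = c(proximity = log(2)),
                         seed = 2026)
pc <- pipeline_config(simulation = cfg,
                      qc = list(min_tumor = 100, min_total = 300, mode = "and"))
res <- run_pipeline(pc)

head(res$metrics[, c("participant_id", "proximity", "consistency",
                     "lymphocyte_count", "proximity_class")], 4)
#>   participant_id proximity consistency lymphocyte_count proximity_class
#> 1          P0001  1.270883   0.9168211              112            high
#> 2          P0002  1.335166   0.9181936              145            high
#> 3          P0003  1.218790   0.9213539              128             low
#> 4          P0004  1.245962   0.9209931              119            high

res$cox_models$univariate_proximity
#> Cox proportional-hazards fit (efron ties): n = 120, events = 31
#>                term       hr    lower    upper    p_value
#>  proximity_classlow 2.378512 1.142462 4.951863 0.02056108

res$tests$logrank_proximity
#> log-rank: statistic = 5.7027, df = 1, p = 0.01694
```

Proximity here sits around 1.2–1.3 (mean tumor-to-CD8 distance of roughly
50–60 µm) and consistency around 0.92. The fitted hazard ratio for
low-vs-high proximity is 2.38 (95% CI [1.14, 4.95]) against a true
simulated value of 2 — the kind of estimate the coverage checks quantify
across 200 replicates. Odds ratios against a molecular class come from the
same interface used for the packaged contingency fixture:

```r
odds_ratio_2x2(283, 29, 401, 201)
#> $or      4.891478       # reported as 4.9
#> $lower   3.220343
#> $upper   7.429817
#> $method  "sample (Woolf CI)"
```

A thin command-line wrapper with `simulate` / `classify` / `metrics` /
`run` / `assoc` subcommands is at `inst/cli/tilprox.R`; see
`vignettes/tilprox-methods.Rmd` for the methods, parameter defaults and
design decisions.

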