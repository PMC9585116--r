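# exposcreen

Non-targeted suspect screening of environmental chemical exposures in
maternal and umbilical-cord serum, as a tidyverse-native R package.

## The problem

Non-targeted analysis (NTA) by LC-QTOF/MS detects thousands of chromatographic
*features* — (neutral mass, retention time, abundance) triples — without a
predefined analyte list, and matches them against a suspect database of
molecular formulas. Turning raw feature tables from a multi-batch, two-city
pregnancy cohort into defensible statements like "chemical X is detected more
often in city A" requires a long chain of decisions: blank filtering,
formula matching, duplicate collapsing within and across batches and
ionization modes, isomer annotation, confounder-matched comparison, and batch
correction. `exposcreen` implements that chain as composable, tested
functions for exposome researchers, plus a synthetic-data generator with
known ground truth so the whole pipeline can be validated without access to
restricted human data.

## What it computes

- **Feature pipeline** — water-blank rule (keep a cell only if abundance ≥ 2×
  the batch's mean water-blank signal), technical-replicate averaging with
  singleton filtering, formula matching by mass accuracy (score
  `100·(1 − |ppm|/tol)`, threshold 70), duplicate grouping by connected
  components of the *same formula ∧ Δm ≤ 15 ppm ∧ ΔRT ≤ 0.5 min* relation
  (retain the highest detection frequency), cross-batch harmonization with
  the same transitive rule, detection at abundance ≥ 5000.
- **Annotation** — most probable isomer per formula by
  `final = (1/k + evidence)/2`, where `evidence` is the mean of min–max
  scaled PubMed mentions, PubChem mentions and production volume; rank-based
  isomer assignment when several co-formula chemicals are differential.
- **Cohort statistics** — propensity scores (ridge-stabilised logistic IRLS)
  for city membership on four matching covariates; deterministic 1:1 nearest
  neighbour matching without replacement; `log` transform with 0 → 0.1;
  parametric empirical-Bayes location/scale batch correction (validated
  against `sva::ComBat`); per-chemical two-sided Fisher's exact tests of
  detection frequencies (probability-mass definition); abundance ratios;
  paired maternal–cord Pearson correlation; PCA batch-mixing checks.
- **External comparisons** — wristband concentrations normalised to
  ng/g/week, formula+rank cross-platform matching, and Spearman correlations
  (exact permutation p for n ≤ 8) of per-participant chemical counts against
  tract-level pollution and pesticide percentiles.

## Worked example

```r
library(exposcreen)

cfg <- pipeline_config(n_formulas = 120, n_per_city = 40, seed = 2024)
res <- run_pipeline(cfg, outdir = file.path(tempdir(), "expo_demo"),
                    quiet = TRUE)

res$feature_pipeline$harmonized
#> Harmonized suspect table: 77 chemicals, 10173 abundance cells

glance(res$analysis$maternal$differential)
#> # A tibble: 1 × 6
#>   n_chemicals n_differential n_higher_fresno n_higher_sf ...
#> 1          77              7               6           1

d <- tidy(res$analysis$maternal$differential)
head(d[order(d$fisher_p), ], 3)
#> # A tibble: 3 × 7
#>   chemical df_fresno df_sf fisher_p abundance_ratio differential direction
#> 1 CHEM0060     0.875 0.475 0.000254          0.284  TRUE      higher_in_fresno
#> 2 CHEM0053     0.95  0.6   0.000297          0.0858 TRUE      higher_in_fresno
#> 3 CHEM0050     0.55  0.15  0.000343          8.64   TRUE      higher_in_fresno

res$geo
#> # A tibble: 4 × 6
#>   city             rho p_value     n counts    percentile
#> 1 Fresno        0.364   0.0210    40 pesticide pesticide_pctile
#> 2 SanFrancisco  0.243   0.131     40 pesticide pesticide_pctile
#> 3 Fresno        0.149   0.358     40 all       pollution_burden_pctile
#> 4 SanFrancisco -0.0722  0.658     40 all       pollution_burden_pctile
```

Reading the output: 120 database formulas yield 77 harmonized suspect
chemicals after blank filtering, the 1.5 ppm-equivalent score cut and
deduplication. Seven chemicals differ between cities at the 0.05 level (the
generator injected differential chemicals at detection frequencies 0.9 vs
0.3), six of them more frequent in Fresno, and the per-participant count of
detected suspect pesticides correlates with the agricultural-pesticide tract
percentile in Fresno (ρ = 0.36) but not significantly in San Francisco —
the coupling the generator encodes. Plots: `autoplot()` on a differential
result draws the by-category dot plot, `plot_detection_counts()` the
per-city detected-count histograms, and `plot_batch_pca()` the before/after
batch R² comparison. All intermediate tables (`features.csv`,
`harmonized.csv`, `differential_results_maternal.csv`, `manifest.json`, ...)
are written to `outdir`.

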