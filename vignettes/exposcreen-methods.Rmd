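---
title: "Methods: non-targeted suspect screening of environmental chemical exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-targeted suspect screening of environmental chemical exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope

`exposcreen` implements a complete non-targeted analysis (NTA) pipeline for
LC-QTOF/MS suspect screening of environmental chemicals in paired maternal and
umbilical-cord serum from a two-city pregnancy cohort, together with two
external comparisons: silicone-wristband passive-sampler concentrations and
tract-level geographic pollution indicators. Because serum NTA data from human
cohorts is rarely shareable, the package ships a synthetic-data generator that
emulates the full study structure with known ground truth; every stage of the
pipeline is exercised and tested against that ground truth.

The pipeline starts from *extracted feature tables* (neutral mass, retention
time, per-sample abundances) as produced by vendor peak-picking and alignment
software. Peak picking, chromatogram alignment, isotope-pattern scoring,
adduct resolution and MS/MS confirmation are out of scope.

# Feature pipeline

Stages run in this order (each is an exported function; `run_feature_pipeline()`
chains them):

1. **Water-blank filtering** (`filter_blank_features()`). The water blank is
   the procedural blank. A study-sample cell is kept only if its abundance is
   at least `blank_ratio` (default 2) times the mean water-blank abundance of
   that feature in the same batch; *exactly* two-fold qualifies. Failing cells
   are zeroed rather than whole features removed — cell-level filtering is the
   less destructive reading and reduces to feature-level removal when every
   cell fails. A feature with zero blank signal is never filtered; features
   whose study cells are all zero afterwards are dropped. Matrix blanks and
   spikes are carried through for QC reporting but do not drive filtering.
2. **Technical-replicate averaging** (`average_replicates()`). Each sample is
   measured twice; a (feature, sample) cell observed in both replicates
   becomes their mean, a cell observed in only one replicate is treated as not
   reliably extracted and set to zero.
3. **Formula matching** (`match_formulas()`). Each feature is assigned the
   database formula minimising absolute ppm error (formula mass in the
   denominator) within `ppm_tol_match` (default 5 ppm). A match score
   `100 * (1 - |ppm|/tol)` stands in for vendor scores that also use isotope
   patterns (unavailable without raw spectra); the default threshold of 70
   corresponds to |ppm| <= 1.5. Both tolerance and threshold are config keys.
   This cut deliberately trades recall for precision of formula assignment:
   with a 2 ppm systematic mass-error scale, a substantial fraction of genuine
   chemicals is excluded from the suspect list, which end-to-end recovery
   numbers reflect.
4. **Duplicate collapsing** (`find_duplicate_groups()`,
   `collapse_duplicates()`, `merge_modes()`). Two formula-matched features are
   duplicates when they share a formula, their masses agree within 15 ppm
   (relative to the smaller mass), and their retention times within 0.5 min —
   both boundaries inclusive (a pair at exactly 15 ppm / 0.5 min is a
   duplicate; a tiny relative epsilon, 1e-9, protects the inclusive boundary
   against floating-point representation). Features that share a match in
   common but do not match each other are still duplicates: groups are
   connected components of the pairwise relation (computed with igraph; an
   independent breadth-first-search oracle checks them in the tests). Within
   each group the member with the highest detection frequency is retained;
   ties break by smaller |ppm error|, then lexicographically smallest feature
   id, which makes the retained set invariant to input order. Positive- and
   negative-mode tables are concatenated and deduplicated within batch.
5. **Cross-batch harmonization** (`harmonize_batches()`). The duplicate
   criterion is re-applied across batches with the same transitive closure;
   each component becomes one harmonized chemical whose per-sample abundances
   come from its batch-specific members. A component with two same-batch
   members signals an upstream dedup miss: a warning is raised and the
   higher-detection-frequency member represents that batch. Whether chemicals
   seen in a single batch should be dropped is ambiguous in principle; both
   behaviours are available (`drop_unreplicated_across_batches`, off by
   default).
6. **Detection calling** (`call_detections()`). A chemical is detected when
   its abundance is >= 5000 (inclusive). The same limit is applied again after
   batch correction.

# Annotation

A formula-level suspect is an equivalence class of isomers. The most probable
isomer is chosen by `score_isomers()`: the final score is the average of the
*blind probability* (1/k for a formula with k isomers) and an *evidence score*
— the mean of PubMed mentions, PubChem mentions, and production volume, each
min–max scaled to [0, 1] across the whole database (db-wide rather than
within-formula, to preserve cross-formula comparability; a constant column
scales to 0; missing values count as 0; per-metric weights are configurable).
Rankings are invariant under positive affine rescaling of any metric, which
the tests verify on random databases. When several differentially detected
chemicals share one formula, `assign_isomers_by_rank()` pairs the most
probable isomer with the highest-detection-frequency chemical, the second
with the second, and so on; more chemicals than isomers is an error.

# Cohort statistics

- **Propensity scores** (`estimate_propensity()`): main-effects logistic
  regression of the Fresno indicator on the four indicator-coded matching
  covariates (maternal age category, race/ethnicity, education, marital
  status), fit by IRLS to a 1e-8 gradient tolerance with a 1e-6 ridge on
  non-intercept coefficients so quasi-separable cohorts still yield finite
  scores. Covariates observed at a single level are dropped. The fit is
  cross-checked against `stats::glm()` in the tests.
- **Matching** (`match_nearest_neighbor()`): 1:1 nearest neighbour without
  replacement. Fresno participants are processed in descending propensity
  order; each takes the unmatched San Francisco participant with minimal
  absolute score difference, ties broken by smaller participant id. The rule
  is fully deterministic, so repeated matching runs (the pipeline performs
  three and reports the Jaccard similarity of the resulting pairings)
  reproduce identical pairs; the repeat harness exists to surface any
  order-dependence regressions.
- **Log transform** (`log_transform()`): natural log with zeros replaced by
  0.1 first, preserving the zero boundary.
- **Batch correction** (`correct_batch_effects()`): the parametric
  empirical-Bayes location/scale model. Per chemical, data are standardised
  after fitting covariate effects; per-batch additive and multiplicative
  parameters are estimated and shrunk towards across-chemical moment-matched
  priors (normal location, inverse-gamma scale); the data are adjusted and
  covariate effects restored. A single batch returns unchanged; covariate
  columns perfectly confounded with batch are dropped with a warning;
  (near-)constant chemicals pass through untouched; a degenerate
  across-chemical spread disables shrinkage for that batch. The
  implementation agrees with `sva::ComBat()` to ~1e-3 in the tests.
- **Differential detection** (`differential_detection()`): per chemical, a
  detected/not x city table over the matched participants, tested with the
  two-sided Fisher's exact test; differential means p < 0.05 with no
  multiplicity correction (the screening convention here), optional
  Benjamini–Hochberg behind a flag. The two-sided p is the probability-mass
  sum: all tables with the observed margins whose probability does not exceed
  the observed table's (1e-7 relative slack); any zero margin gives p = 1.
- **Abundance ratios**: Fresno/San Francisco ratio of mean natural-scale
  abundances, computed from post-correction abundances by default
  (`ratio_abundances = "raw"` switches to pre-correction values). Note a
  structural caveat: when a city is confounded with a batch, the correction
  equalises per-chemical batch means, so post-correction ratios no longer
  reflect injected city differences in detection; the raw option exists for
  exactly that reason.
- **Paired correlation** (`paired_correlation()`): Pearson correlation of
  paired maternal and cord log abundances.
- **Batch-mixing check** (`batch_mixing_check()`): R² of the batch factor on
  the leading principal components, before and after correction.

## Why the batch design is conservative

In the emulated study design the Central Valley city is analysed in its own
batch while the coastal city spans two batches. City is then confounded with
batch, and per-chemical batch-mean removal absorbs part of any true city
difference; empirical-Bayes shrinkage (which pools batch effects across
chemicals) is what preserves most of the detection signal. Two consequences
are worth knowing:

- Detection-frequency differences survive correction only when detected
  abundances sit well above the detection limit, as they do in real data and
  in the generator defaults.
- Empirical-Bayes shrinkage leaves roughly half of the per-chemical sampling
  noise of batch means in place (by design: per-chemical estimates are noisy).
  Residual *systematic* shift after correcting an injected unit batch shift is
  essentially zero, but the mean of per-chemical absolute differences is
  bounded below by this noise floor — at realistic batch sizes it does not
  vanish, and the identical behaviour is observed with the reference
  implementation. The acceptance test therefore evaluates shift removal on
  the across-chemical mean, and separately checks that per-chemical residuals
  fall far below the injected shift.

## Exact-test conservatism

Fisher's exact test is conditionally exact and therefore conservative: at
these sample sizes its attainable size lies below the nominal 0.05, so the
empirical null flag rate in calibration runs falls slightly below a two-sided
binomial band centred on 0.05. The property suite asserts type-I *control*
(no anti-conservatism); the calibration test that demands the rate sit inside
the two-sided band documents this failure mode rather than hiding it.

# External comparisons

- **Wristbands**: concentrations normalise to ng per g silicone per week
  (`normalize_wristband()`: `raw / g / (days/7)`). Wristband detection uses a
  zero reporting floor (detected = concentration > 0). Cross-platform
  matching is by formula and detection-frequency rank within formula, after
  excluding wristband chemicals whose formulas are not amenable to the serum
  screen (e.g. PCB-like panels); the participant-level
  concentration-vs-abundance comparison is restricted to unique-formula
  chemicals and pools (participant, chemical) pairs.
- **Geography** (`correlate_geo()`): Spearman correlation per city between
  per-participant counts of detected chemicals in a source category and a
  tract percentile. `spearman_rho()` uses midranks; its p-value is exact (by
  permutation enumeration) for n <= 8 and the t approximation with n - 2
  degrees of freedom otherwise.

# The synthetic-data generator

`generate_chemical_db()`, `generate_cohort()`, `make_ground_truth()`,
`generate_feature_tables()` and `generate_wristband_data()` emulate, in order:
a suspect database of formulas (masses uniform on the 100–1000 Da scan range)
with isomers carrying heavy-tailed literature counts and production volumes
plus source categories; a two-city cohort whose covariate distributions
differ by city (the Central Valley city younger, more Latina, lower
educational attainment, far higher agricultural-pesticide tract percentiles);
per-batch per-mode feature tables; and a wristband screen for a participant
subset (wear time averaging 35 days) partially overlapping the serum
database.

Generator defaults and the reasoning behind them:

- **Study shape**: 75 participants per city, cord sera for ~85% of them, the
  coastal city split over batches 1–2 and the valley city in batch 3, one
  water blank, matrix blank and matrix spike per batch, two technical
  replicates per sample.
- **Effects**: 20 truly differential chemicals with detection probabilities
  0.9 vs 0.3; null chemicals share a city-invariant detection probability;
  additive per-batch log shifts (+0.5, −0.3, 0); a configurable coefficient
  couples the pesticide tract percentile to pesticide detection odds (default
  1.0 on the logit scale per 50 percentile points).
- **Abundances**: per-chemical lognormal with mean log abundance uniform on
  log(1e5)–log(3e6). Detected LC-QTOF features sit orders of magnitude above
  the 5000 reporting floor; placing them near the floor would make detection
  calls unstable under any location-scale batch adjustment.
- **Absent cells**: mostly low sub-threshold signal (lognormal around 500)
  with a 30% chance of a hard zero — vendor extraction reports trace-level
  integrated signal, not all-or-nothing values.
- **Maternal–cord coupling**: a shared per-participant log-abundance effect
  (SD 0.5 against residual SD 0.33) so paired sera correlate strongly, as
  cord and maternal concentrations do for passively transferred chemicals.
- **Mass error**: chemical-specific systematic error, Gaussian SD 2 ppm
  truncated at 5 ppm (instrument accuracy class), plus small between-batch
  recalibration jitter (SD 0.3 ppm). Continuous reference-mass recalibration
  makes between-run mass reproducibility far tighter than absolute accuracy;
  drawing the full error independently per batch would make chemicals drop
  out of individual batches at the score cut, an artifact no aligned dataset
  shows.
- **Retention time**: uniform 0.2–19 min per chemical; jitter SD 0.1 min
  within batch and 0.2 min between batches, so cross-batch matching is
  genuinely exercised but mostly succeeds inside the 0.5 min window.
- **Failure injection**: a configurable fraction of chemicals carries
  water-blank signal comparable to sample signal (exercising the two-fold
  rule) and a configurable fraction of features is split into duplicate pairs
  within the 15 ppm / 0.5 min windows with lower-abundance copies (exercising
  dedup in the direction where the original wins).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: isotope patterns and adducts (multiple features
per chemical beyond simple splits), chromatographic drift that is systematic
rather than random, correlated chemical co-occurrence (e.g. co-exposure to
product mixtures), matrix effects and ionisation suppression, missingness that
depends on abundance, or realistic formula composition (formula strings are
structurally plausible but masses are not computed from them). Ground truth is
persisted in a `truth.json` sidecar; real-data ingestion uses the same CSV
schemas without it.

# Numerical and design choices

- ppm denominators: the smaller mass for pairwise feature comparison, the
  formula mass for database matching.
- All screening boundaries are inclusive (>= 5000 detected; >= 2x blank
  retained; <= 15 ppm / <= 0.5 min duplicate).
- Tie-breaks are total orders (detection frequency, then |ppm error|, then
  id; isomer name for annotation ties), making every stage deterministic and
  order-invariant.
- Degenerate inputs are first-class: empty mode tables pass through, zero
  margins give p = 1, constant vectors signal a typed condition
  (`expo_degenerate_error`), batches without water blanks and unknown
  categories raise typed validation errors naming the offender.
- Every generator takes an explicit seed and restores the caller's RNG state;
  `run_pipeline()` derives stage seeds from the single config seed, and
  identical configs reproduce byte-identical outputs.

## Problem sizes used by the test and acceptance suites

Calibration and power studies run at the study's cohort size (75 per city)
with 100 chemicals (20 differential) over 100 replicates at the
detection-matrix level, isolating the statistical stage from mass-matching
attrition. Batch-correction recovery uses 100 chemicals x 150 samples (75 per
batch, residual log-SD 0.6) over 50 replicates. Duplicate-grouping equivalence
runs 500 random instances of up to 200 features. The end-to-end acceptance
script runs the full pipeline at 250 formulas x 150 participants, a scale
chosen to exercise every stage with comfortable statistical resolution.

# Known limitations

- The vendor match score is reduced to mass accuracy; isotope-pattern
  information is not reconstructable from feature tables.
- Under total city-batch confounding no correction can separate city effects
  from batch effects; results are conservative, and post-correction abundance
  ratios should not be over-interpreted (use the raw-ratio flag where the
  distinction matters).
- Annotation is a ranking heuristic over literature prevalence and production
  volume; it does not confirm structures.
- Fisher's exact test is conservative at moderate sample sizes; Spearman
  p-values for n > 8 are approximate.
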