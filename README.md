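# drusenseq

Risk prediction of exudative conversion in age-related macular degeneration
(AMD) from longitudinal SD-OCT drusen quantification.

Eyes with intermediate (dry) AMD can convert suddenly to exudative (wet)
AMD, and early treatment preserves vision, so clinicians want a per-visit
estimate of the risk that a given eye converts **within the next k months**
(k = 3, 6, ..., 21). `drusenseq` implements the full pipeline for that
problem in R, for methodologists and pipeline developers who need an
end-to-end, testable reference implementation that runs on synthetic data
(the clinical cohorts this design was developed on are private):

* **Drusen imaging biomarkers** — 21 features per scan (druse count,
  mean/total footprint area and volume, convex-hull extent, density,
  maximum height over Bruch's membrane, mean elevation-gradient slope,
  percentile-normalized reflectivity mean/sd, and area/volume within 3 mm
  and 5 mm of the fovea) from a segmented OCT volume; same-session scans
  averaged into one observation.
* **Outcome labeling with censoring** — per observation and horizon,
  `progressor` if the event falls within (t, t+k], `non_progressor` only if
  a later dry visit proves the window event-free, `censored` otherwise.
* **The sequence model** — a many-to-many, two-layer stacked LSTM
  (50 → 20 units) over the visit sequence, one model per horizon, trained
  with padding-based sequence augmentation (a length-n record yields n
  prefix sequences, post-padded with zero vectors labelled 2) and the
  time-distributed weighted cross-entropy

  ```
  l(Y, Ŷ) = -(1/l) Σ_t (yᵗ ln ŷᵗ + (1 - yᵗ) ln(1 - ŷᵗ)) · λ_{yᵗ},
  λ = (1, n_neg/n_pos, 0)
  ```

  implemented from scratch in R (BPTT + Adam), with a finite-difference
  gradient check in the test suite.
* **Evaluation** — patient-level stratified tenfold CV (no patient in both
  train and test, asserted programmatically), visit-variant analysis,
  external-cohort testing without refitting, patient-level first-5-visits
  sensitivity/specificity, and ROC/PR primitives checked against an O(n²)
  concordance oracle.
* **Synthetic data as a first-class module** — spherical-cap drusen
  phantoms with closed-form area/volume oracles, and longitudinal cohorts
  (default 200 eyes × 24 monthly visits, ~22% conversion) with a planted
  discrete-time logistic hazard on the latent feature path.

See `vignettes/drusenseq-methods.Rmd` for the model, its assumptions, and
every numerical design decision.

## Worked example

```r
library(drusenseq)

# a hemispherical druse phantom: analytic volume (2/3)*pi*0.3^3 = 0.0565 mm^3
ps <- phantom_spec(druse_list = list(
  list(center_xy_mm = c(3, 3), radius_mm = 0.3, peak_height_mm = 0.3)
))
bundle <- generate_phantom(ps)
fv <- assemble_features(bundle)
round(fv[c("n_drusen", "total_volume", "total_area", "density", "max_height")], 4)
#> n_drusen total_volume   total_area      density   max_height
#>   1.0000       0.0562       0.2725       1.0000       0.2982
```

The extractor recovers the closed-form volume to 0.7% at the default
128³ test resolution (0.0562 vs 0.0565 mm³) and the cap height to within
one axial voxel.

```r
cohort <- generate_cohort(cohort_spec(n_eyes = 200, seed = 1))
cohort
#> <cohort> 200 eyes, 4350 visit rows, 36 converters (18.0%)

label_counts(build_labeled_sequences(cohort))
#>   horizon progressor non_progressor censored total_labeled
#> 1       3         93           3538      683          3631
#> 2       6        167           2978     1169          3145
#> 3       9        228           2427     1659          2655
#> 4      12        279           1889     2146          2168
#> 5      15        319           1360     2635          1679
#> 6      18        349            840     3125          1189
#> 7      21        372            331     3611           703
```

Progressor counts grow with the horizon (an event within 3 months is also
an event within 6) while non-progressors and totals shrink (late
observations run out of follow-up and are censored) — the signature shape
of horizon labeling under end-of-study censoring.

```r
rep <- overall_cv(cohort, horizons = 3L, config = model_config(), seed = 1)
rep
#> <evaluation_report> setting: overall_cv
#>   h3: AUC 0.905 +/- 0.063 (pooled 0.885)

baseline_last_visit_cv(cohort, 3L, seed = 1, fold_plan = rep$folds)$auc_mean
#> [1] 0.7512516
```

On the planted-hazard cohort, the sequence model reaches 0.905 ± 0.063
cross-validated AUC at the 3-month horizon (mean ± sd over the ten
patient-level folds), against 0.751 for a logistic regression using only
the current visit: the margin is the value of visit history, which the
generator plants via heavy single-visit measurement noise around a smooth
latent drusen-growth trajectory. Takes ~90 s on one CPU.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "drusenseq", package = "drusenseq"))')
Rscript "$CLI" simulate --out run1 --n-eyes 200 --seed 1 --phantoms 2
Rscript "$CLI" extract  --volumes run1 --out run1/features
Rscript "$CLI" label    --input run1/cohort.csv --out run1/labels
Rscript "$CLI" train    --input run1/cohort.csv --out run1/models --horizons 3,6
Rscript "$CLI" evaluate --mode cv --input run1/cohort.csv --out run1/eval --horizons 3
```

Every output directory carries a `provenance.json` with the resolved
configuration and package versions; identical seeds reproduce artifacts
byte-for-byte.

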