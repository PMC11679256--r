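# subcortstage

Thalamus-referenced subcortical geometry and staged classification of
Parkinson's disease from labeled brain MRI segmentations.

## What it does, and for whom

Parkinson's disease (PD) reshapes the deep grey-matter structures long before
the full clinical syndrome: the prodromal stage already shows measurable
atrophy and spatial reorganization. This package is for neuroimaging
researchers who have subcortical segmentations (FreeSurfer `aseg`-style
labeled volumes or `aseg.stats` summaries) for cohorts of healthy control
(HC), prodromal (PR) and Parkinson's (PD) subjects and want a reproducible
pipeline from voxels to a staged diagnosis:

1. **Geometry features.** Each of 19 deep structures (thalamus, hippocampus,
   amygdala, caudate, putamen, pallidum, accumbens, ventral diencephalon,
   4th ventricle, cerebellum, CSF; merged labels pooled) is reduced to three
   numbers relative to the bilateral thalamus — the within-subject reference
   that tracks head size without involving cortex:

   - normalized volume `V_s / V_thal`,
   - Euclidean centroid distance
     `D_2(x, y) = (Σ_i |x_i − y_i|²)^{1/2}` (the Minkowski distance at
     `p = 2`), in mm,
   - cosine distance `D_cos(x, y) = 1 − (x·y)/(‖x‖‖y‖)` between the two
     centroid position vectors — orientation only, range `[0, 2]`.

   With sex and age this yields the 57-column feature table
   (1 thalamus volume + 3 × 18 structures + 2 demographics).

2. **Group statistics.** Per-feature one-way ANOVA across the three groups,
   Welch pairwise t-tests (HC–PD, HC–PR, PD–PR), chi-squared for sex, and
   Benjamini–Hochberg FDR adjustment within each of four category tables
   (demographics, volumes, Euclidean distances, cosine distances).

3. **Staged classification.** Three binary tasks (HC/PD, HC/PR, PD/PR), each
   with random-forest feature voting, a stratified 70/30 split, grid-searched
   logistic regression / random forest / RBF-SVC, held-out evaluation
   (accuracy, weighted precision/recall/F1, ROC/AUC), and a
   probability-summing ensemble that turns the three binary models into one
   three-way prediction with a confidence tier.

4. **Rough sets.** A minimal Pawlak-style rule classifier (`roughset()`) —
   boundary-midpoint discretization, greedy discernibility cut selection,
   sequential covering — as an interpretable cross-check: human-readable
   threshold rules with support, accuracy and coverage.

Real patient MRIs are access-controlled, so the package ships a synthetic
cohort generator with known ground truth: labeled 3D ellipsoid phantoms
(slow mode, exercises the full voxel path) or parametric feature tables
(fast mode, exercises statistics and learning), both seed-deterministic.

## Worked example

```r
library(subcortstage)

cfg    <- cohort_config(feature_effects = default_feature_effects(), seed = 42)
cohort <- generate_feature_cohort(cfg)   # 3 x 56 subjects, 57 features
tables <- build_category_tables(cohort$features)
head(tables$volumes[, c("feature", "anova_p_adj", "HCvPD_p_adj",
                        "HCvPR_p_adj", "PDvPR_p_adj")], 6)
#>                     feature anova_p_adj HCvPD_p_adj HCvPR_p_adj PDvPR_p_adj
#> 1              Thalamus_vol     0.51089     0.54252     0.83457       0.234
#> 2  Left-Hippocampus_normvol     0.90304     0.90304     0.83063       0.835
#> 3 Right-Hippocampus_normvol     0.90304     0.83457     0.99597       0.835
#> 4     Left-Amygdala_normvol     0.00231     0.00339     0.00421       0.903
#> 5    Right-Amygdala_normvol     0.86349     0.86349     0.71022       0.835
#> 6      Left-Caudate_normvol     0.45354     0.22950     0.72680       0.608

model <- pd_stage(cohort$features, seed = 42)
model
#> Staged three-task classification workflow
#>   HCvPD  16 features, best rf : accuracy 0.88, AUC 0.95
#>   HCvPR  16 features, best lr : accuracy 0.85, AUC 0.94
#>   PDvPR  16 features, best rf : accuracy 0.82, AUC 0.86

predict(model, cohort$features[1:3, ])
#>   CONTROL PRODROMAL PARKINSON predicted margin          tier
#> 1   1.081     1.123     0.797 PRODROMAL 0.0141 extremely low
#> 2   1.947     0.330     0.723   CONTROL 0.4079      moderate
#> 3   0.804     0.732     1.463 PARKINSON 0.2197           low
```

Reading the output: the injected generator effects (left amygdala / putamen /
accumbens atrophy in both patient groups, prodromal-weighted reorientation of
the left basal ganglia) surface exactly where designed — the left-amygdala
volume row is significant for both HC contrasts but not PD-vs-PR, and the
PD-vs-PR task is the hardest of the three, as expected when the two patient
stages differ mainly in orientation features. Ensemble rows sum each class's
probabilities over the two binary models that know about it (raw sums total
3); `margin` is the normalized gap between the top two classes and sets the
confidence tier.

The voxel path works the same way, just slower: `generate_phantom_cohort()`
writes labeled NIfTI volumes, `qc_scan_dir()` applies the exclusion rules
(missing/empty files, missing structures), `extract_subject_features()` +
`assemble_feature_table()` rebuild the same 57-column table from voxels.

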