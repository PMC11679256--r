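---
title: "Thalamus-referenced subcortical geometry and staged classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamus-referenced subcortical geometry and staged classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcortstage)
```

This vignette is the package's account of its own methods: the measurement
model, the statistical battery, the classification workflow, the synthetic
cohorts that stand in for access-controlled patient data, and the numerical
and design choices that were genuinely open. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

The input is a labeled segmentation volume: a 3D integer grid in which each
voxel carries the code of the structure it belongs to (FreeSurfer `aseg`
conventions; 0 = background), plus a 4×4 affine mapping 0-based voxel indices
to RAS millimetres. Nineteen deep structures are measured
(`structure_registry()`); the bilateral thalamus (labels 10 + 49) and each
cerebellar hemisphere (7 + 8, 46 + 47) are *merged* structures whose label
clouds are pooled before any computation.

Each structure is summarized by its voxel count times the voxel volume
(`|det|` of the affine's 3×3 block) and by its centroid — the unweighted mean
of the member voxel-center RAS coordinates. Three features per non-reference
structure follow:

* **Normalized volume** `V_s / V_thal`. The bilateral thalamus is the
  within-subject reference: among subcortical structures it tracks overall
  intracranial volume well while staying inside the subcortex the analysis is
  about. The assumption to keep in mind is that the reference itself is not
  (strongly) affected by group — the thalamus volume is also reported raw as
  its own feature, so a reference-driven artefact would be visible.
* **Euclidean distance** between the structure centroid and the thalamus
  centroid, in mm — the Minkowski distance at `p = 2`. Implemented for
  general `p ≥ 1` (`minkowski_distance()`), with `p = 2` the measurement
  default.
* **Cosine distance** `1 − cosθ` between the two centroids taken as position
  vectors. This measures orientation only — it is invariant to positive
  rescaling of either vector — and ranges over `[0, 2]`.

**The cosine origin question.** A cosine between two *position vectors* is
origin-dependent, and there are two defensible readings: vectors from the
coordinate origin to each centroid (the distance formula applied verbatim to
two centroid coordinates), or vectors *from the thalamus* to the structures
(which would make the thalamus-to-structure cosine degenerate). Only the
first is consistent with applying the printed two-argument formula to a
structure centroid and the thalamus centroid, so that is the implementation:
both centroids are taken as vectors from the native RAS origin, and the
origin is a parameter of `extract_subject_features()` for sensitivity
analyses. The consequence — translating a volume changes cosine features but
not Euclidean ones — is asserted as a property test, not hidden.

**Distance normalization.** Distances are reported raw in mm. Volume
normalization by the thalamus is the only normalization applied; no distance
rescaling is defined, and the interpretable rule thresholds (tens of mm)
match raw distances.

## Group statistics

Per feature: classical one-way fixed-effects ANOVA as the global test, then
Welch pairwise t-tests (unequal variances, Welch–Satterthwaite degrees of
freedom, two-sided) for HC–PD, HC–PR and PD–PR, reported regardless of the
ANOVA outcome. Sex (M = 0, F = 1) is tested once by Pearson chi-squared
without continuity correction. Descriptives use the sample (n−1) standard
deviation.

Multiplicity is handled by Benjamini–Hochberg FDR. The adjustment *family*
was an open choice (per column? per table? global?); the package adjusts
jointly across **all p-values within one category table** (ANOVA plus the
three pairwise columns), for each of the four categories: demographics,
volumes, Euclidean distances, cosine distances. A broader family is more
conservative per test but keeps each published-style table self-contained.
Note what BH does and does not control: on a table with ~60 true-null
p-values, occasional false flags at adjusted α = 0.05 are *expected*
behavior, not a defect — the recovery simulations therefore check the
per-structure significance pattern, not the absence of any other flag.

Degenerate inputs follow fixed conventions: both samples constant with equal
means → `t = 0, p = 1`; constant with different means → infinite statistic,
`p = 0`, with a warning; zero within-group variance everywhere → an error for
ANOVA; expected counts must be positive for chi-squared.

## The classification workflow

`pd_stage()` is the fitting front-end and returns a classed model with
`print`, `summary`, `plot` (ROC) and `predict` (ensemble) methods. Per binary
task (HC/PD, HC/PR, PD/PR):

1. **Feature voting.** A seeded random forest (500 trees) is fit on the full
   two-group sub-dataset; features are ranked by mean decrease in Gini
   impurity. The default selection keeps features with importance at or above
   the mean importance (`"topk"` is available); at least two features are
   always kept. How many features survive is an *outcome*, not a rule — age,
   for instance, is a candidate in every task and survives only where the
   forest ranks it highly.
2. **Split.** Stratified 70/30 train/test: `round(n_class × 0.3)` test
   subjects per class, so 56/56 yields 17 + 17 held-out subjects.
3. **Grid search.** Exhaustive small grids per family, scored by stratified
   5-fold CV accuracy on the training set, ties broken by first-in-grid
   order, winner refit on the full training set. The grids contain the
   workflow's canonical configurations: logistic regression `C ∈ {0.1, 1}`
   (ridge; `glmnet` with `λ = 1/(C·n)`, up to 100 iterations), random forest
   with 75/100 trees at depth 3 and minimum leaf 2/4 (depth is expressed as
   `maxnodes = 2³`, minimum leaf as `nodesize`; `randomForest` exposes no
   separate minimum-split knob), RBF-SVC with `C ∈ {1, 10}`,
   `γ ∈ {0.01, 0.1}` with probability estimates enabled. Fold count and the
   accuracy objective were unstated choices; 5-fold/accuracy is the common
   default and both are arguments.
4. **Evaluation.** Confusion counts; support-weighted precision, recall and
   F1 (the weighted average is what reproduces the equal accuracy/precision/
   recall pattern that balanced test sets produce); ROC over the positive
   class probabilities with trapezoid AUC. The best family per task (highest
   test accuracy, ties in family order) is retained for the ensemble.

**Selection leakage.** Voting on the full sub-dataset *before* splitting
follows the original workflow design, but it lets the selector see the
eventual test subjects, which measurably inflates null-cohort test accuracy
above chance. The package keeps the vote-first order as the workflow default;
the calibration experiment in the test suite votes on the training half only,
so that what it measures is classifier calibration rather than selection
optimism. Users who want leakage-free estimates should split first and pass
the training table to `rf_feature_vote()` themselves.

**Ensemble.** For each class, the probabilities assigned by the two binary
models whose task involves it are summed (raw sums total the number of
models); the prediction is the argmax, ties broken in the fixed order
CONTROL, PRODROMAL, PARKINSON and forced to the lowest tier. After
normalizing the sums to 1, the top-two margin sets the confidence tier:
high ≥ 0.5, moderate ≥ 0.25, low ≥ 0.1, else extremely low. The tier names
follow the workflow's design; the cutoffs are package choices (arguments of
nothing — they are fixed constants — but documented here as such).
Threshold comparisons use a 1e-9 tolerance because exact fractions like
`2/3 − 1/6` fall one ulp short of 0.5 in floating point. A caveat inherited
from the design: the three binary models share training subjects, so their
probabilistic outputs are not independent, and ensemble performance estimated
on any of the shared data is optimistic.

## The rough-set classifier

`roughset()` is a minimal Pawlak-style pipeline standing in for an external
rule-induction system whose exact algorithms are not public: boundary-midpoint
candidate cuts; greedy global cut selection maximizing newly discerned
different-class object pairs (deterministic, first-candidate tie-break, per
attribute budget `max_cuts_per_attribute = 4`); then sequential covering per
class, growing conjunctions of half-interval conditions (`attr ≤ τ`,
`attr > τ`) until class-pure or no condition improves purity, recording
support and accuracy, removing covered objects, repeating. Prediction lets
all matching rules vote with weight support × accuracy; unmatched samples and
exact vote ties abstain, and abstentions count against coverage.

Two regularizing choices matter: `max_rule_len = 4` caps conjunction length,
and `min_support` (default 12% of the training size, floored at 3) forbids
conditions that would shrink a rule below a meaningful support — without it,
sequential covering happily manufactures pure near-singleton rules that do
not generalize. Pairs of identical objects with different classes are
undiscernible by construction and are reported as inconsistencies rather than
silently absorbed.

## The synthetic cohorts

Real cohort data sits behind a controlled-access application, so the
generators define the study conditions the tests run under: three groups of
56 subjects (CONTROL, PRODROMAL, PARKINSON), 1 mm isotropic labeled volumes,
demographics with group means/SDs matching the published cohort (ages ~61.5
(11.5) / 66.3 (6.2) / 61.8 (11.0) years truncated to [40, 90]; female
proportions 0.321 / 0.250 / 0.429; optional UPDRS3 scores ~0.8 / 4.9 / 23.9).

**Phantom mode** rasterizes 23 axis-aligned ellipsoids (19 structures;
thalamus and cerebella contribute two labels each) at atlas-plausible RAS
offsets. Radii were chosen so volume *ratios* sit where the interpretable
rule thresholds put them (left amygdala ≈ 0.11 × thalamus), then uniformly
shrunk by a packing factor of 0.8 so neighbouring structures stay disjoint
under default jitter — the rasterizer treats any voxel claimed twice as a
hard error, per the generator contract. The default `template_scale = 1.25`
keeps the smallest structure near a thousand voxels because 1 mm voxelization
of smaller ellipsoids cannot recover volumes to the 3% tolerance the
ground-truth tests use; reduced scales (0.5–0.6) are used in tests where only
structural properties matter. Inter-subject variability is a per-structure
centroid jitter (`jitter_sd = 0.6` mm at scale 1, scaling with the template)
and a per-structure volume CV of 5%; group effects multiply ellipsoid radii
by `volume_scale^(1/3)` (so the expected volume scales exactly) and/or shift
centroids. The grid origin is floored to integer millimetres so the affine
survives NIfTI's float32 storage exactly.

**Fast mode** draws the 57-column feature table directly from independent
normals whose baseline means derive from the same template geometry; group
effects enter as standardized mean shifts (`d` units of the feature's
within-group SD) in designated columns. `default_feature_effects()` encodes
the qualitative group pattern the pipeline is designed to detect — early
bilateral-onset atrophy of left amygdala/putamen/accumbens (both patient
groups vs controls), PD-weighted caudate and ventral-diencephalon volume
loss, shortened left-hippocampus and right-caudate distances, lengthened
right pallidum/putamen distances, and prodromal-weighted reorientation of the
left basal ganglia. The PD/PR asymmetry of the cosine effects is what makes
PD-vs-PR learnable while remaining the hardest task. Effect *sizes* are
plausibility choices (the source material reports test statistics, not
generator-usable effect sizes); the parameter-recovery simulation injects
`d = −1.1` on the three volume columns so that the pattern check is decisive
rather than marginal at n = 56 per group.

What fast mode deliberately does **not** emulate: correlations between
features (real normalized volumes and distances co-vary), non-Gaussian tails,
scanner/site effects (the study population mixes scanners and applies no
harmonization), and any volume–demographic coupling. Passing tests therefore
show the pipeline's statistical machinery is correct and calibrated under its
stated model — not that real MRI cohorts will reach comparable accuracies.

## Problem sizes and numerical conventions

The test suite runs the statistical calibration on 37 null cohorts pooled
across 55 null features (≥2000 ANOVA and ≥6000 Welch p-values; rejection
rates checked against the (0.04, 0.06) band), the classifier calibration on
10 null cohorts (340 pooled held-out predictions against the binomial 95%
interval around 0.5), the parameter recovery on 100 seeded replicates, and
the oracle equivalence on 20 reduced-scale phantoms against a literal
full-grid voxel scan. These sizes were chosen so each check has the power to
fail meaningfully while the whole suite stays comfortably interactive.

Conventions worth knowing when extending the package: voxel indices are
0-based at the API surface (matching the affine convention) and converted
internally to R's 1-based arrays; cosine distances are clamped to `[0, 2]`
and return exact endpoints for exactly equal or exactly antipodal inputs;
`fdr_adjust` validates `p ∈ [0, 1]` and preserves input order; splits,
forests, folds and SVM probability models are all governed by explicit
integer seeds and reproduce bit-identically under them.

## Limitations

Ellipsoid phantoms have none of the shape complexity of real anatomy, and
centroid-based features discard it by construction. The ensemble has no
external validation path in-package — by design it shares training subjects
across tasks. Age is a candidate feature but never a covariate; no
mixed-effects or harmonization layer is provided. The rough-set learner is a
minimal faithful pipeline, not a reimplementation of any particular external
rule-induction software; rule counts and exact rule sets will differ from
such systems even at matched accuracy.
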