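# rnfltcorrect

Detection and correction of segmentation-failure artifacts in peripapillary
retinal nerve fiber layer thickness (RNFLT) maps from spectral-domain OCT,
with a harness for measuring what correction buys downstream glaucoma
analyses.

## The problem

RNFLT maps are the primary structural measurement for diagnosing and
monitoring glaucoma, but OCT layer segmentation fails often — degraded
signal, vitreous opacity, retinal pathology — and failed pixels collapse
below the physiological measurement floor of ~50 µm. The package treats
those pixels as missing data to be restored:

* **Artifact**: a pixel with thickness < 50 µm outside the optic disc.
  Artifact pixels keep their measured values (they are never assumed zero).
* **Artifact ratio (AR)**: artifact area / map area excluding the disc.
  AR < 2% ⇒ *high quality* (usable as ground truth); AR > 5% ⇒ *low
  quality* (artifact-pattern donor).
* **Pseudo-artifacts**: since the truth under a real artifact is
  unobservable, supervised pairs are built by transplanting artifact
  patterns (mask *and* sub-floor values) from low-quality donors onto
  high-quality maps.
* **Correction model**: a compact convolutional encoder–decoder with skip
  connections, trained with

  L_overall = L_correct + w_contrast · L_contrast + w_consistency · L_consistency

  where L_correct is a global plus mask-weighted L1 reconstruction error,
  L_contrast is a normalized-temperature cross-entropy tying the bottleneck
  embedding of each map to that of a shifted/rotated copy, and
  L_consistency matches the mean and SD of the prediction to the
  uncorrupted part of the input. At inference only the detected artifact
  region is replaced (clipped to ≥ the floor); measured pixels pass through
  untouched.

Accuracy is reported as MAE and Pearson R in the pseudo-artifact region,
pooled across maps, overall and stratified by AR (≤10%, >10%, >20%), for
full maps and for the standard 3.46-mm circumpapillary circle scan.
A clinical-utility harness adds visual-field (VF) reliability filtering,
30-day OCT–VF pairing, circle-scan structure–function regression, four
trend-based progression criteria (MD, VFI, pointwise TD, fast MD),
patient-level cross-validation and bootstrap comparison of raw vs corrected
inputs. Everything runs on a built-in synthetic cohort generator, so the
whole pipeline is exercisable without clinical data.

## Worked example

```r
library(rnfltcorrect)

# a synthetic cohort: maps with arcuate-bundle anatomy + linked VF series
cohort <- simulate_cohort(n_patients = 45, size = 64, donor_prob = 0.35, seed = 7)
cohort

# pseudo-artifact training pairs, split 70/30 at patient level
corpus <- build_pseudo_corpus(cohort, seed = 8)

# fit the correction model
model <- train_correction_model(corpus$train, epochs = 10, seed = 9)
model

# correct one held-out corrupted map and score it
pair <- corpus$test[[1]]
res <- predict(model, pair$input, pair$disc)
region_metrics(unclass(res$map), unclass(pair$target), pair$pseudo_mask)

# AR-stratified accuracy over the whole held-out set
stratified_report(corpus$test, model)
```

Output from this exact run:

```
synthetic RNFLT cohort: 56 eyes of 45 patients (23 donor maps), 64x64 px
RNFLT artifact-correction model (64x64 input, widths 8-16-32-32)
  trained 10 epochs; L_overall 1.0396 -> 0.6519
  loss weights: w_contrast 0.1, w_consistency 0.1, lambda_mask 5
region metrics: MAE 5.21 um, R 0.535 (R2 0.286), 716 px
artifact-correction accuracy in the pseudo-artifact region
  stratum surface n_maps n_pixels  mae     r    r2
  overall     map     17     9251 5.32 0.692 0.479
  overall  circle     17      774 6.71 0.764 0.584
 ar_le_10     map      5     1573 5.57 0.719 0.517
 ar_le_10  circle      5      157 6.88 0.732 0.536
 ar_gt_10     map     12     7678 5.27 0.682 0.465
 ar_gt_10  circle     12      617 6.67 0.768 0.590
 ar_gt_20     map      2     1631 4.89 0.690 0.476
 ar_gt_20  circle      2      133 5.88 0.728 0.530
```

Reading it: the training pairs carry pseudo-artifacts at ARs between ~5%
and 30%; after ten epochs on this deliberately small cohort (39 training
pairs) the model restores corrupted regions to within ~5 µm of the hidden
truth — the corrupted inputs themselves are ~45 µm off — with pooled R
around 0.7 in the artifact region. At the study scale the acceptance
script runs (300 maps, 208 training pairs), the same ten epochs reach an
artifact-region MAE near 3.5 µm with pooled R above 0.9.

The same pipeline is scriptable from a shell via the thin CLI
(`inst/cli/rnfltcorrect`): `simulate`, `corrupt`, `train`, `correct`,
`evaluate`, `label-progression`, `predict-vf`, `compare`; every run writes
a `run_config.json` snapshot of all parameters and seeds.

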