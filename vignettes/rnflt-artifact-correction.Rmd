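---
title: "Correcting segmentation-failure artifacts in RNFLT maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting segmentation-failure artifacts in RNFLT maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Peripapillary retinal nerve fiber layer thickness (RNFLT) maps from
spectral-domain OCT are the workhorse structural measurement in glaucoma
care. Their weak point is the segmentation step: when the device fails to
delineate the nerve fiber layer — degraded signal, vitreous opacity, retinal
pathology — the reported thickness collapses below the physiological
measurement floor of about 50 µm. Such sub-floor pixels are, for practical
purposes, missing data, and they are common enough to compromise both visual
interpretation and downstream machine-learning use of the maps.

`rnfltcorrect` treats this as a supervised inpainting problem:

1. **Detect.** An *artifact* is any pixel with thickness below the floor
   (default 50 µm) outside the optic-disc region. The *artifact ratio* (AR)
   is the artifact area over the map area excluding the disc. Maps with
   AR < 2% are *high quality*; maps with AR > 5% are *low quality*.
   Importantly, artifact pixels keep their measured values — they are never
   zeroed.
2. **Build training pairs.** Ground truth cannot be observed for a corrupted
   eye, so supervised pairs are manufactured: artifact patterns (mask *and*
   sub-floor values) are harvested from low-quality donor maps and
   transplanted, under a random rigid shift/rotation, onto high-quality
   maps. The corrupted copy is the model input; the untouched high-quality
   map is the target. Values are transplanted rather than masks alone so
   the model sees realistic corrupted intensities.
3. **Correct.** A compact convolutional encoder–decoder with skip
   connections predicts a full thickness map; the returned result keeps the
   measured values everywhere except on the detected artifact mask, where
   the network's prediction (clipped to at least the floor) is blended in.

## The model and its loss

The network has four resolution levels (default widths 8–16–32–32 at
64×64 input), 3×3 kernels, ReLU activations, average-pool downsampling,
nearest-neighbor upsampling, and skip connections from each encoder level to
the matching decoder level. Inputs enter as two channels: thickness scaled
by 1/100 and a binary sub-floor indicator. A global-average-pool +
linear head on the bottleneck produces an L2-normalized embedding used by
the contrastive term. The implementation is self-contained (compiled
convolution primitives plus an explicit backward pass) and deterministic
given a seed.

Training minimizes

\[
L_{\mathrm{overall}} \;=\; L_{\mathrm{correct}}
\;+\; w_{\mathrm{contrast}}\, L_{\mathrm{contrast}}
\;+\; w_{\mathrm{consistency}}\, L_{\mathrm{consistency}},
\]

with:

* \(L_{\mathrm{correct}}\): mean absolute error over the whole grid plus
  \(\lambda_{\mathrm{mask}}\) (default 5) times the MAE restricted to the
  pseudo-artifact region. L1 was chosen because the evaluation metric is
  MAE in the artifact region; the masked term focuses capacity on the
  pixels that actually need reconstruction.
* \(L_{\mathrm{contrast}}\): normalized-temperature cross-entropy over
  cosine similarities of bottleneck embeddings. Each map in a batch is
  paired with a shifted/rotated version of itself (reflection fill);
  the pair are positives, all other batch members negatives. This pushes
  the encoder toward representations that are stable under the nuisance
  transforms an OCT acquisition can undergo.
* \(L_{\mathrm{consistency}}\): \(|\Delta \mathrm{mean}| +
  |\Delta \mathrm{sd}|\) between the prediction and the input over the
  *uncorrupted, non-disc* pixels — a first-two-moments reading of
  "the corrected map should keep the statistical distribution of the
  original measurements".

Defaults \(w_{\mathrm{contrast}} = w_{\mathrm{consistency}} = 0.1\),
temperature 0.5, augmentation bounds ±8 px and ±10°; all exposed in
`loss_config()`. Optimization is Adam (default learning rate 3e-3, batch
size 8, 10 epochs). These optimizer settings were chosen during model
development on synthetic corpora; nothing in the package depends on them
beyond the defaults.

Two design points were genuinely open and decided here: (i) only the
artifact region is replaced at inference (measured data are preserved;
`regenerate_all = TRUE` gives the raw network output for diagnostics), and
(ii) a corrected map is idempotent under re-correction, because the blend
clips filled values to the floor so nothing remains sub-floor.

## The synthetic cohort generator

The clinical maps the method is meant for are not distributable, so the
package ships a generator that reproduces the features the pipeline
actually exercises:

* **Anatomy.** Thickness = background (62 µm) + superior and inferior
  arcuate bundles modeled as Gaussian ridges on an annulus (peak radius
  1.7 mm, radial sd 0.55 mm, angular sd 0.55 rad, amplitude 55 µm at the
  poles ±65° from the temporal axis), giving the familiar double-hump
  TSNIT profile on the 3.46-mm scan circle. A `severity` parameter in
  [0, 1] scales bundle loss, emulating glaucomatous thinning; across a
  cohort severities are Beta(1.2, 2.2). Gaussian pixel noise (sd 3 µm) is
  added and the result clipped to the floor outside a low-valued disc
  (radius 0.8 mm, disc area ≈ 2 mm², the typical adult disc). With these
  settings the cohort mean thickness and circle-scan profile sit in the
  physiological range of a mixed glaucoma-clinic population.
* **Artifacts.** Unions of random ellipses (scale 0.5 mm) plus, with
  probability 0.5, an annular wedge crossing the scan circle — the shape a
  run of failed B-scans produces. Fill values are uniform on [0, 45] µm.
  Blobs are added, the last one shrunk to size, until the achieved AR is
  within ±20% of the target.
* **Visual fields.** Per-eye series of 24-2 exams: evenly spaced dates, MD
  and 52 TDs linear in time plus test–retest noise (default sd 0.5 dB), VFI
  an affine function of MD clipped to [0, 100] (VFI = 100 + 2.1·MD, which
  reproduces the usual clinic means), and reliability indices drawn so
  ~90% of exams pass the fixation-loss ≤ 33% / false-positive ≤ 20% /
  false-negative ≤ 20% filter — so the filter has something to filter.
* **Structure–function link.** Baseline MD = a·(mean circle-scan
  thickness − b) + noise (defaults a = 0.12 dB/µm, b = 100 µm,
  sd 0.7 dB), so a real signal exists for the prediction harness; a
  fraction of eyes (default 30%) declines at −1.5 dB/year, the rest are
  stable.

What the generator does **not** emulate: media-opacity physics, floor-level
measurement censoring beyond a hard clip, epiretinal-membrane morphology,
inter-visit co-registration error, or any device-specific texture. Passing
tests on this cohort therefore demonstrate that the pipeline's mechanics
(detection, transplantation, training, blending, evaluation, statistics)
are correct — not that the trained network would reach clinical accuracy on
real Cirrus maps.

## Geometry conventions and numerics

* Grids are row-major with pixel centers at integer coordinates and origin
  top-left; the default map is 200×200 at 0.03 mm/px (6×6 mm, standard for
  this device class) — the desk-scale profile used in tests and examples is
  64×64 at the same physical extent.
* The scan circle (3.46 mm diameter) is centered on the disc-mask centroid,
  falling back to the grid center; sampling is bilinear at 256 angles,
  counter-clockwise from the temporal side (TSNIT order). The sample count
  and start are configuration, not fixed truth.
* AR strata follow the reporting convention: ≤10% vs >10% partition the
  data and >20% is nested inside >10%; boundary values go to the ≤ side.
* Metrics pool pixels across maps within a stratum (a per-map aggregation
  is attached for diagnostics); Pearson r is flagged undefined on
  zero-variance regions; circle-scan restriction uses nearest-pixel mask
  lookup at each angular sample, since masks are pixel-level and samples
  continuous.
* Trend p-values are two-sided t-tests on the OLS slope (time in years
  since first exam); a zero-residual fit returns p = 0. All printed
  thresholds are applied with their printed inequality directions
  (slope < 0, slope ≤ −1 dB/yr, p < 0.05, ≥ 5 exams, ≥ 4 years,
  reliability bounds inclusive).
* The bootstrap comparison resamples evaluation units (eyes) with
  replacement and reports a percentile CI and two-sided p for the paired
  metric difference; the unit is the eye because eyes are the natural
  evaluation unit for progression, with patient-level resampling available
  by aggregating first.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise the full pipeline at a
desk scale chosen so everything reruns comfortably on one CPU: 300
synthetic high-quality maps (64×64) with 60 low-quality donors at target
ARs 5–30%, a 70/30 patient-level split, 10 training epochs; 200 simulated
VF series per progression condition; 200 bootstrap-calibration replicates
of 200 resamples each. At this scale the held-out artifact-region MAE of
corrected maps runs well under half the corrupted inputs' MAE with pooled
R above 0.8 — the package's headline property on synthetic data.

## Known limitations

* The correction network is intentionally small; it reconstructs bundle
  anatomy at the fidelity the synthetic cohort contains, and pixel noise is
  irreducible for it. Real clinical performance would require training on
  real high-quality maps.
* Donor patterns are transplanted with their values; if a future source of
  donors had values *at* the floor rather than below it, the pseudo-mask
  and the detected mask could diverge. The package always records the
  pseudo-mask explicitly for that reason.
* `classify_quality` boundaries (2%, 5%) and the floor (50 µm) are
  conventions of the problem domain, exposed as parameters but not
  revisited by the package.
* The VGG-scale deep structure–function predictors used in large-cohort
  studies are out of scope; the harness ships the linear/logistic
  circle-scan variants and a pluggable interface (`fit_vf_predictor`,
  `fit_progression_classifier`) so a heavier regressor can be swapped in.
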