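---
title: "Classifying MR series from DICOM metadata and images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying MR series from DICOM metadata and images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large MR imaging repositories accumulate thousands of series whose
descriptive header fields (Series Description, Sequence Name, Protocol Name)
are vendor-specific, locally defined, frequently missing, and sometimes
stripped by anonymisation. Cataloguing such archives by hand does not scale,
yet most downstream research — cohort selection, radiomics, segmentation
model training — needs each series labelled by what it actually is: its
weighting (T1W / T2W / DWI), whether fat suppression was applied, whether it
was acquired after contrast administration, and its pulse-sequence family
(spin echo, gradient recalled, inversion recovery, echo planar).

`mrseries` implements a hierarchical cascade of five conditionally connected
classifiers over these axes. The cascade reflects clinical logic rather than
a flat multiclass problem:

1. **Others** — an initial relevance filter separating diagnostic
   T1W/T2W/DWI acquisitions from localisers, calibration scans, parametric
   maps, screenshots, and under-represented sequence types. An "other"
   decision stops the cascade.
2. **Weighting** — T1W vs T2W vs DWI, for relevant series only. A DWI
   decision stops the top branch.
3. **Fat Suppression** — FS vs nFS, only for T1W and T2W.
4. **Contrast** — CE vs nCE, only for T1W, and *image-based*: acquisition
   parameters of pre- and post-contrast T1W series are typically identical,
   and the Contrast Bolus Agent tag is often left empty, so the module
   analyses the central slice of a representative volume instead.
5. **Family** — SE / GR / IR / EP for every relevant series. The Scanning
   Sequence tag answers this directly when present and usable; the learned
   model is invoked only when the tag is empty or carries the value
   "Mode Research" (compared case-insensitively after trimming, since the
   exact formatting in the wild is not standardised).

The final composite label follows the grammar
`OTHERS | DWI | (T1W|T2W)_(FS|nFS)[_(CE|nCE)]`, eight classes in total,
with the family reported separately.

Because the cascade is conditional, end-to-end accuracy is bounded by the
product of the traversed modules' accuracies: small per-module error rates
compound, and an early mistake routes a series down a branch where every
later decision is wrong. `evaluate_pipeline()` therefore reports both
per-module accuracies on ground-truth-routed populations and the end-to-end
eight-class metrics.

## Tabular modules

Four modules operate on encoded DICOM tags. The default schema
(`default_tag_schema()`) covers the acquisition-physics tags that determine
the five targets — repetition/echo/inversion time, flip angle, echo train
length, scanning sequence, scan options, diffusion b-values, bandwidth,
geometry — plus the three descriptive text tags and the contrast agent tag.
Per-instance values reduce to one value per series: numeric tags take the
median when constant within tolerance and otherwise become a sorted-unique
joined code list (so a two-b-value diffusion series yields `"0|800"`); text
tags take the first non-empty value.

A preliminary keyword classifier over the normalized concatenation of the
three descriptive tags assigns a coarse textual category (T1-like, T2-like,
DWI-like, FLAIR/IR-like, localiser-like, map/derived-like, UNKNOWN) plus
independent contrast-marker and fat-suppression-marker flags. Its output is
*never* a final prediction — the router does not read it — it is an
engineered feature concatenated with the encoded tags for every tabular
module. The keyword lists live in a versioned configuration file
(`inst/extdata/lexicon.yaml`); the category set fixes the one-hot width, so
changing the lexicon version is an explicit, visible act.

Encoding: numerics pass through with missing-as-zero plus a missingness
indicator (tree ensembles split on the indicator; imputing physics values
would invent data); categoricals one-hot over the levels observed in
training, with unseen predict-time levels encoding as an all-zero group;
text tags contribute presence indicators. Feature selection is performed
per module on training rows only, with a chi-square test of independence
(no continuity correction) for indicator columns and Kruskal–Wallis for
numeric columns at a flat per-test level of 0.01 and no multiple-testing
correction by default (a `correction` switch exists). The choice of tests
is a design decision — any distribution-free association test would serve —
and both the tests and the level are configurable. Each fitted selection
carries a fingerprint of the rows it saw, so accidentally reusing it on a
different split is flagged as leakage.

Two tree-ensemble backends are provided with fixed hyperparameters: a
random forest (maximum depth 9, `floor(log2(p))` features per split, no
pruning; `ranger` stands behind this backend, which offers Gini rather than
entropy node impurity — with fully grown depth-limited trees on these
features the distinction is immaterial) and gradient-boosted trees
(logarithmic loss, depth 6, L2 regularisation 3, 64 histogram borders;
`xgboost` stands behind this backend). Unstated training lengths default to
500 trees / 500 boosting rounds at learning rate 0.1, chosen for stability
at desk scale and overridable. Class weighting (inverse frequency) is on by
default. The boosted backend is the pipeline default; both backends are
exercised by the tests and reach equivalent accuracy on separable header
data.

## The contrast image branch

For the representative image, volumes of a series are split by image-type
class, b-value, echo time, and temporal position (in that precedence);
derived/secondary volumes (DERIVED, SUBTRACT, PROJECTION, MPR, SCREEN) are
excluded, the surviving volume with the most slices wins, and ties resolve
to the lowest discriminator value — so a multi-b-value diffusion series
contributes its b=0 volume and a dual-echo series its short-echo volume.
The central slice is `floor(N/2)` (0-based) of the spatial order (slice
positions projected on the volume normal, falling back to instance
numbers); the even-`N` convention is a documented choice since "central"
is ambiguous there. Preprocessing clips to the 1st–99th percentile window,
rescales to [0, 1] — making the branch invariant to vendor intensity
scaling — and resizes bilinearly to 224 × 224.

The reference training schedule for this branch (batch 128, 100 epochs,
binary cross-entropy, Adam at 1e-5 with reduce-on-plateau: factor 0.8,
patience 10, minimum 1e-7) is designed for fine-tuning a pretrained
ResNet-50 with its last three blocks unfrozen. No deep-learning runtime is
bundled with this package, so the `resnet50` backbone option exists in the
configuration but raises an informative error; the runnable backbone is
`small_cnn`: three 3×3 convolution blocks (8/16/32 channels, ReLU, 2×2 max
pooling) over a 32×32 average-pooled, per-image mean-centred input, a
global max-pooling head (suited to "is a bright local structure present"
decisions — enhancement manifests as compact bright vessels and rims), and
a sigmoid output. It is implemented directly on BLAS matrix products and
trains in well under a minute on one CPU at the cohort sizes used here.
Training from scratch needs a larger step size than fine-tuning, so the
small-CNN experiments in the tests pass `lr = 2e-3`, batch 16, and 10–12
epochs explicitly; the scheduler and best-validation-loss checkpointing
behave identically under both schedules.

## The synthetic cohort generator

The PRIMAGE repository itself is not publicly available, so the package
ships a generator whose defaults emulate the published composition of that
cohort: 18,181 series with Others 1,310; T1W 9,489 / T2W 5,832 / DWI 1,550
among the analysed series; fat suppression 8,249 vs 7,072 within T1W/T2W;
contrast 7,272 vs 2,217 within T1W; vendor counts Siemens 10,734 / Philips
4,182 / GE 3,162 / Toshiba 103; the 1.5 T : 3 T and per-country mixes of
the published test set. Patients carry a truncated-geometric number of
series (mean 15, cap 60, matching roughly 18,181 series over ~1,200
studies), grouped into studies that fix vendor and field strength — so
patient-grouped splitting is meaningful rather than trivially balanced.

Header values follow label-conditional textbook ranges chosen to make the
labels recoverable: T1W spin echo TR 400–800 ms / TE 8–20 ms; T1W gradient
echo TR 100–400 ms / TE 2–10 ms / flip 10–35°; T1W inversion recovery
(MPRAGE-like) TI 800–1,200 ms; T2W spin echo TR 2,000–6,000 ms /
TE 80–120 ms; T2W IR (FLAIR-like) TI 1,800–2,800 ms; DWI echo-planar with
b ∈ {0, 800–1,000}. Families are drawn conditionally on weighting
(DWI → EP; T1W → SE/GR/IR at 0.40/0.57/0.03; T2W → SE/IR at 0.96/0.04);
the published per-family counts cover only 15,470 of the 16,871 analysed
series, so exact proportionality is unattainable and the conditional rates
were fixed once to respect physics (no T2W gradient-echo rule exists in the
generator) while keeping the marginals in the published rank order.

Four vendor dialects differ in descriptive vocabulary (tse/fse,
SPAIR/fatsat, "+c"/"gd"/"post"), which optional tags they populate, and a
global pixel intensity scale. Fat suppression is encoded redundantly — a
Scan Options flag (85%) and a description keyword, with at least one
guaranteed on uncorrupted headers — and contrast fills the Contrast Bolus
Agent tag only 40% of the time even when enhanced (the tag is known to be
unreliable in practice), again with the description keyword guaranteed when
the tag is absent. Corruption is applied after generation: per-tag
missingness (tags are removed; absence is the only missing encoding), text
garbling, and ground-truth label noise. Defaults are mild (5% missingness,
30%/20% extra dropout of Sequence Name/Protocol Name, 5% text noise, 1%
label noise); passing zeros yields a *clean* cohort on which a hand-written
rule classifier inverting the generation rules (`rule_classify()`) recovers
100% of labels — this certification gates every learning experiment.

Pixel data are elliptical body phantoms, not anatomy: compartment
intensities follow the weighting (bright fat on T1W, bright fluid on T2W,
blurred noisy DWI), fat suppression attenuates the fat ring by 75%, and
enhancement adds vessels, a rim, and a lesion at a configurable
contrast-to-noise ratio (default 5× the noise SD; 0 disables the signal
entirely, giving a null task). What passing tests on this generator shows
is that the pipeline's machinery — encoding, selection, routing, training,
evaluation — recovers planted signal under controlled corruption; it does
not show that real MR headers are this separable, that real enhancement is
this visible on a central slice, or that the published accuracies transfer.
The published end-to-end numbers are reproduced only through the exact
metric oracle on the published confusion matrix (`primage_confusion()`).

## Splitting and evaluation

Splits are by patient (80/20 by default), with a greedy assignment that
processes patients in decreasing series count and places each where the
squared deviation of per-class and total series counts from their targets
shrinks most — "series balanced" is under-specified in the source, and this
deterministic greedy honours both patient disjointness and class balance to
within ±0.03 at the cohort sizes used. Cross-validation (5-fold, 90/10)
uses the same machinery with k bins; encoder and feature selection are
re-fitted inside every fold.

`metrics_from_confusion()` computes per-class precision/sensitivity/F1,
macro and support-weighted aggregates, and accuracy, with half-up display
rounding to 3 decimals; weighted sensitivity equals accuracy by identity,
which the tests assert on random matrices. Confidence intervals are
percentile bootstrap over series (2,000 resamples, 95%, seed-deterministic);
the interval method in the source publication is unstated, and percentile
bootstrap was chosen as the assumption-free default, configurable via
`n_boot`/`level`. Multiclass AUC, where reported, is one-vs-rest
macro-averaged and is never part of the exact oracle. Subgroup reports by
vendor, field strength, or country flag levels below 30 series as unstable
rather than suppressing them.

## Numerical and degenerate-input choices

* Argmax ties in any module resolve to the lexicographically first class.
* A constant image preprocesses to all zeros; a constant feature column is
  dropped from selection with p recorded as 1.
* A series with no pixel data routes contrast to `"undetermined"`: the
  label renders without a CE suffix and is flagged, never guessed.
* Multi-valued Scanning Sequence tags resolve by IR > EP > GR > SE (the
  more specific acquisition designators win); this priority is a design
  decision, as no multi-value rule is stated in the source.
* A cohort with a single patient cannot satisfy a test fraction; the split
  warns and returns everything as training data.
* The plateau scheduler reduces when the non-improvement count reaches the
  patience (with constant losses from epoch 1, patience 10 triggers at
  epoch 11) and never drops below the configured floor.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen as the package's own desk-scale study conditions: 2,000-series
cohorts for the end-to-end and oracle-certification experiments, 1,000
series per replicate (three seeds) for the corruption-monotonicity
comparison, 500 phantoms for the contrast-recovery experiment and 300 per
seed for its null counterpart, 15,000 series (~1,000 patients) for the
split-hygiene check, and 200 repeats of a five-column null for selection
calibration.

## Known limitations

* The pretrained deep-residual contrast backbone is configuration-only; the
  shipped trainable backbone is the small CNN.
* The DICOM codec is deliberately minimal: explicit VR little endian,
  single-frame uncompressed monochrome pixel data, no sequence (SQ)
  elements, no DICOMDIR, no networking. pydicom reads its output, and it
  reads its own output plus the tag subset it knows from conformant files.
* The generator's header ranges are plausible, not fitted: no per-label
  header statistics exist in the source to calibrate against.
* Family evaluation on real data depends on the Scanning Sequence tag's
  honesty; the generator's "Mode Research" quirk models only one of the
  ways that tag fails in the wild.
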