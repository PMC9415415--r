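---
title: "Within-season crop recognition: models, synthetic data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-season crop recognition: models, synthetic data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(croprec)
```

## The problem

Crop maps are usually produced once, at the end of a growing season, from a
full-season image time series plus a same-year field survey. Decision makers
(irrigation districts, food-security planners) need the opposite: to know
*during* the season which plots carry corn, alfalfa or bean, without a new
field survey, and despite clouds removing many optical acquisitions.

`croprec` implements a within-season recognition pipeline for that setting:

1. per-plot zonal mean reflectance in nine Sentinel-2 L2A 20 m bands
   (B2-B12/B8A, unit scale, i.e. surface reflectance divided by 10^4);
2. two vegetation indices per plot and date:
   NDVI = (B8A - B4)/(B8A + B4) and WDVI = B8A - a·B4, where *a* is the
   soil-line slope estimated from bare plots as a ratio of sums,
   a = Σ B8A_i / Σ B4_i;
3. multitemporal records pairing the current scene with scenes 15/30/60 days
   earlier under four combination schemes (C1: 0/30/60 days; C2: 0/30;
   C3: 0/15/30; C4: 0/15), 11 descriptors per scene (nine bands + NDVI +
   WDVI), so records have 33 or 22 descriptors;
4. a vegetation-emergence filter: a record is eliminated if WDVI < 0.005 on
   any of its scenes (no standing crop there);
5. two classifiers: a one-vs-one SVM with the cubic polynomial kernel
   k(x, x_i) = ((xᵀx_i) + 1)³ on standardized descriptors, and a 100-tree
   bagged ensemble; stratified 5-fold cross-validation;
6. evaluation by confusion matrix: overall, producer's and user's accuracy,
   Cohen's kappa κ = (p_o - p_e)/(1 - p_e) with its qualitative (Altman)
   rating, including a per-date timeline on a later, unlabeled crop cycle.

Because no plot-level survey data are deposited with the study this package
emulates, a first-class synthetic generator reproduces the survey's
statistical design so every stage is testable end to end.

## The synthetic irrigation module

`generate_dataset()` simulates one crop cycle of an irrigation module:

* **Crop pattern.** Labels are either fixed counts (preset `"survey2019"`:
  280 plots — 154 corn, 72 alfalfa, 54 bean — with a stratified 50/50
  train/validation split; preset `"cycle2020"`: 895 plots — 590 corn,
  264 alfalfa, 41 bean) or sampled from the 2019 priors
  (corn 67.2%, alfalfa 22.5%, bean 5.9%, other 4.4%,
  `crop_priors_2019()`). "Other" plots are generated but excluded from the
  training pool by default, matching three-class training.
* **Phenology.** Canopy cover is a normalized logistic rise (zero exactly at
  sowing) to `peak_cover`, with exponential senescence for annuals; bean
  drops to bare soil after its early-July harvest (day-of-year 186); corn
  stands until the end of September; alfalfa is an exactly periodic sawtooth
  with a 56-day (eight-week) cut interval regrowing from 8% stubble cover.
  The sources give no functional form for these trajectories, only the
  qualitative calendar (sowing through April/May, bean harvested at grain
  filling in early July, alfalfa cut roughly every eight weeks); the logistic
  rise + exponential senescence is this package's choice, with all shape
  parameters exposed in `crop_calendar_entry()`. Sowing dates are drawn
  uniformly within each crop's sowing window — staggered sowing is exactly
  what makes single-date classification hard and multitemporal records
  informative.
* **Spectra.** Each pixel is a linear soil/vegetation mixture weighted by
  cover, plus per-band Gaussian noise (default sd 0.01 reflectance), clipped
  to [0, 1]; the plot record is the zonal mean over its 8-10 pixels. The
  default soil endmember lies exactly on the default soil line
  (B8A = 1.62 · B4). Species differ spectrally at equal cover:
  `default_vegetation_offsets()` gives corn a brighter NIR/SWIR plateau,
  alfalfa a darker, wetter canopy (depressed NIR and SWIR) and bean a
  near-base legume spectrum. The `class_separation` multiplier scales these
  contrasts (0 collapses all crops onto one canopy spectrum, which leaves
  cover trajectory as the only class signal and makes short-lag schemes
  nearly blind at canopy plateau).
* **Calendars.** `calendar_2019()` encodes the 5-day overpass cadence
  April-September with 27 usable scenes (all of April, May, August; four
  each in June and July; one in September). The per-month counts are known
  but not every cloudy date is, so the June/July subsets were fixed once,
  consistent with the published scene-matching examples (6 July with C1
  resolves to 6 July / 6 June / 7 May, with C3 to 6 July / 21 June /
  6 June). `calendar_2020()` uses a 15-day usable cadence anchored at
  21 April 2020, reproducing the test-cycle structure in which 6 May admits
  only C4, 21 May adds C2/C3, and C1 first forms on 20 June.
* **Seeding.** Every stochastic stage (labels, sowing dates, pixel counts,
  noise, splits, folds, bootstrap) draws from a seed derived from one root
  seed, so equal seeds give byte-identical datasets.

### What the generator does and does not emulate

It reproduces the *statistical design*: class priors and imbalance, staggered
sowing, alfalfa cutting, bean harvest, cloud outages, plot-level sampling
units, two independent cycles. It does not attempt radiative-transfer
realism: no atmosphere or BRDF, no within-field heterogeneity beyond iid
pixel noise, no spectral trajectory of senescence (browning is modeled as
cover loss, not a changed canopy spectrum), no georeferenced rasters. Tests
passing on this generator therefore validate the *pipeline logic and its
statistical behavior* — record assembly, filtering, training protocol,
accuracy bookkeeping, the rising within-season accuracy trend — not
field-data accuracy levels, which are typically lower (the synthetic spectra
are cleaner than real canopies). The published field-survey accuracy tables
cannot be reproduced without the survey itself.

## Numerical and design choices

* **Soil line.** Eq.-style ratio of sums, not least squares: exact on
  noiseless collinear plots, scale-invariant under a common brightness
  factor, and robust to zero variance in B4. `estimate_soil_line()` errors
  on an empty list or zero red-band sum.
* **Emergence boundary.** Elimination is specified for WDVI *strictly below*
  the threshold, so exactly 0.005 counts as emerged. The filter applies to
  *all* scenes of a record by default — a plot bare on the current date
  (e.g. harvested bean) is equally non-crop, and the models are trained on
  standing crops only; `scenes = "lagged"` gives the stricter
  previous-scenes-only reading. Raising the threshold is monotone
  non-increasing in survivors.
* **NDVI at B8A + B4 = 0** is an error, not 0: impossible for real L2A
  reflectance, so it flags corrupt input.
* **Scene matching.** Per lag, the nearest usable date within a tolerance of
  ±5 days (one revisit period — the published matched dates drift 0-1 days),
  ties broken toward the earlier date for determinism; the combination is
  infeasible if any lag is unmatched. Classification happens only on scene
  dates — no interpolation or gap filling.
* **SVM.** `e1071::svm` (libsvm) with `gamma = 1`, `coef0 = 1`,
  `degree = 3`, i.e. the raw-inner-product kernel ((xᵀx_i)+1)³ — no kernel
  scaling; standardization (fitted on training data only) provides scaling.
  The box constraint C is not stated by the source methodology; the default
  is 1 (the common library default regime), exposed in `classifier_spec()`.
  One-vs-one aggregation is reimplemented over libsvm's pairwise decision
  values with a fixed tie-break chain: vote count, then summed decision
  values per class, then class order.
* **Bagged trees.** `randomForest` with `mtry = p` (every descriptor
  available at every split), `replace = TRUE`, 100 trees — exactly bootstrap
  aggregation of fully grown trees; only the ensemble size is specified by
  the methodology, tree controls stay at library defaults.
* **Class weighting** is off by default: the crop pattern is heavily
  unbalanced (few bean plots) and the method's characteristic weakness on
  bean is part of its behavior; `class_weights` is available as an
  extension.
* **Altman bands.** The printed bands leave (0.20, 0.21) uncovered;
  implemented as half-open intervals at 0.20/0.40/0.60/0.80 (poor ≤ 0.20 <
  regular ≤ 0.40 < moderate ≤ 0.60 < good ≤ 0.80 < particularly good ≤ 1),
  which matches all printed examples; negative values rate poor.
* **Undefined PA/UA** (empty truth row / never-predicted class) are reported
  `NA` and excluded from aggregates rather than coerced to 0.
* **Standardization of constant columns** uses sd 1 (centering only), so
  degenerate descriptors cannot produce NaNs.

## Problem sizes and runtime

The test suite and worked examples run the full design: 280 training-cycle
plots × 27 scenes and 895 test-cycle plots × 10 scenes, all four
combinations, both classifiers, and a ten-seed Monte-Carlo check of the
next-cycle timeline (evaluated on the 6 May - 20 June protocol dates, every
15 days). A complete pipeline run (`run_pipeline()`, preset scenarios)
takes well under a minute on one CPU; the whole test suite runs in about a
minute.

## Known limitations

* Accuracy levels on synthetic data exceed field levels; only structure and
  trends transfer.
* The 2020 scene calendar is a 15-day reconstruction, not the true archive.
* Visit-to-scene matching of the original survey protocol is not emulated;
  labels attach directly to scene dates, so the synthetic database has one
  record per plot per feasible date rather than the handful of visit-matched
  stages per plot of the original database.
* No GeoTIFF ingestion: zonal means are computed from pixel tables; plot
  polygons are exported to GeoJSON as fixtures only.
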