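---
title: "Methods: multi-scale decoding of evoked pain intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale decoding of evoked pain intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(painscales)
```

## The scientific question

Where in the brain is evoked pain intensity represented — in a single
region, in a resting-state network, in a distributed multisystem
configuration, or everywhere? `painscales` operationalizes this as a model
comparison: six *model spaces* constrain which voxels a linear decoder of
trial-level pain ratings may use. Three are *modular* (the decoder picks a
single best elementary region, fine resting-state network parcel, or
coarse network parcel — module choice is itself a cross-validated
hyperparameter); three are *fixed* (an a priori pain-pathways union, a
meta-analytic mask covering roughly 30% of the brain, and the full brain).
If pain information is local, the best region should decode ratings as
well as the full brain; if it is distributed, multisystem and full-brain
spaces should win. Decoding accuracy is the within-participant Pearson
correlation between cross-validated predictions and observed ratings,
Fisher-z transformed so it can be modeled with linear mixed effects across
participants and studies.

## Pipeline

1. **Ingestion** (`load_dataset`, `load_label_image`): trial-level beta
   maps as NIfTI volumes over one grid, plus a trial metadata table.
   Features are the in-mask voxel vector per trial; metadata order is
   never changed, row *i* describes volume *i*.
2. **Standardization** (`standardize_images`, `zscore_ratings`): per
   study, the study mean map is subtracted from every trial; each image is
   then rescaled to mean 0 / SD 1 across voxels, so images differ only in
   spatial configuration, not net intensity. Ratings are z-scored within
   study, preserving between-participant differences.
3. **Quartile averaging** (`quartile_collapse`): each participant's trials
   are ranked by rating (ties broken by trial order — deterministic and
   seed-free) and split into four equal-count bins, remainders to the
   lower bins; features, ratings, and covariates are averaged per bin.
   Four bins are the minimum at which every bin informs a linear intensity
   effect. Participants with fewer than four trials or constant ratings
   are excluded and logged.
4. **Decoding** (`fit_pcr`, `optimize_dims`, `select_module`,
   `nested_cv_predict`): principal component regression (PCA on
   column-centered features without column scaling — images are already
   row-standardized, and column scaling would distort voxel weighting —
   then OLS on the first k component scores, back-projected to voxel
   weights). k is chosen on 1..rank by inner CV minimizing MSE; the outer
   2 x 5 repeated CV groups rows by participant (no participant is split
   across folds) and deals participants round-robin within study, so per
   fold the study composition is balanced within one participant. Modular
   spaces add an exhaustive module selection level with its own innermost
   dimension CV (three nesting levels). Intercept-only models (k = 0) are
   precluded.
5. **Inference** (`participant_performance`, `compare_spaces`,
   `bayes_factor_null`, `calibration_check`): per-participant Fisher z
   (predictions averaged over the two repeats first; r clipped at
   1 − 1e−6 before `atanh`), then mixed models of z with planned
   orthogonal contrasts over the six spaces, Satterthwaite denominator
   degrees of freedom, and BIC-approximated Bayes factors for
   non-significant contrasts (BF01 > 10 reported as a confirmed null).
6. **Characterization**: participant-cluster bootstrap weight maps with
   the component count frozen at the full-data choice (isolating weight
   variability from hyperparameter variability), fold conjunction,
   cross-scale spatial similarity, and region-coverage permutation tests;
   within-participant mediation of experimental factors through brain
   predictions; behavioral variance wedges; and specificity tests of
   frozen decoders on labeled task-contrast maps.

## The synthetic multi-study generator

Real multi-study corpora of trial-level pain maps are large and access
restricted, so the package ships a generator (`generator_config`,
`simulate_multistudy`) whose defaults emulate the corpus structure the
pipeline was designed for: 7 training plus 4 validation studies with
heterogeneous sample sizes (16–87 participants), trial counts (16–97),
thermal intensities spanning 41.1–50 °C, and per-study factor schemas
(expectation cues, social cues, perceived control; studies that did not
manipulate a factor omit it from their schema). Ratings follow

rating = Σ_f b_f x_f + b_latent g + u_participant + ε,

with standardized factor values x_f, habituation linear in trial index,
cues sampled independently of temperature (so the sample cue–intensity
correlation shrinks with n), participant intercepts, and a latent
per-trial pain signal g that the brain expresses but the manipulated
factors do not cause — this is what lets decoders capture rating variance
beyond the experimental factors. Default coefficients (b_temp = 0.5,
b_exp = 0.25, b_social = 0.2, b_control = −0.15, b_habit = −0.2,
b_latent = 0.4, intercept SD 0.6, noise SD 0.6 on the z scale) were chosen
once so that the factor wedge decomposition and overall behavioral R²
give a realistic factor hierarchy (temperature dominating, psychological
factors smaller, participant idiosyncrasies substantial). Because
quartile averaging of many trials is strongly denoising, behavioral
R-squared on quartiled synthetic data runs higher than on real corpora
(whose ratings carry unmodeled variance the generator does not emulate).

Trial images place each factor's spatial pattern, scaled by the trial's
factor value, plus g times a pain pattern, inside scenario-defined
regions; then add parcel-correlated Gaussian noise (one shared factor per
parcel, correlation `noise_rho`, the simplest structure that makes module
selection nontrivial), a fixed per-study offset map, and a per-study
log-normal amplitude — the study heterogeneity that the standardization
stage must remove.

**Spatial scope is the ground truth.** In `LOCAL` every pattern lives in
one region; in `MULTISYSTEM` in a handful of regions spanning at least two
coarse networks (drawn from the pathway set, mirroring the a priori
hypothesis that pain pathways contain the signal); in `GLOBAL` in at least
half of all regions. Critically, each signal region expresses its own
*corrupted copy* of every signal component (x_f + `expr_noise_sd`·e):
without such region-specific expression noise, any single region would
carry essentially all decodable information and local decoders would
match full-brain decoders even under a distributed ground truth. With it,
a single region faces a reliability ceiling that integrating across
regions lifts — the defining statistical signature of a distributed
representation. Pattern norms are split across signal regions so total
signal energy is scenario-invariant.

**Calibration.** Amplitudes (`amp_pattern` = 2.4, `amp_pain` = 3.6,
`expr_noise_sd` = 2.5, `noise_rho` = 0.1, voxel noise SD 1) were fixed
once against the published performance levels the generator emulates:
full-brain within-participant Fisher z around 1–1.6 on quartiled data,
a distributed-minus-local advantage on the order of 0.3–0.5 under a
multisystem ground truth, near-equivalence of the best region and the
full brain under a local ground truth, and pain-versus-non-pain
discrimination sensitivities near 0.5–0.8 for the task-map generator
(`simulate_specificity_maps`, heat > mechanical > visceral amplitudes,
a shared salience component, and task-idiosyncratic patterns).

**What the generator does not emulate:** hemodynamics and time-series
preprocessing (generation is at the beta-map level), realistic anatomy
(regions are Voronoi blobs on a compact grid), spatial autocorrelation
beyond the parcel factor, non-linear habituation, and site-specific
sensitization. Passing tests therefore show the *pipeline* recovers known
structure under a plausible noise model, not that any particular real
dataset has that structure.

## Numerical and design choices

- **Voxel indexing** is 1-based over the flattened in-mask list (R
  convention); the mask geometry is stored with every dataset so volumes
  reconstruct exactly.
- **PCR decomposition** works on `crossprod(X)` or `tcrossprod(X)`
  depending on shape; rank tolerance is `max(n,p)·eps·d₁`. Because
  component scores are orthogonal, the inner-CV MSE for *every* k is
  computed from one decomposition per fold (cumulative per-component
  contributions), so the deterministic grid search is the default. The
  Bayesian mode (Gaussian-process surrogate on the integer range,
  expected-improvement acquisition, 30 evaluations, seeded) exists for
  workflows where each evaluation is expensive; both modes optimize the
  same objective.
- **Module-selection objective** is inner-CV MSE, the same objective used
  for dimensionality. Ties go to fewer voxels, then label order.
- **Mixed-model ladder**: z ~ contrasts + (1|participant) +
  (contrasts|study), attempted only when the study count can identify the
  slope covariance; otherwise independent (diagonal) slopes, accepted
  even at a zero-variance boundary (dropping slopes entirely would
  discard real study-by-contrast heterogeneity and inflate type-I error);
  study intercepts only as the last resort. With as few as three studies,
  slope variances are unidentifiable and analyses at that scale use
  random intercepts with participant-level degrees of freedom — reported
  as such.
- **Contrast coding**: the planned contrast matrix is completed to a full
  orthogonal basis internally, so each reported coefficient *is* the
  contrast value. The non-orthogonal FULL − REGION comparison is fit
  separately on the two spaces involved.
- **Calibration intervals** add the holdout study's within-study sampling
  variance (residual variance over its participant count) to the
  study-intercept component; the interval targets the *observed* mean of
  a new study, which would otherwise be undercovered.
- **Mediation** removes participant means from every variable and fits the
  two path models jointly over all factors; bias-corrected (not
  accelerated) percentile intervals from a participant-cluster bootstrap;
  inputs are not rescaled internally, so standardized coefficients are
  the caller's responsibility. Degrees of freedom use
  n − participants − parameters.
- **Wedge attribution** averages R² increments over all factor orderings
  (Shapley/LMG) after the participant block enters first; shares are
  nonnegative and sum exactly to the model R².
- **Cut points** minimize |sensitivity − specificity| with ties broken by
  the larger sum; Youden's J is also reported.
- **Seeding**: every randomized stage draws a named sub-seed from the
  global seed (`derive_seed`), so any stage can be re-run in isolation.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline at
reduced sizes chosen to keep a laptop-scale run practical while leaving
every qualitative property intact: scope-recovery runs use V = 2000
voxels, 20 regions, 3 studies × 30 participants × 48 trials; the
acceptance script uses V = 1200, 16 regions, 3 studies × 16 participants;
weight-map bootstraps use 500–1000 resamples (the package default is
5008) and mediation bootstraps 1000 (default 5000). The methods scale
unchanged to full-size data.

## Known limitations

- Real atlases need not nest regions within networks; only synthetic
  parcellations are nested, and no code assumes nesting.
- The region-coverage permutation test treats voxels as exchangeable
  under the null; smooth real maps violate this, making its p values
  anticonservative on strongly autocorrelated data.
- BIC-approximated Bayes factors are a large-sample approximation and are
  sensitive to pseudo-replication (deliberately so — see the tests).
- Learner-generalization inference treats studies as the sampling unit;
  with few studies its power is intrinsically low, and study-level
  conclusions from three studies should be treated as illustrative.
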