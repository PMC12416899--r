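---
title: "Cross-task decoding of preparatory attentional templates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-task decoding: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdecode)
```

## The scientific problem

When people search for a target (say, a specific face), the brain holds a
"target template" in working memory that biases sensory processing toward
template-matching input. A central question is whether this template can
contain *associated* information rather than the target itself: if each of
four faces has been paired with a scene category, does cueing a face evoke a
preparatory representation of its associated scene before any scene is shown?

`crossdecode` implements the complete analysis used to answer this question
with fMRI multivoxel pattern analysis (MVPA), plus a forward simulator that
generates data with known ground truth so every stage can be validated at
desk scale:

1. **Task designs** — a cued visual-search task (1-s face cue, 8-s blank
   delay, 0.25-s search display, 8.75-s inter-trial interval; 8 runs of 16
   trials, 12 scene-valid : 4 scene-invalid, each face cued 4 times per
   run), a face/scene 1-back task (4 runs; 4 trials per face and per scene
   category plus 6 repeat trials per run), the pre-scan associative learning
   test (108 trials), and a six-category block localizer.
2. **First-level GLMs** — canonical-HRF design matrices (search task: four
   1-s cue regressors, four 8-s delay regressors, display regressors;
   1-back: 17 regressors; localizer: six 4-s block regressors), motion
   nuisance columns, and voxelwise OLS.
3. **Cross-task decoding** — per-voxel z-scoring with training statistics,
   six pairwise linear SVMs (C = 1) trained on search-task betas and tested
   on 1-back betas under four schemes (`cue_face`, `cue_scene`,
   `delay_face`, `delay_scene`), accuracy averaged over the six pairs.
4. **Group inference** — within-run label-permutation nulls averaged across
   subjects, p = (n+1)/(N+1), Bonferroni control, and noncentral-t power
   analysis.
5. **Whole-brain mapping** — 9-mm searchlights, 4-mm FWHM smoothing,
   one-tailed group t maps against 50% chance, and threshold-free cluster
   enhancement (TFCE) with sign-flip max-statistic correction.

## The forward model

The simulator inverts the analysis GLM. For every run it builds the same
design matrix the analysis will fit and multiplies it with a true beta
matrix: a constant baseline, a uniform evoked response on task regressors,
and — in information-bearing ROIs — condition-specific Gaussian patterns.
Gaussian noise (optionally AR(1)) is added per scan.

Cross-decodability is created by *sharing* patterns across tasks: the face
pattern used for the search-cue regressor of face *f* also drives the 1-back
sample regressor of face *f*, and the scene pattern keyed by the associated
scene of face *f* drives both the search-delay regressor of *f* and the
1-back trials of that scene category. This mirrors the hypothesis under
test: a common neural code for a stimulus seen in one task and recalled (or
re-seen) in another. The association between faces and scene categories is
a bijection on {1..4} (identity by default, any permutation supported); for
scene schemes, test samples are relabeled with the face id associated with
their scene category before scoring, because classifiers are trained on
face-keyed search-task classes.

```{r forward-demo, eval = FALSE}
cfg <- sim_config(n_subjects = 4, dim = c(8, 8, 6),
                  roi_specs = list(FFA = list(center = c(3, 3, 3), radius_mm = 4),
                                   PPA = list(center = c(6, 6, 4), radius_mm = 4),
                                   CTRL = list(center = c(3, 6, 3), radius_mm = 4)),
                  information = list(FFA = "cue_face", PPA = "delay_scene"),
                  seed = 1)
report <- run_pipeline(list(sim = cfg, n_perm = 1000))
report$decoding
```

## Parameters that matter

* **Timing and counts** (TR 1.5 s, 18-s search trials, run/trial counts,
  75% scene validity) follow the study design and are the generator
  defaults; they should not normally be changed, because the regressor
  structure of the GLMs assumes them.
* **Pattern amplitude** (`amplitude`, default 0.5, in beta units) and
  **scan noise** (`noise_sd`, default 1). Under the search design the OLS
  standard error of a cue beta at unit scan noise is ~0.42 and of a delay
  beta ~0.06 (delay regressors integrate 8-s boxcars), so the default gives
  a per-voxel pattern-to-noise ratio of ~1.2 for cue patterns and ~8 for
  delay patterns — strong but not saturated single-subject decoding,
  comparable to robust category effects in ventral-stream ROIs.
* **Behavioral effect** (`dz_behav`, default 0.678): the population mean of
  the per-subject invalid-minus-valid RT difference is set to
  `dz_behav * sqrt(sd_subject^2 + sd_trial^2 * (1/n_inv + 1/n_val))`, so the
  across-subject standardized effect targets `dz_behav` exactly in
  expectation, accounting for trial-sampling noise.
* **SVM cost** C = 1 (the field's default for beta-pattern MVPA);
  normalization is per-voxel z-scoring estimated on training samples only.
* **Searchlight radius** 9 mm (123 voxels deep inside a 3-mm grid),
  smoothing 4 mm FWHM for accuracy maps (8 mm is conventional for
  univariate group maps).
* **TFCE** E = 0.5, H = 2, 26-connectivity, dh = max/100 — the literature-
  standard exponents; the integration step is fixed from the observed map so
  permuted maps are enhanced on the same scale.

## Numerical and design choices

* **HRF**: double-gamma (peak delay 6 s, undershoot delay 16 s, dispersions
  1, ratio 6, 32-s support), peak-normalized, convolved at 16× TR
  oversampling and sampled at scan onsets. "Canonical HRF" is
  underdetermined in the literature; this is the most common convention.
* **Estimation**: OLS without prewhitening keeps the forward model exactly
  invertible (noiseless simulations recover betas to ~1e-13); AR(1)
  prewhitening is available behind a flag for serially correlated noise.
* **Display regressors** are modeled with a 1-s duration although the
  display lasts 0.25 s, matching the described task GLM. The error-response
  display regressor is included only when the event table flags error
  trials; an all-zero column would make the design rank deficient, which
  `fit_glm` treats as an error rather than silently dropping columns. A
  fully-correct subject therefore has 10 search-task regressors, a subject
  with behavioral errors the full 11.
* **1-back trial counts** ("four trials per face and scene category plus
  six repeats") are interpreted *per run*, which yields balanced per-run
  chunks (4 test samples per condition from 4 runs). The 1-back inter-trial
  interval is not fixed by the task description beyond the 8-s delay; it is
  exposed as a parameter with a 9-s default so that 1-back trials have the
  same 18-s period as search trials.
* **Permutations** shuffle *training* labels within runs (preserving the
  chunk structure), re-run the full train/test chain, and pair subjects by
  iteration index; with small designs the sampled null matches the
  exhaustively enumerated one. The alternative (shuffling test labels) is a
  weaker null because it leaves the trained classifiers fixed.
* **SVM solver**: an SMO solver for the linear C-SVC (second-order
  working set, stopping tolerance 1e-3, the LIBSVM default) is compiled into the package so that the
  10,000-iteration permutation nulls and searchlight maps run in seconds;
  its solutions agree with LIBSVM to solver tolerance (tested against
  e1071). Decision-boundary ties (score exactly 0) go to the smaller
  condition id, deterministically.
* **Degenerate inputs**: zero-variance voxels are mapped to 0 by the
  normalizer (not NaN); zero-variance group accuracies flag infinite t;
  empty ROIs, rank-deficient designs and unmapped scene categories are
  errors, not warnings.
* **Functional ROIs** are the largest contiguous suprathreshold cluster
  (26-connectivity) within a search region, with a lenient-threshold
  fallback mirroring localizer practice when nothing survives the primary
  threshold. Thresholds are configuration, not constants, because the
  family-wise procedure behind localizer thresholds varies across packages.

## What the simulations do and do not show

The generator reproduces the statistical structure the analysis assumes:
exact design counts, HRF-confounded but separable cue/delay responses,
run-structured samples, cross-task shared patterns, and a calibrated
behavioral validity effect. It does **not** emulate physiological noise
spectra, motion-correlated artifacts, anatomical variability, or realistic
spatial autocorrelation of patterns (patterns are white within an ROI).
Passing tests therefore demonstrate that the pipeline is *correct* (it
recovers known ground truth, controls error rates at the nominal level, and
matches independent oracles), not that any particular real-data effect size
is expected.

Problem sizes used by the validation suite were chosen for a desktop run:
cohorts of 8 subjects on small voxel grids, 500–1,000 permutation
iterations, 200 null cohorts for the type-I calibration, and 20 seeds for
the double-dissociation recovery check.

## Known limitations

* OLS ignores serial correlation unless AR(1) prewhitening is requested;
  permutation inference is unaffected, but parametric single-run t values
  are optimistic on strongly autocorrelated noise.
* The searchlight recomputes normalization per sphere (as it must to avoid
  leakage), so accuracies of overlapping spheres are correlated; map-level
  inference relies on the sign-flip TFCE correction, not on voxelwise
  independence.
* Scene-category exemplar effects are not modeled: all exemplars of a
  category share one pattern.
* The pipeline analyzes beta patterns (one per run and condition), not
  trialwise estimates; designs with many fewer runs than conditions will
  starve the classifiers.
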