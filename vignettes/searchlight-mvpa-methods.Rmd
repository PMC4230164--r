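---
title: "Searchlight MVPA for block-design fMRI: models, simulator, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight MVPA for block-design fMRI: models, simulator, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`searchlightr` implements a complete decoding pipeline for blocked-design
fMRI: per-run GLM estimation of condition responses, whole-brain spherical
searchlight classification with a linear support-vector machine and
leave-one-run-out cross-validation, permutation-based group inference on the
resulting accuracy maps, and a mass-univariate comparison arm. Because
cohorts of this kind (two participant groups — here 10 controls and 7
congenital-prosopagnosia (CP) subjects — viewing faces, objects, bodies and
body parts in 16-s blocks) are rarely publicly available, the package ships
a synthetic-cohort generator with known informative regions, so every stage
of the pipeline can be validated against ground truth.

This vignette explains the models and the choices behind them. It states no
empirical numbers beyond what the package's tests and acceptance script
themselves compute.

# The single-subject model

## Signal

Each voxel's time course in run $r$ is modeled and simulated as

$$ y(t) = \beta_0 + \sum_c w_c \,(b_{c,r} \ast h)(t) + d(t) + \varepsilon(t), $$

where $b_{c,r}$ is the 0/1 boxcar of category $c$'s blocks in run $r$, $h$
is the canonical haemodynamic response function, $w_c$ the voxel's response
amplitude to category $c$, $d$ a slow drift and $\varepsilon$ temporally
autocorrelated noise.

The canonical HRF is the standard double-gamma form

$$ h(t) = g(t;\,6,\,1) - \tfrac{1}{6}\, g(t;\,16,\,1), $$

with $g$ the gamma density, truncated at 32 s: a positive lobe peaking near
5 s and a late undershoot near 16 s with one sixth the mass. All five
parameters are exposed in `hrf_params()`; the defaults are the de-facto
canonical parameterization. Convolution is carried out on a 0.1-s grid and
sampled at scan acquisition times (TR = 3 s by default), scaled by the grid
step so a sustained block plateaus near the HRF integral ($1 - 1/6$).

## Design

`make_design()` lays out 8 runs of 112 volumes (336 s). Each run holds one
16-s block per category (so 32 stimulus blocks per session), each preceded
by a 16-s fixation block, with a fixation block closing the sequence;
remaining run time is rest. Within-run category order rotates Latin-square
fashion across runs, with runs beyond one full rotation using the reversed
category list, so none of the 8 runs shares an order — a deterministic
surrogate for counterbalancing. Individual 500-ms stimulus presentations
inside a block are not simulated: the GLM models whole blocks, so
block-level simulation matches the estimation granularity exactly.

The acquisition timing deserves a note: the emulated protocol's stated run
length, volume count and TR are mutually inconsistent (114 volumes at TR
3 s is 342 s, not 336 s). The simulator prioritizes internal consistency —
run length is defined as `n_volumes_per_run * tr_s`, defaulting to
112 × 3 s = 336 s — and leaves both knobs configurable. Likewise, "32
blocks" is read as 32 stimulus blocks per session (4 per run); the
per-run reading is available through `blocks_per_category`.

## Estimation

`fit_glm()` is voxelwise ordinary least squares with one regressor per
(category, run) and one constant per run. Before fitting, a discrete-cosine
high-pass projection (`dct_highpass_project()`, cutoff 128 s) is applied to
the data *and* the condition regressors; this residualization is identical
to including the cosine basis as confounds, and since the projection removes
the constant, each run reduces to a fit of its filtered condition
regressors. Fixation is deliberately unmodeled, so betas are relative to the
fixation baseline. The result is 8 beta maps per category — the searchlight's
input vectors.

Smoothing (`gaussian_smooth()`) is separable Gaussian convolution with
$\sigma = \mathrm{FWHM} / \sqrt{8 \ln 2}$ per axis in voxel units and
reflective boundaries (which preserve the volume mean exactly). The emulated
analysis smooths once at preprocessing (4 mm FWHM) and describes the MVPA
inputs as "additionally" smoothed by 4 mm; because the two readings differ
materially (effective $\sqrt{32} \approx 5.7$ mm), the pipeline applies a
single configurable 4-mm pass by default and exposes `smooth_passes = 2` for
the double-smoothing reading.

No prewhitening is applied: the emulated analysis does not state its
autocorrelation handling for these estimates, and OLS is unbiased under
AR(1) noise; only efficiency, not calibration, is affected.

# The searchlight

For every voxel inside the analysis mask, `searchlight_map()` gathers all
voxels within a 10-mm-radius sphere (anisotropic voxel sizes respected:
offsets are included when their *physical* displacement is within the
radius), intersected with the mask. The 16 beta patterns (2 categories × 8
runs) restricted to the sphere form the feature vectors — every voxel
contributes, no feature selection, no scaling by default (an optional
per-fold z-scoring flag exists for sensitivity analyses). A soft-margin
linear SVM (cost C = 1, the common default; configurable) is trained on 7
runs and tested on the held-out run's two patterns, for all 8 folds; the
mean accuracy is assigned to the center voxel. Spheres truncated by the mask
edge keep their in-mask voxels; centers retaining fewer than
`min_sphere_voxels` (default 2) are NA.

The inner solver is a compiled C-support-vector classifier operating on the
sphere's precomputed Gram matrix (sequential minimal optimization with
maximal-violating-pair selection, convergence tolerance $10^{-8}$). With 14
training vectors per fold the dual problem is tiny and the solution exact;
the test suite cross-checks decisions against the reference libsvm
implementation (via `e1071`) on randomized problems and verifies the whole
map against a naive triple-loop implementation. A test pattern falling
exactly on the decision boundary is assigned to the lexicographically first
category — a deterministic convention for a measure-zero event. The map is
computed independently per center voxel, so results do not depend on
traversal order.

Because the synthetic cohort lives in a common space, the spatial
normalization the original analysis applied to accuracy maps before group
statistics is the identity here; no additional smoothing is applied to
accuracy maps.

# Group inference

`one_sample_t_map()` compares accuracy maps to the two-class chance level
(50%); `two_sample_t_map()` compares groups (controls minus CPs), pooled by
default for the decoding arm — matching the df = 10 + 7 − 2 = 15 behind the
display threshold $t > 3.73$, i.e. `critical_t(0.001, 15)` — and
Welch-corrected for the univariate arm, whose source analysis specifies
unequal variances. Zero-variance voxels become NA and are counted, never
silent infinities.

Familywise and cluster-level correction is by permutation
(`permutation_correct()`): sign flipping around the null value for one-sample
tests, group-label shuffling for two-sample tests. Each permutation's
maximum statistic (voxel-level FWE) and maximum supra-threshold cluster
extent (cluster-level FWE, cluster-forming threshold $p = 0.001$ one-sided
by default, 18-connectivity) build the empirical null; corrected p-values
are $(1 + \#\{\text{perm} \ge \text{observed}\}) / (1 + n_\text{perm})$
with the identity permutation always included. The original analysis used
random-field-theory corrections; those thresholds depend on smoothness
estimates of the undeposited data and are not reproducible, whereas
permutation correction is assumption-free and its calibration is itself
verified in the test suite (empirical FWE over 200 null cohorts). One-sided
tests follow the directional hypotheses (accuracy above chance; controls
above CPs); both tails are configurable.

# The synthetic cohort and what it does (not) show

`make_ground_truth()` implants three spherical informative regions (5-mm
radius; occipital-, fusiform- and anterior-temporal-like placements) inside
an ellipsoidal brain mask on a 24 × 28 × 16 grid of 1.4 × 1.4 × 2.0 mm
voxels — a desk-scale stand-in for the acquisition slab; all sizes are
configurable. Within each region, every category evokes
`mean_amplitude + pattern`, the pattern being a Gaussian weight map
mean-centered across the region's voxels. Centering enforces
*mean-amplitude matching*: all categories (and both groups) share the same
regional mean response, so amplitude-based analyses carry no category or
group signal by construction, while multivoxel patterns differ.

The CP group effect is a separability deficit: face and object patterns are
shrunk toward their common mean by `cp_separability_factor` (default 0.3;
1 = no effect, 0 = identical face/object patterns). Other pairs are
untouched, mirroring the emulated finding of a face-object-specific
reduction. A `cp_amplitude_factor` knob (default 1) can instead implant a
face-selective amplitude deficit — the kind of effect the univariate arm
*does* detect — as a positive control.

Pattern layouts are drawn per subject by default, seeded from the subject
seed: the regions and the separability structure are shared, the voxel-level
arrangement is not. This models the between-subject variability of pattern
topography in real cohorts and has an important consequence: the voxelwise
univariate group contrast is zero in expectation, not merely its regional
mean. With a cohort-shared template (`subject_specific = FALSE`), the fixed
face-minus-object pattern map itself becomes a per-voxel group effect of
size $(1 - f)\,d(v)$, and the univariate arm's blindness then depends on a
knife-edge noise regime rather than on the design — the shared-template mode
is retained for completeness but is not the default.

Noise is white Gaussian (`white_sd`, default 1.2 against a block response
amplitude of 1 — roughly 1% signal change on the baseline of 100), passed
through an AR(1) filter (coefficient 0.3) for realistic temporal
autocorrelation, plus slow drift: per voxel and run, random coefficients on
cosine components with periods of 160 s and longer (temporal standard
deviation `drift_amplitude`, default 1). Drift is deliberately confined to
the band a 128-s high-pass filter removes; drift constructed outside that
span (e.g. an arbitrary-phase run-length cosine) leaks boundary energy into
the pass band, and the structured residuals measurably bias null decoding
accuracy above chance — a useful demonstration that the calibration tests
exist for a reason. Defaults were chosen once so that control subjects
decode face-vs-object well above chance but below ceiling, the regime in
which a group difference in decodability is expressible; they are the
package's definition of "moderate noise".

What passing tests show: the estimator recovers implanted responses exactly
in the noiseless limit; the decoder is calibrated at chance on null data and
monotone in implanted pattern strength; permutation inference controls FWE;
and on default cohorts the multivariate path detects the mean-matched group
effect while the univariate path does not. What they do not show: robustness
to head motion, susceptibility dropout, anatomical misalignment across
subjects, physiological noise, or any nonlinearity of real BOLD responses —
none of which are simulated.

# Numerical choices and degenerate inputs

* DCT drift basis: component $k$ over $n$ scans has period $2nT/k$;
  components with period above the cutoff (plus the constant) are removed.
  Cutoffs at or below $2\,T_R$ are rejected.
* Smoothing kernels are truncated at $4\sigma$ and renormalized; FWHM 0 is
  the identity.
* The SMO solver caps at $10^5$ iterations (never approached at these
  problem sizes); the unbounded-pair safeguard treats quadratic coefficients
  below $10^{-12}$ as degenerate.
* Rank-deficient designs abort with the offending columns named. Empty
  masks, empty regions, sub-2-run cross-validation and non-finite features
  are errors, not warnings.
* Cluster extraction on an everywhere-subthreshold map returns an empty
  table; corner-touching voxels merge under 26- but not 6- or
  18-connectivity.
* Per-subject seeds are derived as `cohort_seed * 1000 + subject_index`
  (pattern draws offset by a constant), keeping every derived seed well
  below $2^{31}$.

# Problem sizes used by the test and acceptance suites

The suites were sized for a single CPU: the chance-level calibration runs 17
null subjects at the full default grid; oracle-equivalence comparisons use a
6 × 6 × 4 grid; FWE calibration uses 200 null cohorts of 14 subject maps on
an 8 × 8 × 5 grid with 199 permutations; and the recovery experiment runs 10
cohorts (10 + 7 subjects, 8 runs) on a 14 × 14 × 10 grid with a 6-mm
searchlight. These reduced grids preserve every structural property of the
full-size analysis (anisotropic voxels, sphere truncation, fold structure,
permutation schemes).

# Known limitations

Single-subject FWE for the univariate arm uses an exact sign-flip null over
runs (256 patterns at 8 runs) and falls back to Bonferroni below 6 runs,
where the max-statistic null is too coarse. The Welch two-sample permutation
test uses the map-median Welch df for its cluster-forming threshold. The
pipeline does not implement random-field-theory thresholds, TFCE, nonlinear
kernels, feature selection, or anatomical cluster labeling, and it has not
been validated against SPM's prewhitened estimates.
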