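---
title: "Methods: connectivity, graph metrics and stability selection in strokefc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity, graph metrics and stability selection in strokefc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokefc)
```

`strokefc` implements a resting-state functional-connectivity analysis of
lower-limb performance after stroke: an edgewise ROI-to-ROI screen under
false-discovery-rate control, threshold-free nodal graph metrics, and a
repeated elastic-net feature-selection stage, with a corticospinal-tract
lesion-load covariate and a synthetic-cohort generator that plants known
ground truth. This vignette explains the model behind each stage, the
tunable parameters and why their defaults are what they are, the numerical
choices, and what the package's validation does and does not demonstrate.

## Networks and hemispheric standardisation

Three ROI sets are built in: the cortical sensorimotor network (12 ROIs:
M1, SMA, premotor, S1, superior parietal lobule and precuneus in each
hemisphere), the full SMN (adding VL/VA/VP thalamus, posterior putamen and
two cerebellar ROIs per hemisphere, 24 in all) and the default mode network
(14 ROIs). Every ROI is tagged ipsilesional (`Ip`) or contralesional (`C`)
and paired with its contralateral homologue. Subjects whose lesion is in
the left hemisphere are standardised so the lesioned side is always
"ipsilesional": because the package operates after ROI extraction, this is
implemented as the homologue permutation of matrix rows and columns
(`flip_hemispheres()`), which is exactly equivalent to voxel-space
left-right flipping at the ROI level and is an involution — applying it
twice is the identity, a property the test suite checks.

## Denoising

The denoising chain runs in a fixed order: outlier detection, confound
regression, band-pass filtering, scrubbing.

* **Outlier frames**: a frame is flagged when framewise displacement
  exceeds 0.9 mm or the global signal deviates from its mean by more than
  5 standard deviations. Both thresholds are configurable
  (`fc_config()$fd_threshold_mm`, `$gs_sd_threshold`).
* **Confound regression**: every ROI series is replaced by the residual of
  an OLS fit on an intercept plus the subject's nuisance regressors
  (white-matter/CSF signals, motion parameters). Rank-deficient confound
  sets are reduced via the QR pivot with a warning. Regression is
  idempotent up to numerical noise.
* **Band-pass**: zero-phase filtering in the frequency domain — the DFT of
  each series is masked to `0.008–0.09 Hz` and inverted. A hard spectral
  mask was chosen because no filter family is prescribed for this analysis;
  it gives an exact pass-band (retained sinusoids keep > 90% amplitude by
  construction) at the cost of possible ringing near sharp transients,
  which matters little after outlier frames are removed. The upper default
  is 0.09 Hz: with TR = 3 s the Nyquist frequency is 1/6 Hz, so a cut-off
  of 0.9 Hz — sometimes quoted for this kind of denoising — is physically
  unreachable; 0.008–0.09 Hz is the standard resting-state band. Both edges
  are configurable and the filter refuses bands beyond Nyquist, citing the
  TR.
* **Scrubbing** deletes flagged frames outright (no interpolation), so all
  downstream correlations are computed over clean frames only. Subjects
  with more than half their frames flagged are unusable; `run_pipeline()`
  drops and logs them.

## Edgewise screen

For each ROI pair the package regresses the subjects' Fisher-z connectivity
on the clinical measure and reports the slope *t* and its two-sided *p*
(complete cases; edges with fewer than 4 observations are skipped). The
slope *t* of a simple regression equals the correlation *t*, so the
implementation computes it via the identity `t = r sqrt((n-2)/(1-r^2))`;
the tests verify exact agreement with `lm()`. Which variable is response
and which predictor does not affect *t* or *p*. No covariates enter the
model. *p* values are adjusted by Benjamini–Hochberg step-up within one
network × one measure family, with significance at adjusted p < 0.05, and
*t* scores are sign-adjusted (negated for GAIT and TUG, where lower scores
are better) so a positive value always means better function with higher
connectivity.

The asymmetry index for bilateral sensory measures is
`(unaffected − affected) / (unaffected + affected)`; negative values mean
greater impairment on the affected side. A zero denominator yields a
missing value with a warning.

## Graph metrics over a threshold sweep

The per-subject Pearson matrix is binarized at each threshold of the grid
τ = 0.15, 0.16, …, 0.50 with a strict `r > τ` rule — negative correlations
never create edges — and three nodal metrics are computed from scratch at
each τ:

* **Global efficiency**: `GE(i) = mean_{j≠i} 1/d(i,j)` with hop-count
  distances from breadth-first search and `1/∞ = 0` for unreachable nodes.
* **Clustering coefficient**: `CC(i) = 2 e_i / (k_i (k_i − 1))`, defined as
  0 for degree < 2.
* **Betweenness centrality**: fractional shortest-path counting (Brandes'
  dependency accumulation), disconnected pairs skipped, normalised by
  `(n−1)(n−2)/2` so the value is a proportion in [0, 1].

Thresholding is applied to *r* rather than Fisher *z* (the binarization
rule concerns the correlation scale; both are monotone so only the grid
values differ), and each metric-versus-τ curve is reduced to its
trapezoidal AUC, a scalar independent of any single threshold choice. The
grid bounds reflect the usual working range for such matrices: below 0.15
the graphs are near-complete-to-unstable, above 0.5 too sparse; both
bounds and the step are configurable. The implementation is validated two
ways — exact agreement with an independent reference (igraph) on ~1000
random graphs of up to 7 nodes, and for betweenness also against explicit
enumeration of every shortest path.

## Outcome preparation and stability selection

Each outcome passes a Shapiro–Wilk gate: if p < 0.05, it is Box-Cox
transformed at the λ maximising the profile log-likelihood
`-n/2·log σ̂²(λ) + (λ−1)Σ log y` (non-positive outcomes are shifted by
`-min(y)` plus 0.1% of the range first; the shift and λ are recorded).
The λ = 0 branch is the logarithm; the optimiser searches [−2, 3].

The elastic net relates the subjects × ROI AUC features of one metric (GE,
CC and BC are fitted as three separate models per outcome) to the prepared
outcome. Tuning follows a 100-candidate grid — 10 mixing values α linearly
spaced on [0.05, 1] crossed with 10 penalties λ log-spaced on
[0.0002, 0.36]; λ is log-spaced because its range spans three decades. Each
candidate is scored by 5-fold cross-validated RMSE (pooled over folds), the
minimising pair is refit on the full data, and coefficients are reported on
the standardised-feature scale so magnitudes are comparable across ROIs.
The whole fit is repeated 20 times with freshly drawn fold assignments
(repeat r seeds the fold draw with `base_seed + r`; this is the only
repeat-level randomness). A feature counts as "associated" in a repeat when
its coefficient in that repeat's chosen model is nonzero; features
associated in at least 90% of repeats (≥ 18 of 20) form the
strong-association set. Mean coefficients are averaged over the repeats in
which the feature was selected, ranked proportionally with the largest
|mean β| assigned 100%, and signed by the simple Pearson correlation
between the raw feature and the raw (pre-transform) outcome.

### A known limitation of fold-reshuffle stability selection

Because the 20 repeats reshuffle cross-validation folds but never resample
subjects, any feature whose sample correlation with the outcome is large —
whether causally or by chance in that particular sample — tends to be
selected in *every* repeat. At the study dimensions (n = 37 subjects, 24
features) the expected maximum absolute null correlation across features is
roughly 0.4, which is comparable to the strongest penalty on the tuning
grid, so a lucky noise feature can pass the 90% rule. The package's
simulations quantify this: the procedure is highly sensitive to genuine
effects, but its per-dataset false-selection behaviour is materially more
liberal than a subject-resampling (subsampling/bootstrap) stability scheme
would be. The fold-reshuffle design is retained because it is the procedure
this analysis stack defines; users wanting conservative selection should
treat the strong set as a ranking device, not an error-controlled
discovery set.

## Lesion load

The corticospinal-tract lesion load counts lesion ∩ CST voxels per axial
slice, weights each slice by `max_slice_area / slice_area` — the simplest
weighting that up-weights narrow tract portions, where a lesion of given
volume severs proportionally more of the tract — and sums. The weight
function is an argument (`weight_fn`) so alternative slice weightings can
be substituted; lesion voxels outside the tract never change the value,
and masks are accepted as binary arrays or NIfTI files (assumed
co-registered; registration is out of scope).

## The synthetic-cohort generator

`simulate_cohort()` draws each subject's ROI series from a multivariate
normal whose correlation matrix is a base matrix (default: exchangeable
with off-diagonal 0.2, a typical within-network resting-state level)
shifted on the Fisher-z scale at every planted location by an independent
standard-normal latent trait scaled by `edge_modulation` (default 0.3,
roughly the between-subject SD of edge z values seen in small cohorts).
Latent-trait modulation — rather than resampling a fixed matrix — is what
makes edge z values genuinely covary with the clinical score, matching the
regression the pipeline runs. Node-level plants shift a node's whole row
jointly so its GE/CC/BC move predictably. The target clinical measure is
the effect-weighted sum of the subject's *true* planted quantities (edge z
values; for node plants, the threshold-AUC metrics of the true correlation
matrix) plus Gaussian noise; lower-is-better measures (GAIT, TUG) receive
the negated latent score. Remaining measures are independent noise at
cohort-realistic means and SDs. Motion traces have |N(0.2, 0.05)| mm
baseline FD with spikes > 0.9 mm injected at a configurable rate, and
spike frames receive large artifacts in all ROIs simultaneously. Matrices
that fail a positive-definiteness check after planting are rejected with a
diagnostic naming the offending plant.

What the generator does *not* emulate: hemodynamic response, spatial
smoothness or anatomically realistic lesion geometry, autocorrelated BOLD
noise, scanner differences, or heterogeneous covariance structure across
subjects beyond the planted modulation. Passing tests therefore demonstrate
that the statistical machinery recovers what it claims under a known,
well-behaved generative model — not that it is robust to every property of
real fMRI.

## Problem sizes and determinism

The validation suite runs at the study's own dimensions where that is
informative — 37-subject cohorts on the 24-ROI network for FDR calibration
(200 null replicates), planted-edge recovery (100 replicates), and the
elastic-net operating characteristics (50 replicates of the full 20-repeat
procedure) — and at reduced sizes elsewhere (8–15 subjects, the 12-ROI
cortical set) where the property under test does not depend on scale.
All randomness flows through explicit seeds: identical configurations
reproduce cohorts, fits and result tables bit-for-bit, which the suite
asserts end-to-end.

## Degenerate inputs and tie-breaks

Zero-variance ROIs produce missing correlations (with a warning) and are
excluded downstream; correlations at ±1 are clipped to 1 − 1e-7 before
`atanh`; equal CV RMSEs are broken toward the first grid candidate in
(α ascending, λ descending) order; a zero Pearson correlation reports
direction 0; empty strong sets yield an empty ranking; Box-Cox refuses
constant data, and `prepare_outcome()` requires at least 3 non-missing
values (Shapiro–Wilk itself requires 3–5000).
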