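---
title: "Voxel-based encoding models and identification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based encoding models and identification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A voxel-based encoding model (VBEM) asks whether the response of a single
fMRI voxel can be written as a linear function of stimulus features. For a
set of `p` stimuli with feature vectors collected in a design matrix `X`
(`p × q`), each voxel `v` is modelled as

    y_v = X h_v + c_v + n,

where `h_v` is the voxel's kernel over the `q` input channels, `c_v` a
constant, and `n` noise. Fitted across all voxels of a target region (early
retinotopic cortex, V1/V2/V3), the model predicts a full multi-voxel
activity pattern for any new image. Prediction quality is scored by
*identification*: correlate each predicted pattern with each observed test
pattern, and ask for every observed pattern whether its own prediction is
its best match.

The same machinery runs with a different design matrix. When `X` holds
another region's voxel activity patterns (e.g. the lateral occipital
complex, LOC) instead of image features, the fit is an *analogical* encoding
model (AVBEM) that maps one region's activity to another's. No code path in
`voxelenc` distinguishes the two cases, which is the point: feature spaces
and brain regions are interchangeable input channels. Averaging the
predictions of the stimulus model and the region-to-region model tests
whether the two carry complementary information.

## Gabor features

`gabor_pyramid()` builds the feature dictionary: at each spatial frequency
of `n` cycles per field of view, wavelets tile the image on an `n × n` grid
and occur at eight orientations; a luminance-only channel is prepended. The
default six frequencies (1–32 cycles/FOV) on 128 px images give
`(1 + 4 + 16 + 64 + 256 + 1024) × 8 + 1 = 10921` channels.
`gabor_features()` maps each image through every wavelet's quadrature pair
and returns `log(1 + magnitude)` per channel.

Parameter choices the dictionary definition leaves open, and how this
package fixes them:

* **Envelope width.** The Gaussian envelope s.d. follows the standard
  half-amplitude bandwidth relation
  `sigma = lambda * sqrt(ln 2 / 2) / pi * (2^b + 1)/(2^b - 1)` with carrier
  period `lambda` and `b = bandwidth_octaves` (default 1 octave, i.e.
  `sigma ≈ 0.56 lambda`). The bandwidth is exposed in `gabor_pyramid()`.
* **Quadrature magnitude.** "Log of the magnitude" is read as the complex
  (quadrature) magnitude `sqrt(e² + o²)` of the cosine/sine filter pair,
  which is phase-invariant; the magnitude of a single phase would depend on
  stimulus alignment.
* **Log offset.** The log is taken as `log(1 + m)`: monotone, zero at zero
  magnitude, and non-negative for all inputs.
* **DC correction.** At 1-octave bandwidth the envelopes of border-cell
  wavelets are clipped by the image canvas, which leaves a spurious DC
  component in the truncated filters. Both quadrature components are
  therefore rendered zero-mean. This changes no feature value — images are
  mean-centered before band-pass filtering — but restores the analytic
  zero-sum property of the odd-phase filter exactly. Quadrature
  orthogonality, similarly, is exact only for wavelets whose envelope fits
  the canvas; border-cell pairs deviate by a few percent, inherently.
* **Normalization.** Pixel values are used as given and are expected on a
  common `[0, 1]` scale, which the PNG loader and the synthetic generator
  produce. Featurization deliberately does *not* rescale per image: that
  would erase contrast differences between stimuli. Each image is
  mean-centered for the band-pass channels; the luminance channel sees the
  raw image through a uniform unit-sum filter.
* **Geometry.** Grid cell centers sit at `(i + 0.5)/n` of the image extent,
  row-major, 0-based; orientation is measured counterclockwise from
  horizontal; filters are rendered on the full canvas without cropping.

## The estimator

`fit_voxel()`/`fit_encoding()` estimate each kernel by full-batch gradient
descent on the summed squared error, from a zero kernel, with early stopping
and bootstrap averaging:

1. Channels are z-scored using all training rows (one set of statistics per
   model, stored for prediction). Without this, no single learning rate
   suits thousands of channels with heterogeneous scales.
2. A *stopping set* (20% of rows by default) is drawn once per voxel and
   excluded from every gradient computation.
3. For each of `n_bootstrap` rounds (default 10), the remaining rows are
   resampled with replacement and descent runs at a fixed learning rate
   (default 1e-4). Every `eval_every` iterations the stopping-set MSE is
   evaluated; the best snapshot is kept and descent halts after `patience`
   non-improving evaluations.
4. Kernels and intercepts are averaged across rounds.

Early-stopped descent from zero shrinks coefficient magnitudes — the
regularization that makes the fit usable when channels outnumber stimuli.
The intercept is initialised at the bootstrap-sample mean (the kernel at
zero, as the shrinkage argument requires); a zero-variance response
short-circuits to a flagged degenerate fit rather than an error.

Numerical notes. The loss is the *sum* (not mean) of squared errors, so the
stable step size scales as `2 / lambda_max(X'X)`; the default 1e-4 on
standardized channels is safe up to a few thousand stimuli, and should be
reduced for much larger designs. If the stopping error diverges the round
keeps its best (possibly initial) snapshot rather than failing. Every
stochastic choice — the stopping-set draw and bootstrap indices — is a
deterministic function of the control seed and the voxel index, so refits
are bit-identical; the stopping set is drawn once per voxel, not per round,
keeping the stopping criterion stable across rounds. Whether to draw it per
round instead is genuinely open; per-voxel was chosen for that stability.

One estimator property worth knowing: against a *full* descent run to the
iteration cap, early stopping wins in the regime image features occupy
(correlated channels, decaying covariance spectrum). Under a purely
isotropic random design, interpolating descent is benign and the comparison
is uninformative; the test suite exercises the correlated case.

## Identification

`pattern_correlation()` forms the `P × P` matrix of Pearson correlations
across voxels, element `(n, m)` pairing the predicted pattern of image `n`
with the observed pattern of image `m`. `identify_patterns()` scores column
`m` as correct when the diagonal element is the *strict* maximum of the
column — ties count as incorrect, a conservative, deterministic convention.
Accuracy is stored as an exact fraction and displayed as a one-decimal
percentage. Zero-variance (flat) patterns yield correlation 0 with a
warning, never an exception mid-pipeline. `identify_by_roi()` repeats the
procedure within voxel subsets; a single-voxel region is reported as
undefined, since a Pearson pattern correlation needs two voxels.

`combine_predictions()` averages two predicted patterns elementwise
(weight 0.5 by default, the plain average). An optional per-voxel z-scoring
switch exists for models predicting on different scales, but is off by
default to keep the plain average; whether the original procedure
standardized before averaging is not established, and raw averaging is the
fidelity-preserving default.

## The synthetic data generator

`synthetic_study()` simulates the statistical structure the analysis
assumes, so the full pipeline is testable without any neuroimaging data:

* **Stimuli** are 1/f-spectrum (pink) noise images — matching the
  second-order statistics of natural scenes — or sums of random wavelets.
* **Target-region voxels** follow the forward model exactly: a sparse,
  spatially localized kernel (one neighborhood × 1–2 orientations × 2
  adjacent frequency bands, ~1% of channels) applied to the features, plus
  an optional latent stimulus-driven component that is *not* a linear
  function of the features, plus i.i.d. Gaussian noise scaled to a requested
  per-voxel SNR. Test responses average 13 independent noise repeats,
  mirroring repeated test presentations.
* **Source-region voxels** are sparse random mixtures of the target
  region's *noise-free* signals plus independent noise: a linear mapping
  back to the target region exists but is noisy — exactly the premise of the
  analogical model — and what the regions share is stimulus-driven variance,
  never measurement noise.
* **ROI labels** ("V1"/"V2"/"V3") are assigned by each kernel's dominant
  frequency band (high to low).

Reference conditions. The package's desk-scale reference simulation uses
800 training and 60 test stimuli at 128 px, frequencies 1–8 (681 channels),
60 target voxels, SNR 2, 13 test repeats, and a latent fraction of 0.3 —
a scaled-down stand-in for the full study design (1750/120 stimuli, 10921
channels, hundreds of voxels), sized so that a full run fits in minutes on
one CPU. SNR defaults are the package's own calibration, chosen so
accuracies land between chance and ceiling; no empirical noise estimates
exist to import. At these conditions the stimulus model identifies 80–90%
of test images (chance 1.7%).

Two experiment-specific calibrations, fixed once:

* **Shared-signal experiment** (does combining help?): 300/60 stimuli,
  frequencies 1–4, 40 target and 30 source voxels, source SNR 0.7, 3 test
  repeats. At the reference source SNR of 2 the region-to-region model sits
  at ceiling and averaging cannot show an advantage; lowering the source
  region's effective SNR (consistent with the weaker stimulus-locked
  reliability of higher-order areas) puts all three models mid-range, where
  the combination's advantage is visible (roughly 83% / 70% / 95% for
  stimulus, region, and combined models).
* **Sub-region gradient experiment**: source mixing biased toward
  low-frequency target voxels (`freq_bias = 2`) and a per-band SNR gradient
  (`roi_snr_gradient = 1.5`, high-frequency band 2.5× the low band). A
  V1-to-V3 gradient of the stimulus model does not emerge from the linear
  model alone — in cortex it is physiological — so the generator builds it
  in; the biased mixing then reverses the gradient for the region model.
  Over three seeds the band *endpoints* separate reliably (stimulus model
  better in V1 than V3, region model the reverse); the middle band sits
  within simulation noise at this scale, so qualitative checks target the
  endpoint contrast.

What the generator does **not** emulate: haemodynamics and temporal
autocorrelation (responses are per-stimulus amplitudes, as in deconvolved
data), retinotopic cortical geometry, eccentricity-dependent receptive-field
size, voxel-to-voxel noise correlations, and non-linearities beyond the
compressive log of the feature stage. Passing tests therefore demonstrate
that the estimation and scoring machinery behaves correctly under the
model's own assumptions — not that real cortex satisfies them.

## Parameter recovery, and what "the kernel" means

Recovery of generating kernels is measured in the estimator's
*standardized* channel space (true kernel times channel s.d.), where
early-stopping shrinkage is isotropic; in raw channel units the shrinkage is
anisotropic and correlations are systematically lower without being more
informative. Recovery simulations run on the pure forward model (latent
fraction 0): a latent component is structured noise for the stimulus model
and would confound the measurement. With pink-noise stimuli the feature
matrix is strongly collinear, so kernels are identified only up to the
feature covariance's effective rank — mean standardized-space correlations
around 0.7 at reference scale coexist with excellent identification
accuracy, and both facts are expected.

## File formats

Matrices (features, responses, predictions, kernels) travel as
full-precision CSV (`%.17g`, exact double round-trip) with an `id` column;
ROIs, configurations, results, and run logs as JSON; stimuli as PNG
directories in lexicographic order, or generated in memory. Pipeline runs
stamp every artifact directory with the seed, an MD5 of the serialized
configuration, and per-stage wall times; rerunning a configuration
reproduces every artifact bit-exactly.

## Known limitations

* The fixed learning rate requires attention for designs much larger than
  the reference scale (see the stability note above); there is no automatic
  step-size selection.
* Kernels of near-silent channels (zero training variance) are held at zero
  by construction but such channels are not pruned.
* The identification score is the strict column-maximum rule only; rank- or
  set-size-based scores are out of scope.
* The generator's i.i.d. noise makes test-repeat averaging exactly
  `sqrt(k)`-efficient, which is optimistic for real repeated measurements.
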