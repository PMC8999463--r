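---
title: "Methods: photometric-stereo hyperspectral skin-lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometric-stereo hyperspectral skin-lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hand-held hyperspectral imagers can separate skin-lesion classes by their
diffuse reflectance spectra, which are shaped by tissue chromophores
(melanin, haemoglobin) across the visible and near-infrared range. A
photometric-stereo variant of such an imager additionally captures each
waveband under three known illumination directions, so that per-band albedo
(illumination-corrected reflectance) and a skin-surface height model can be
reconstructed before classification. `hsiderm` implements that full analysis
chain — reflectance calibration, per-band Lambertian photometric stereo,
Fourier depth integration, machine-learning pre-processing, a dual-branch
3D/2D convolutional network, and lesion-level majority voting — together
with a synthetic capture generator, because the clinical captures behind the
original study are not publicly available. Every stage is therefore testable
end to end with known ground truth.

## Forward model and its inversion

A capture consists of 33 wavebands (477–891 nm) split into VIS and VNIR
channel groups, each acquired under three light directions, plus dark and
white reference frames. The renderer uses the Lambertian model

    counts = dark + (white - dark) * albedo_b * max(0, n . l) * fov + noise,

with unit surface normals `n` derived from the phantom height field and unit
light vectors `l`. Reflectance calibration is the standard flat-field ratio
`R = (raw - dark) / (white - dark)`; white frames are rendered as full-signal
flat-field references so that `R = albedo * (n . l)` exactly. Pixels whose
white reference does not exceed the dark level (outside the light-protection
cone) are flagged invalid.

Per band, photometric stereo solves `I = rho (n . l)` for the three lights:
`g = L^-1 I`, `rho = |g|`, `n = g / |g|`. Pixels with any non-positive
intensity, vanishing `|g|`, or downward normal are shadow-flagged and receive
the explicit degenerate values `rho = 0`, `n = (0, 0, 1)` rather than silent
NaNs; albedo is clipped to `[0, 1]`.

### Depth integration

Depth is recovered per band from the normal field by global Fourier least
squares (the Frankot–Chellappa projection onto integrable gradient fields),
with two numerical choices that matter:

* **Mean-gradient ramp.** The Fourier basis contains no linear term, so the
  mean gradient is removed first and added back as an explicit planar ramp.
  Tilted planes are then recovered exactly.
* **Boundary handling.** The default inverts the field on its own domain
  (periodic assumption). For band-limited surfaces — which the synthetic
  phantoms are by construction, and which includes any sampled harmonic —
  this is exact to machine precision. The common mirror-padding variant is
  available (`boundary = "mirror"`), but the even extension of a generic
  surface has a slope discontinuity at the seam that caps accuracy near
  1e-3 relative RMSE; we measured exactly that on the analytic sinusoid
  oracle, which is why "mirror" is the option and "periodic" the default.
  On real (aperiodic) captures the mirror mode is the safer choice; on the
  synthetic world the periodic mode is both faster and exact.

The renderer computes height-map gradients spectrally (FFT derivative), so
render → solve → integrate is exactly invertible on noiseless captures; this
is the package's strongest internal consistency check (albedo to < 1e-8,
height to well under 1% of the height range).

Depth maps are Gaussian-smoothed (default sigma 2 px, reflective
symmetric-with-repeat boundary, which conserves total mass) and stacked with
the albedo frames into the 66-channel processed cube (channels 1–33 albedo,
34–66 surface models; 1605 × 1640 × 66 at the device's full frame).

## Synthetic world

The generator states one fixed world; its defaults are not tuned against
test outcomes.

* **Spectra.** Class spectra are built from a smooth sigmoidal skin baseline
  with melanin attenuation (pigmented classes: nevus `PN`, melanoma `MM`
  with stronger attenuation — monotone increasing reflectance, melanoma
  depressed below nevus everywhere) and oxyhaemoglobin-like absorption dips
  near 545/575 nm (vascular classes `BCC`, `SCC`; `ID` is a brighter,
  skin-colored elevated nevus). All lesion spectra are scaled radially
  around the healthy spectrum so the minimum per-band gap to healthy equals
  `delta` (default 0.03 reflectance units, about six times the default
  sensor noise expressed in reflectance and close to the unscaled
  chromophore design). A smooth seeded perturbation (sd 0.01) emulates
  inter-lesion biological variability.
* **Geometry.** Background relief is a band-limited periodic Gaussian field
  (sd 2 px ≈ 50 µm at the 24 µm pixel pitch, correlation length 15% of the
  frame); the lesion is a raised compact dome with a low-order irregular
  outline. The field of view is the circular cone aperture. The real LED
  angles are not published; the default is three azimuths at 0/120/240° and
  40° zenith — a symmetric, well-conditioned system — and fully
  configurable. The VIS/VNIR split is likewise not published; the default
  boundary is the first band at or above 700 nm.
* **Noise.** Additive Gaussian counts (sd 0.5% of the white level), the
  simplest model supporting signal-to-noise sweeps. ADC quantization is off
  by default (the exact inverse property needs continuous counts) and
  available as an option.

What a green end-to-end test establishes: the pipeline's stages compose
correctly, the network can exploit spectral/surface structure, and accuracy
responds monotonically to class separation. What it does not establish:
clinical performance. The phantoms have spatially flat class spectra, no
subsurface scattering, no specular term, no hair/reflection artefacts, no
camera distortion, and annotations equal to ground truth; the published
sensitivities and specificities on patients are therefore out of scope by
construction.

## Machine-learning pre-processing

Masks are derived from the annotation by exact Euclidean-distance-transform
disk morphology: the annotation eroded by 30 px forms the lesion sampling
core, a 60 px band around the lesion border is excluded entirely, and
healthy skin is sampled from an annulus (default 200 px beyond the
annotation) inside the eroded field of view. These radii are full-resolution
quantities (24 µm/px); `cohort_config()` scales them by `height_px / 1605`
so desk-scale frames keep the same physical margins.

Feature cubes keep the 33 albedo channels plus the single most informative
surface frame (575 nm, the band nearest on ties-to-lower). Non-finite values
are zeroed, then channels are min-max scaled to `[0, 1]` inside the field of
view. The scaling scope is a deliberate choice: the 33 albedo channels share
one affine map ("grouped", the default) because per-channel scaling of the
synthetic phantoms — where each band's minimum is literally the lesion level
— collapses every band to lesion ≈ 0 / healthy ≈ 1 and erases the spectral
shape; the surface channel, in different units, is scaled on its own.
Per-channel scaling remains available.

Each image is sliced vertically at the annotation centroid column: left half
trains, right half tests. Per half, 250 lesion-core and 100 healthy center
pixels are drawn uniformly without replacement among centers whose
30 × 30 window fits inside the half (the "middle pixel" of the even window
sits at 0-based offset (15, 15)). A 20% stratified validation split is taken
*before* balancing and augmentation so no duplicate can leak into
validation; the training side is then balanced by random over-sampling and
tripled by horizontal + vertical flip augmentation. The 0.2 fraction is an
inference from the published 1400-of-7000 and 1540-of-7700 validation sizes
and is configurable. The published training-set totals (29,136 / 31,168) are
not reproducible from any factorization of the stated quotas, split and
augmentation, and are deliberately not treated as contracts.

## The classifier

The network mirrors the published sketch: a 3D-convolution branch over the
30 × 30 × 33 albedo patch (spectral + spatial features) and a 2D branch over
the 30 × 30 surface frame, LeakyReLU (slope 0.1) and max pooling in both,
flatten, concatenate, dense hidden layers, softmax with 3 (pigmented) or 4
(non-pigmented) classes. Exact filter counts are not published; the default
is `conv(8, 3×3×7) → pool(2×2×2) → conv(16, 3×3×5) → pool(2×2×2)` against
`conv(8, 3×3) → pool(2×2) → conv(16, 3×3) → pool(2×2)`, dense 128 → 64 —
small enough for a single CPU and fully configurable. Pooling spans the
spectral axis (the open choice; spanning keeps the parameter count down).
Training is categorical cross-entropy with Adam at its default parameters
(lr 0.001, beta1 0.9, beta2 0.999), early stopping on validation loss
(default patience 10, epoch cap 50), best-validation weights restored.
Because no deep-learning framework is assumed, the convolutions (im2col +
GEMM), pooling, backpropagation and Adam are implemented in the package
itself (RcppArmadillo kernels + R orchestration); backpropagation is
verified against finite differences in the test suite. With a fixed seed and
single-threaded BLAS, training is bit-reproducible.

## Evaluation

Pixel-wise metrics are computed on the sampled test windows: one-vs-rest
sensitivity, specificity, PPV and F1 per class, with support-weighted
aggregates ("weighted specificity" is this package's definition — a
support-weighted one-vs-rest mean — not a standard library aggregate;
weighted sensitivity equals overall accuracy). Ratios with zero denominators
are reported as 0 and flagged. The implementation is tested for exact
agreement against a brute-force tally.

Per lesion, the trained model classifies every annotated test-half pixel
whose window fits the frame (maps are restricted to the field of view — the
out-of-view pixels the original authors note as an accuracy bias are never
scored; whole-image accuracy is intentionally not reported). Majority voting
tallies raw counts of lesion-type predictions only (healthy predictions are
recorded for diagnostics but excluded, following the "lesion pixels per
lesion type" rule); confidence-weighted voting was considered and not used
since the source procedure counts pixels. Ties break by malignancy priority
(MM > PN; SCC > BCC > ID): over-calling malignancy is the clinically safer
error.

## Numerical and scale choices

* Desk-scale defaults (256 px frames for count contracts, 128 px for the
  end-to-end recovery tests, scaled morphology radii, 4–8 conv filters,
  fewer epochs) exist purely to fit CPU budgets; generator noise, class
  separation, quotas for count contracts, and the architecture's *structure*
  are never scaled. The full 1605 × 1640 frame is exercised by the
  acceptance script's shape-contract target.
* At desk scale a lesion must keep its eroded core at least ~16 px from the
  slice column, or no 30 px window fits the half; `sample_windows` reports
  the shortfall explicitly rather than silently under-sampling.
* Degenerate inputs are explicit errors: empty annotations, all-invalid
  integration masks, single-class over-sampling input, validation fractions
  that empty a stratum, kernels that exceed the patch.

## Known limitations

* The synthetic world omits subsurface scattering, specular reflection,
  quantization (by default), registration error and annotation noise.
* Periodic depth integration is exact only for band-limited fields; real
  captures should use the mirror boundary and accept ~1e-3 boundary error.
* The CNN is CPU-sized; no attempt is made to match the original model's
  (unpublished) capacity, and no hyperparameter search is performed.
* Masks and maps persist as PGM/PPM (netpbm) rather than PNG/TIFF to avoid
  image-codec dependencies; numeric cubes round-trip through RDS with JSON
  sidecars.
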