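# hsiderm

Hyperspectral photometric-stereo skin-lesion analysis: a tested, reusable R
implementation of the full pipeline behind hand-held 3D spectral imaging of
pigmented and non-pigmented skin tumours.

## What it does, and for whom

Dermatological hyperspectral imagers distinguish lesion classes by their
diffuse reflectance spectra (477–891 nm, 33 wavebands), shaped by melanin and
haemoglobin. A photometric-stereo imager captures every band under three
known LED directions, so per-band **albedo** and a **skin-surface height
model** can be reconstructed before classification — adding shape and depth
information that plain spectral imaging lacks. This package is for
researchers in biomedical optics / computational dermatology who want a
working, inspectable version of that analysis chain:

1. **Photometric pre-processing** — flat-field reflectance calibration
   `R = (raw − dark)/(white − dark)`; per-band Lambertian photometric stereo
   (`I = ρ·(n·l)` solved for three lights: `g = L⁻¹I`, `ρ = |g|`,
   `n = g/|g|`); Frankot–Chellappa Fourier integration of the normals into
   depth maps; Gaussian smoothing; assembly of the 66-channel cube
   (33 albedo + 33 surface-model frames; 1605 × 1640 × 66 at full device
   resolution).
2. **ML pre-processing** — annotation-driven masks (30 px erosion to the
   lesion core, 60 px excluded border margin, healthy annulus inside the
   eroded field of view), selection of 33 albedo channels + the 575 nm
   surface frame (34 channels), min-max normalization, vertical train/test
   slicing through the lesion centroid, 250 lesion / 100 healthy
   30 × 30 × 34 windows per half, stratified validation split, random
   over-sampling, flip augmentation.
3. **Dual-branch CNN** — a 3D-convolution branch over the albedo patch and a
   2D branch over the surface frame; LeakyReLU + max pooling; flatten,
   concatenate, dense layers, softmax (3 classes for pigmented MM/PN/healthy,
   4 for non-pigmented BCC/SCC/ID/healthy). Adam (default parameters),
   categorical cross-entropy, early stopping. Implemented from scratch
   (RcppArmadillo im2col/GEMM kernels) — no deep-learning framework needed.
4. **Evaluation** — pixel-wise one-vs-rest sensitivity / specificity / PPV /
   F1 with confusion matrices, per-lesion classification and confidence
   maps, and **majority voting**: one diagnosis per lesion from the most
   frequent lesion-type prediction over annotated test-half pixels (ties
   break by malignancy: MM > PN, SCC > BCC > ID).

The clinical captures behind the original study are not public, so the
package ships a first-class **synthetic capture generator**: chromophore-like
class spectra with a configurable minimum separation δ, periodic band-limited
skin relief plus a lesion dome, three-light Lambertian rendering with dark /
white references and sensor noise, and known ground truth for every stage.
The noiseless render → calibrate → solve → integrate loop is exactly
invertible (albedo to < 1e-8), which anchors the test suite.

## Worked example

A desk-scale pigmented cohort (128 px frames, 6 lesions), end to end:

```r
library(hsiderm)
sc <- sensor_config(128, 128)
cohort <- make_cohort(6, c(MM = 2, PN = 4), sensor = sc, seed = 21,
                      lesion_radius_px = 24)
cfg <- cohort_config(sensor = sc, n_lesion_px = 60L, n_healthy_px = 24L,
  model = list(conv3d_spec = list(list(filters = 4L, kernel = c(3L, 3L, 7L)),
                                  list(filters = 8L, kernel = c(3L, 3L, 5L))),
               conv2d_spec = list(list(filters = 4L, kernel = c(3L, 3L)),
                                  list(filters = 8L, kernel = c(3L, 3L))),
               dense_units = c(32L), max_epochs = 12L, patience = 4L))
rep <- run_cohort(cohort, "pigmented", cfg, seed = 5)
print(rep)
```

prints (about 5 minutes on one CPU):

```
Cohort report: 6 lesions, 504 test windows
Pixel-wise weighted: sens 0.954 spec 0.959 ppv 0.958 f1 0.953
Majority voting: 6 / 6 lesions correct
```

Reading this: 6 lesions × (60 lesion + 24 healthy) test windows = 504
pixel-wise test samples; the class-weighted one-vs-rest sensitivity over
MM/PN/healthy is 0.954 (equal to overall pixel accuracy by construction);
and the per-lesion majority vote over annotated test-half pixels recovered
the true diagnosis for all 6 lesions. `write_report(rep, "out/")` persists
metrics and confusion matrices as CSV, votes as JSON, and indexed class maps
as PPM images with a JSON legend.

Individual stages are plain functions if you want the pieces:
`class_spectrum()`, `make_phantom()`, `render_capture()`,
`calibrate_reflectance()`, `solve_photometric_stereo()`,
`integrate_depth()`, `preprocess_capture()`, `build_masks()`,
`select_channels()`, `normalize_features()`, `split_vertical()`,
`sample_windows()`, `balance_oversample()`, `augment_flips()`,
`build_model()`, `train_model()`, `predict()`, `classification_map()`,
`majority_vote()`, `pixelwise_metrics()`.

A small CLI lives at `inst/cli/hsiderm`
(`hsiderm simulate|preprocess|all --out DIR [--group pigmented] [--seed 1]`).

## Scope

The generator emulates the statistical structure the analysis assumes — not
skin optics. Published clinical accuracies are not reproduction targets
(data unavailable); see `vignettes/hsiderm-methods.Rmd` for the model,
parameter choices, and limitations.
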