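#' Lesion class labels
#'
#' Pigmented group: `MM` (malignant melanoma), `PN` (benign pigmented nevus).
#' Non-pigmented group: `BCC` (basal cell carcinoma), `SCC` (squamous cell
#' carcinoma), `ID` (intradermal nevus). `healthy` denotes surrounding skin.
#' @export
lesion_classes <- function() c("MM", "PN", "BCC", "SCC", "ID")

pigmented_classes <- function() c("MM", "PN")
nonpigmented_classes <- function() c("BCC", "SCC", "ID")

#' Spectrum generator knobs
#'
#' @param delta minimum per-band reflectance separation between the healthy
#'   spectrum and every lesion-class spectrum. Lesion spectra are scaled
#'   radially around the healthy spectrum so this minimum gap equals `delta`.
#'   Default 0.03 reflectance units (about 6x the default sensor noise
#'   expressed in reflectance, and close to the unscaled chromophore design).
#' @param jitter_sd standard deviation of the smooth per-seed spectral
#'   perturbation emulating inter-lesion biological variability.
#' @param max_band_step smoothness contract: upper bound on the absolute
#'   reflectance difference between adjacent bands.
#' @export
spectrum_params <- function(delta = 0.03, jitter_sd = 0.01,
                            max_band_step = 0.12) {
  stopifnot(delta >= 0, jitter_sd >= 0, max_band_step > 0)
  list(delta = delta, jitter_sd = jitter_sd, max_band_step = max_band_step)
}

# Chromophore building blocks -------------------------------------------------

# Baseline diffuse skin reflectance without haemoglobin features: a smooth
# sigmoidal rise from blue to NIR (melanin/scattering trend of fair skin).
skin_base <- function(wl) 0.30 + 0.38 * stats::plogis((wl - 590) / 45)

# Oxyhaemoglobin-like double absorption dip near 545 and 575 nm.
haem_dips <- function(wl) {
  0.07 * exp(-0.5 * ((wl - 545) / 12)^2) +
    0.055 * exp(-0.5 * ((wl - 575) / 12)^2)
}

# Melanin transmission factor; larger k = more pigment, strongest in blue.
melanin_tx <- function(wl, k) exp(-k * (wl / 700)^(-3))

# Full-strength (unscaled) class spectra. Pigmented classes are melanin
# attenuated and monotone increasing (dips are masked by pigment); vascular
# classes keep/deepen the haemoglobin dips.
full_strength_spectrum <- function(class, wl) {
  b <- skin_base(wl)
  d <- haem_dips(wl)
  switch(class,
    healthy = b - d,
    PN  = b * melanin_tx(wl, 0.35),
    MM  = b * melanin_tx(wl, 0.80),
    ID  = 1.10 * b - d,
    BCC = 0.86 * b - 1.6 * d,
    SCC = 0.70 * b - 2.4 * d,
    stop("unknown lesion class: ", class)
  )
}

#' Per-band albedo spectrum for a lesion class
#'
#' Deterministic in `seed`. Lesion spectra are generated from smooth
#' chromophore models (melanin slope for pigmented classes, haemoglobin dips
#' near 545/575 nm for vascular classes) and scaled around the healthy
#' spectrum so that the minimum per-band gap to healthy equals
#' `params$delta`; a smooth seeded perturbation adds inter-lesion
#' variability.
#'
#' @param lesion_class one of `lesion_classes()` or `"healthy"`.
#' @param wavelengths band centers (nm), sorted ascending.
#' @param params see [spectrum_params()].
#' @param seed integer seed for the per-lesion perturbation.
#' @return numeric vector of albedos in `[0.02, 0.98]`, one per band.
#' @export
class_spectrum <- function(lesion_class, wavelengths = default_wavelengths(),
                           params = spectrum_params(), seed = 1L) {
  if (!lesion_class %in% c("healthy", lesion_classes()))
    stop("unknown lesion class: ", lesion_class)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be sorted ascending")
  h <- full_strength_spectrum("healthy", wavelengths)
  if (lesion_class == "healthy") {
    s <- h
  } else {
    # scale all classes by a common factor so min-gap-to-healthy = delta
    gaps <- vapply(lesion_classes(), function(cl)
      min(abs(full_strength_spectrum(cl, wavelengths) - h)), numeric(1))
    scale <- params$delta / min(gaps)
    s <- h + scale * (full_strength_spectrum(lesion_class, wavelengths) - h)
  }
  if (params$jitter_sd > 0) {
    x <- (wavelengths - min(wavelengths)) /
      max(wavelengths[length(wavelengths)] - wavelengths[1], 1)
    jit <- with_seed(seed, {
      a <- stats::rnorm(4) / (1:4)
      rowSums(vapply(1:4, function(j) a[j] * cos(j * pi * x),
                     numeric(length(x))))
    })
    s <- s + params$jitter_sd * jit
  }
  clamp(s, 0.02, 0.98)
}
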