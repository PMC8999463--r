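#' Phantom generator knobs
#'
#' Defaults emulate skin-scale relief at the imager's 24 um pixel pitch:
#' background relief of ~2 px (~50 um) with a correlation length of ~15% of
#' the frame, a raised lesion dome, mildly irregular lesion boundary, and a
#' gentle multiplicative albedo texture.
#'
#' @param height_sd_px standard deviation of the background height field (px).
#' @param height_corr_frac correlation length of the background relief as a
#'   fraction of the smaller frame dimension.
#' @param dome_height_px peak added elevation of the lesion dome (px);
#'   `NULL` = `max(3, lesion_radius_px / 5)`.
#' @param boundary_irregularity relative radial modulation of the lesion
#'   outline (0 = perfect disk).
#' @param texture_sd standard deviation of the multiplicative albedo texture.
#' @param edge_soft_px width of the albedo blend at the lesion boundary (px).
#' @param annulus_px healthy margin that must fit between the lesion outline
#'   and the field-of-view edge; `NULL` = `round(100 * height_px / 1605)`
#'   (the full-resolution 60 px sampling margin + 30 px window + buffer,
#'   scaled to the frame).
#' @param spectrum see [spectrum_params()].
#' @export
phantom_params <- function(height_sd_px = 2, height_corr_frac = 0.15,
                           dome_height_px = NULL,
                           boundary_irregularity = 0.08,
                           texture_sd = 0.02, edge_soft_px = 3,
                           annulus_px = NULL,
                           spectrum = spectrum_params()) {
  list(height_sd_px = height_sd_px, height_corr_frac = height_corr_frac,
       dome_height_px = dome_height_px,
       boundary_irregularity = boundary_irregularity,
       texture_sd = texture_sd, edge_soft_px = edge_soft_px,
       annulus_px = annulus_px, spectrum = spectrum)
}

#' Low-level scene phantom constructor
#'
#' A phantom stores the surface height field, the lesion and field-of-view
#' masks, and a compact albedo model: per-band healthy and lesion spectra, a
#' lesion blend-weight map and a multiplicative texture. The (possibly large)
#' albedo cube is materialised on demand by [phantom_albedo()].
#'
#' @param height_map numeric matrix, surface elevation in pixel units.
#' @param lesion_mask,fov_mask logical matrices; `lesion_mask` must be a
#'   subset of `fov_mask`.
#' @param lesion_class class label of the lesion.
#' @param spectra list with numeric vectors `healthy` and `lesion` (albedo
#'   per band, in `[0, 1]`).
#' @param class_weight matrix in `[0, 1]`: 1 = pure lesion spectrum.
#' @param texture multiplicative albedo texture matrix (around 1).
#' @param wavelengths_nm band centers.
#' @return object of class `scene_phantom`.
#' @export
scene_phantom <- function(height_map, lesion_mask, fov_mask, lesion_class,
                          spectra, class_weight = lesion_mask * 1,
                          texture = 1 + 0 * height_map,
                          wavelengths_nm = default_wavelengths()) {
  stopifnot(is.matrix(height_map),
            identical(dim(height_map), dim(lesion_mask)),
            identical(dim(height_map), dim(fov_mask)),
            identical(dim(height_map), dim(class_weight)),
            length(spectra$healthy) == length(wavelengths_nm),
            length(spectra$lesion) == length(wavelengths_nm))
  if (any(lesion_mask & !fov_mask))
    stop("lesion_mask must be contained in fov_mask")
  structure(list(height_map = height_map, lesion_mask = lesion_mask,
                 fov_mask = fov_mask, lesion_class = lesion_class,
                 spectra = spectra, class_weight = class_weight,
                 texture = texture, wavelengths_nm = wavelengths_nm),
            class = "scene_phantom")
}

#' Materialise phantom albedo for one or more bands
#'
#' @param phantom a [scene_phantom()].
#' @param bands band indices (default all).
#' @return H x W x length(bands) array of true albedos in `[0, 1]`.
#' @export
phantom_albedo <- function(phantom, bands = seq_along(phantom$wavelengths_nm)) {
  H <- nrow(phantom$height_map); W <- ncol(phantom$height_map)
  out <- array(0, c(H, W, length(bands)))
  for (i in seq_along(bands)) {
    b <- bands[i]
    a <- phantom$spectra$healthy[b] +
      phantom$class_weight * (phantom$spectra$lesion[b] - phantom$spectra$healthy[b])
    out[, , i] <- clamp(a * phantom$texture, 0, 1)
  }
  out
}

# Band-limited periodic Gaussian random field, unit variance.
random_smooth_field <- function(H, W, corr_px) {
  wn <- matrix(stats::rnorm(H * W), H, W)
  fy <- c(0:floor(H / 2), -(ceiling(H / 2) - 1):-1) / H
  fx <- c(0:floor(W / 2), -(ceiling(W / 2) - 1):-1) / W
  f2 <- outer(fy^2, rep(1, W)) + outer(rep(1, H), fx^2)
  filt <- exp(-2 * (pi * corr_px)^2 * f2)
  z <- Re(stats::fft(stats::fft(wn) * filt, inverse = TRUE)) / (H * W)
  z / stats::sd(z)
}

#' Generate a synthetic lesion scene
#'
#' Builds a smooth periodic background relief plus a raised lesion dome, an
#' irregular-disk lesion mask, a circular field of view, and a compact albedo
#' model (healthy spectrum outside the lesion, class spectrum inside, with a
#' soft blend at the boundary and a smooth multiplicative texture).
#' Deterministic given `seed`.
#'
#' @param sensor a [sensor_config()].
#' @param lesion_class one of [lesion_classes()].
#' @param lesion_radius_px nominal lesion radius (px).
#' @param seed integer.
#' @param params see [phantom_params()].
#' @return a [scene_phantom()].
#' @export
make_phantom <- function(sensor, lesion_class,
                         lesion_radius_px = round(0.13 * min(sensor$height_px, sensor$width_px)),
                         seed = 1L, params = phantom_params()) {
  if (!lesion_class %in% lesion_classes())
    stop("unknown lesion class: ", lesion_class)
  H <- sensor$height_px; W <- sensor$width_px
  if (lesion_radius_px < 1) stop("lesion_radius_px must be >= 1")
  fov_r <- min(H, W) / 2 - 4
  annulus <- params$annulus_px %||% max(8L, round(100 * H / 1605))
  irr <- params$boundary_irregularity
  max_r <- lesion_radius_px * (1 + 2 * irr)
  if (max_r + annulus > fov_r) {
    need <- ceiling(2 * (max_r + annulus + 4))
    stop(sprintf(paste0("lesion (radius %d px) plus the %d px healthy annulus ",
                        "does not fit the %d x %d frame; need a frame of at ",
                        "least %d x %d px"),
                 lesion_radius_px, annulus, H, W, need, need))
  }
  dome_h <- params$dome_height_px %||% max(3, lesion_radius_px / 5)

  with_seed(seed, {
    cy <- H / 2 + 0.5 + stats::runif(1, -0.05, 0.05) * lesion_radius_px
    cx <- W / 2 + 0.5 + stats::runif(1, -0.05, 0.05) * lesion_radius_px
    yy <- matrix(seq_len(H), H, W) - cy
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    r <- sqrt(yy^2 + xx^2)
    th <- atan2(yy, xx)

    # irregular lesion outline: low-order radial modulation
    ab <- stats::rnorm(6)
    mod <- (ab[1] * cos(2 * th) + ab[2] * sin(2 * th) +
            ab[3] * cos(3 * th) + ab[4] * sin(3 * th) +
            ab[5] * cos(4 * th) + ab[6] * sin(4 * th)) / sqrt(6)
    rad <- lesion_radius_px * (1 + clamp(irr * mod, -2 * irr, 2 * irr))
    lesion_mask <- r <= rad
    fov_mask <- r_center_dist(H, W) <= fov_r

    # surface: periodic background relief + compactly supported dome
    corr <- params$height_corr_frac * min(H, W)
    height <- params$height_sd_px * random_smooth_field(H, W, corr)
    dome_r <- 1.3 * lesion_radius_px
    inside <- r < dome_r
    height[inside] <- height[inside] + dome_h * cos(pi * r[inside] / (2 * dome_r))^2

    sp <- list(
      healthy = class_spectrum("healthy", sensor$wavelengths_nm,
                               params$spectrum, seed = seed),
      lesion = class_spectrum(lesion_class, sensor$wavelengths_nm,
                              params$spectrum, seed = seed)
    )
    # soft blend weight from the signed distance to the outline
    w <- clamp((rad - r) / max(params$edge_soft_px, 1e-9) + 0.5, 0, 1)
    texture <- 1 + params$texture_sd * random_smooth_field(H, W, corr / 3)

    scene_phantom(height, lesion_mask, fov_mask & TRUE, lesion_class, sp,
                  class_weight = w, texture = texture,
                  wavelengths_nm = sensor$wavelengths_nm)
  })
}

r_center_dist <- function(H, W) {
  yy <- matrix(seq_len(H), H, W) - (H / 2 + 0.5)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - (W / 2 + 0.5)
  sqrt(yy^2 + xx^2)
}
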