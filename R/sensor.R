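#' Sensor configuration for an emulated hyperspectral capture
#'
#' Describes the emulated Fabry-Perot imager: frame geometry, the 33 band
#' centers between 477 and 891 nm, the VIS/VNIR channel-group split, and the
#' radiometric reference levels. Defaults give a desk-scale 256 x 256 frame;
#' the physical device frame is 1605 x 1640 at ~24 um per pixel.
#'
#' @param height_px,width_px frame size in pixels.
#' @param wavelengths_nm strictly increasing band centers, 33 values in
#'   `[477, 891]`. Default: 33 evenly spaced centers.
#' @param vis_band_count number of bands in the VIS channel group. Default
#'   puts the group boundary at the first band >= 700 nm (conventional
#'   VIS/NIR boundary).
#' @param dark_level,white_level sensor counts of the dark reference and of a
#'   unit-albedo flat target under full illumination.
#' @param noise_sd additive Gaussian read-noise (counts). Default 0.5% of
#'   `white_level`.
#' @param pixel_pitch_um physical pixel size (24 um on the device).
#' @return an object of class `sensor_config`.
#' @export
sensor_config <- function(height_px = 256L, width_px = 256L,
                          wavelengths_nm = default_wavelengths(),
                          vis_band_count = NULL,
                          dark_level = 64, white_level = 4000,
                          noise_sd = 0.005 * white_level,
                          pixel_pitch_um = 24) {
  stopifnot(height_px >= 64, width_px >= 64)
  if (length(wavelengths_nm) != 33L)
    stop("wavelengths_nm must contain exactly 33 band centers")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be strictly increasing")
  if (min(wavelengths_nm) < 477 || max(wavelengths_nm) > 891)
    stop("band centers must lie in [477, 891] nm")
  if (is.null(vis_band_count))
    vis_band_count <- sum(wavelengths_nm < 700)
  vis_band_count <- as.integer(vis_band_count)
  if (vis_band_count <= 0L || vis_band_count >= 33L)
    stop("vis_band_count must satisfy 0 < vis_band_count < 33")
  if (dark_level >= white_level) stop("dark_level must be < white_level")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 vis_band_count = vis_band_count,
                 dark_level = dark_level, white_level = white_level,
                 noise_sd = noise_sd, pixel_pitch_um = pixel_pitch_um),
            class = "sensor_config")
}

#' Default 33 band centers, evenly spaced over 477-891 nm
#' @return numeric vector of 33 wavelengths (nm).
#' @export
default_wavelengths <- function() seq(477, 891, length.out = 33L)

#' Photometric-stereo illumination geometry
#'
#' Three unit vectors pointing from the surface toward each LED set. The
#' device's LED tilt angles are not public; the default is three azimuths at
#' 0/120/240 degrees with a common zenith angle, which gives a symmetric,
#' well-conditioned 3 x 3 system.
#'
#' @param zenith_deg zenith angle of each light (degrees from vertical).
#' @param azimuth_deg three azimuths (degrees).
#' @param directions optionally, a 3 x 3 matrix of unit row vectors
#'   (overrides the angles).
#' @return object of class `light_geometry`: a 3 x 3 matrix, rows = lights.
#' @export
light_geometry <- function(zenith_deg = 40,
                           azimuth_deg = c(0, 120, 240),
                           directions = NULL) {
  if (is.null(directions)) {
    th <- zenith_deg * pi / 180
    ph <- azimuth_deg * pi / 180
    directions <- cbind(sin(th) * cos(ph), sin(th) * sin(ph),
                        rep(cos(th), 3L))
  }
  directions <- as.matrix(directions)
  if (!all(dim(directions) == c(3L, 3L)))
    stop("directions must be a 3 x 3 matrix (rows = lights)")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8))
    directions <- directions / nrm
  if (any(directions[, 3] <= 0))
    stop("all light directions must have positive z-component")
  if (abs(det(directions)) < 1e-10)
    stop("light direction matrix is singular")
  structure(directions, class = c("light_geometry", "matrix"))
}
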