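#' Render a raw capture set from a phantom (Lambertian forward model)
#'
#' Per band b and light l, sensor counts are
#' `dark + (white - dark) * albedo_b * max(0, n . l) * fov + noise`,
#' where surface normals come from the height-map gradients. Gradients are
#' taken spectrally (FFT derivative), consistent with the depth integrator,
#' so the render/solve/integrate loop is exactly invertible on noiseless
#' captures. White reference frames are full-signal flat-field references
#' (`dark + (white - dark) * fov`), the dark frame is the dark level; both
#' carry the same additive noise model. Counts are continuous (no ADC
#' quantization) and clamped at 0.
#'
#' @param phantom a [scene_phantom()].
#' @param lights a [light_geometry()] (or plain 3 x 3 matrix of unit rows;
#'   singularity is only checked at solve time).
#' @param sensor a [sensor_config()]; frame size must match the phantom.
#' @param seed integer driving the noise.
#' @param quantize round counts to integers (ADC emulation) and store the
#'   stacks as integer arrays (halves memory at full resolution). Default
#'   `FALSE`: the exact forward/inverse property needs continuous counts.
#' @return object of class `raw_capture`: list with `raw` (groups `vis`,
#'   `vnir`, each a list of 3 band-stacks, one per light), `dark_frame`,
#'   `white_frames` (list per group), `light_geometry`, `sensor`.
#' @export
render_capture <- function(phantom, lights = light_geometry(),
                           sensor, seed = 1L, quantize = FALSE) {
  H <- sensor$height_px; W <- sensor$width_px
  if (!identical(dim(phantom$height_map), c(H, W)))
    stop("phantom and sensor frame shapes disagree")
  L <- unclass(as.matrix(lights))
  if (!all(dim(L) == c(3L, 3L)) || any(abs(sqrt(rowSums(L^2)) - 1) > 1e-6))
    stop("lights must be three unit direction vectors")

  g <- spectral_gradient(phantom$height_map)      # p = dz/dx, q = dz/dy
  nz <- 1 / sqrt(g$p^2 + g$q^2 + 1)
  nx <- -g$p * nz; ny <- -g$q * nz
  shading <- lapply(1:3, function(l)
    pmax(0, nx * L[l, 1] + ny * L[l, 2] + nz * L[l, 3]))

  dk <- sensor$dark_level; span <- sensor$white_level - sensor$dark_level
  fov <- phantom$fov_mask * 1
  nb <- length(sensor$wavelengths_nm)
  vis_idx <- seq_len(sensor$vis_band_count)
  vnir_idx <- setdiff(seq_len(nb), vis_idx)

  with_seed(seed, {
    noise <- function() if (sensor$noise_sd > 0)
      matrix(stats::rnorm(H * W, sd = sensor$noise_sd), H, W) else 0
    adc <- function(a) {
      if (quantize) { a <- round(a); storage.mode(a) <- "integer" }
      a
    }
    render_group <- function(bands) {
      stacks <- lapply(1:3, function(l) {
        a <- array(0, c(H, W, length(bands)))
        for (i in seq_along(bands)) {
          alb <- phantom_albedo(phantom, bands[i])[, , 1]
          a[, , i] <- pmax(dk + span * alb * shading[[l]] * fov + noise(), 0)
        }
        adc(a)
      })
      stacks
    }
    raw <- list(vis = render_group(vis_idx), vnir = render_group(vnir_idx))
    white_group <- function(bands) {
      a <- array(0, c(H, W, length(bands)))
      for (i in seq_along(bands))
        a[, , i] <- pmax(dk + span * fov + noise(), 0)
      adc(a)
    }
    white <- list(vis = white_group(vis_idx), vnir = white_group(vnir_idx))
    dark_frame <- adc(pmax(matrix(dk, H, W) + noise(), 0))
    structure(list(raw = raw, dark_frame = dark_frame, white_frames = white,
                   light_geometry = L, sensor = sensor),
              class = "raw_capture")
  })
}

# Spectral (FFT) partial derivatives of a periodic surface.
spectral_gradient <- function(z) {
  H <- nrow(z); W <- ncol(z)
  wy <- 2 * pi * c(0:floor(H / 2), -(ceiling(H / 2) - 1):-1) / H
  wx <- 2 * pi * c(0:floor(W / 2), -(ceiling(W / 2) - 1):-1) / W
  if (H %% 2 == 0) wy[H / 2 + 1] <- 0   # drop Nyquist for real derivative
  if (W %% 2 == 0) wx[W / 2 + 1] <- 0
  Z <- stats::fft(z)
  WX <- matrix(wx, H, W, byrow = TRUE)
  WY <- matrix(wy, H, W)
  p <- Re(stats::fft(1i * WX * Z, inverse = TRUE)) / (H * W)
  q <- Re(stats::fft(1i * WY * Z, inverse = TRUE)) / (H * W)
  list(p = p, q = q)
}

#' Generate a synthetic lesion cohort
#'
#' One capture set per lesion, with per-lesion seeds derived from `seed`.
#' The annotation mask equals the phantom's true lesion mask (emulating a
#' histology-confirmed manual annotation).
#'
#' @param n_lesions total number of lesions.
#' @param class_mix named integer vector (names in [lesion_classes()])
#'   summing to `n_lesions`, e.g. `c(MM = 7, PN = 13)`.
#' @param sensor a [sensor_config()].
#' @param seed integer.
#' @param lights a [light_geometry()].
#' @param lesion_radius_px nominal lesion radius; default as in
#'   [make_phantom()].
#' @param params see [phantom_params()].
#' @return list of lesions, each a list with `capture`, `annotation`,
#'   `label`, `phantom` (ground truth) and `id`.
#' @export
make_cohort <- function(n_lesions, class_mix, sensor = sensor_config(),
                        seed = 1L, lights = light_geometry(),
                        lesion_radius_px = NULL, params = phantom_params()) {
  if (length(class_mix) == 0) stop("class_mix must not be empty")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% lesion_classes()))
    stop("unknown class in class_mix")
  if (sum(class_mix) != n_lesions)
    stop("class_mix counts must sum to n_lesions")
  labels <- rep(names(class_mix), times = class_mix)
  seeds <- derive_seeds(seed, n_lesions)
  radius <- lesion_radius_px %||%
    round(0.13 * min(sensor$height_px, sensor$width_px))
  lapply(seq_len(n_lesions), function(i) {
    ph <- make_phantom(sensor, labels[i], lesion_radius_px = radius,
                       seed = seeds[i], params = params)
    cap <- render_capture(ph, lights, sensor, seed = seeds[i] %% 1000000L + 7L)
    list(id = sprintf("lesion_%02d_%s", i, labels[i]),
         capture = cap, annotation = ph$lesion_mask,
         label = labels[i], phantom = ph)
  })
}
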