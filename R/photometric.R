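#' Flat-field reflectance calibration
#'
#' `R = (raw - dark) / (white - dark)` per pixel and band. Pixels where the
#' white reference does not exceed the dark frame carry no signal (outside
#' the light-protection cone's field of view); they are set to 0 and flagged
#' invalid.
#'
#' @param raw H x W x B array of raw counts (B >= 1).
#' @param dark H x W dark-frame counts.
#' @param white H x W x B white-reference counts.
#' @param band_centers_nm band centers of the B bands.
#' @return object of class `reflectance_cube`: list(values, band_centers_nm,
#'   valid) where `valid` is an H x W x B logical array.
#' @export
calibrate_reflectance <- function(raw, dark, white, band_centers_nm = NULL) {
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))
  if (length(dim(white)) == 2L) white <- array(white, c(dim(white), 1L))
  if (!identical(dim(raw), dim(white)) ||
      !identical(dim(raw)[1:2], dim(dark)[1:2]))
    stop("shape mismatch between raw, dark and white frames")
  B <- dim(raw)[3]
  band_centers_nm <- band_centers_nm %||% seq_len(B)
  denom <- white - as.vector(dark)
  valid <- denom > 0
  vals <- array(0, dim(raw))
  vals[valid] <- (raw[valid] - rep(dark, B)[valid]) / denom[valid]
  structure(list(values = vals, band_centers_nm = band_centers_nm,
                 valid = valid),
            class = "reflectance_cube")
}

#' Merge the VIS and VNIR channel groups of one light direction
#'
#' @param vis,vnir `reflectance_cube`s with disjoint band sets.
#' @return single `reflectance_cube` ordered by wavelength.
#' @export
merge_channel_groups <- function(vis, vnir) {
  if (!identical(dim(vis$values)[1:2], dim(vnir$values)[1:2]))
    stop("channel groups have different frame shapes")
  if (length(intersect(vis$band_centers_nm, vnir$band_centers_nm)) > 0)
    stop("overlapping band centers between channel groups")
  bands <- c(vis$band_centers_nm, vnir$band_centers_nm)
  ord <- order(bands)
  vals <- array(0, c(dim(vis$values)[1:2], length(bands)))
  vals[, , seq_along(vis$band_centers_nm)] <- vis$values
  vals[, , length(vis$band_centers_nm) + seq_along(vnir$band_centers_nm)] <- vnir$values
  valid <- array(FALSE, dim(vals))
  valid[, , seq_along(vis$band_centers_nm)] <- vis$valid
  valid[, , length(vis$band_centers_nm) + seq_along(vnir$band_centers_nm)] <- vnir$valid
  structure(list(values = vals[, , ord, drop = FALSE],
                 band_centers_nm = bands[ord],
                 valid = valid[, , ord, drop = FALSE]),
            class = "reflectance_cube")
}

# Per-band Lambertian solve on an N x 3 intensity matrix. Returns albedo,
# unit normals and the invalid (shadow) flag.
solve_ps_band <- function(I3, Linv_t) {
  G <- I3 %*% Linv_t
  rho <- sqrt(rowSums(G^2))
  bad <- (rowSums(I3 <= 0) > 0) | rho == 0 | G[, 3] <= 0
  n <- G / ifelse(rho > 0, rho, 1)
  n[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
  rho[bad] <- 0
  list(albedo = clamp(rho, 0, 1), normals = n, shadow = bad)
}

#' Per-waveband Lambertian photometric stereo
#'
#' Per pixel and band, solves `I = rho * (n . l)` for the three known light
#' directions: `g = L^-1 I`, `rho = |g|`, `n = g / |g|`. Pixels with any
#' non-positive intensity, zero `|g|`, or non-positive `n_z` are flagged in
#' the shadow mask and receive `rho = 0`, `n = (0, 0, 1)`. Albedo is clipped
#' to `[0, 1]`.
#'
#' @param cubes list of three `reflectance_cube`s (one per light direction,
#'   identical band sets).
#' @param lights a [light_geometry()].
#' @return object of class `photometric_products`: list(albedo_cube
#'   (H x W x B), normal_cube (H x W x 3 x B), shadow_mask (H x W x B),
#'   band_centers_nm).
#' @export
solve_photometric_stereo <- function(cubes, lights) {
  stopifnot(length(cubes) == 3L)
  bands <- cubes[[1]]$band_centers_nm
  for (k in 2:3)
    if (!isTRUE(all.equal(cubes[[k]]$band_centers_nm, bands)))
      stop("the three cubes must share identical band sets")
  L <- unclass(as.matrix(lights))
  if (abs(det(L)) < 1e-10) stop("singular light matrix")
  Linv_t <- t(solve(L))
  d <- dim(cubes[[1]]$values)
  H <- d[1]; W <- d[2]; B <- d[3]
  albedo <- array(0, c(H, W, B))
  normals <- array(0, c(H, W, 3, B))
  shadow <- array(FALSE, c(H, W, B))
  for (b in seq_len(B)) {
    I3 <- cbind(as.vector(cubes[[1]]$values[, , b]),
                as.vector(cubes[[2]]$values[, , b]),
                as.vector(cubes[[3]]$values[, , b]))
    s <- solve_ps_band(I3, Linv_t)
    albedo[, , b] <- s$albedo
    normals[, , , b] <- array(s$normals, c(H, W, 3))
    shadow[, , b] <- s$shadow
  }
  structure(list(albedo_cube = albedo, normal_cube = normals,
                 shadow_mask = shadow, band_centers_nm = bands),
            class = "photometric_products")
}

# Frankot-Chellappa least-squares integration of a gradient field.
fc_solve <- function(p, q) {
  H <- nrow(p); W <- ncol(p)
  wy <- 2 * pi * c(0:floor(H / 2), -(ceiling(H / 2) - 1):-1) / H
  wx <- 2 * pi * c(0:floor(W / 2), -(ceiling(W / 2) - 1):-1) / W
  WX <- matrix(wx, H, W, byrow = TRUE)
  WY <- matrix(wy, H, W)
  denom <- WX^2 + WY^2
  denom[1, 1] <- 1
  Z <- (-1i * (WX * stats::fft(p) + WY * stats::fft(q))) / denom
  Z[1, 1] <- 0
  Re(stats::fft(Z, inverse = TRUE)) / (H * W)
}

#' Depth map from per-pixel surface normals
#'
#' Gradients `p = -n_x / n_z`, `q = -n_y / n_z` (invalid pixels take gradient
#' 0) are integrated by global Fourier least squares (Frankot-Chellappa).
#' The mean gradient is handled as an explicit planar ramp (the Fourier basis
#' carries no linear term), so tilted planes are recovered exactly. With
#' `boundary = "periodic"` (default) the field is inverted on its own domain
#' — exact to machine precision for band-limited surfaces, which the
#' synthetic phantoms are by construction. `boundary = "mirror"` integrates
#' on the even 2H x 2W extension, trading exactness (the extension has a
#' slope kink, error ~1e-3) for robustness on aperiodic field data.
#' The result is zero-mean.
#'
#' @param normals H x W x 3 array of unit normals.
#' @param valid logical H x W mask of pixels with trustworthy normals
#'   (default all).
#' @param boundary `"periodic"` or `"mirror"`.
#' @return H x W zero-mean depth map (pixel units).
#' @export
integrate_depth <- function(normals, valid = NULL,
                            boundary = c("periodic", "mirror")) {
  boundary <- match.arg(boundary)
  H <- dim(normals)[1]; W <- dim(normals)[2]
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  if (!any(valid)) stop("all pixels are invalid; nothing to integrate")
  nz <- normals[, , 3]
  ok <- valid & nz > 0
  p <- q <- matrix(0, H, W)
  p[ok] <- -normals[, , 1][ok] / nz[ok]
  q[ok] <- -normals[, , 2][ok] / nz[ok]
  pbar <- mean(p[ok]); qbar <- mean(q[ok])
  p[ok] <- p[ok] - pbar; q[ok] <- q[ok] - qbar
  if (boundary == "mirror") {
    pp <- rbind(cbind(p, -p[, W:1]), cbind(p[H:1, ], -p[H:1, W:1]))
    qq <- rbind(cbind(q, q[, W:1]), cbind(-q[H:1, ], -q[H:1, W:1]))
    z <- fc_solve(pp, qq)[seq_len(H), seq_len(W)]
  } else {
    z <- fc_solve(p, q)
  }
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  y <- matrix(seq_len(H), H, W)
  z <- z + pbar * (x - mean(x)) + qbar * (y - mean(y))
  z - mean(z)
}

#' Gaussian smoothing of a depth map
#'
#' Separable Gaussian with reflective boundary; `sigma = 0` returns the input
#' unchanged.
#'
#' @param depth numeric matrix.
#' @param sigma standard deviation in pixels (>= 0).
#' @return smoothed matrix.
#' @export
smooth_depth <- function(depth, sigma = 2) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(depth)
  gauss_blur_cpp(depth, sigma)
}

#' Assemble the 66-channel processed cube
#'
#' Channels 1..33 are the albedo frames by ascending wavelength; channels
#' 34..66 the smoothed depth maps in the same band order.
#'
#' @param products a `photometric_products` (or plain H x W x B albedo array
#'   plus `band_centers_nm`).
#' @param depths H x W x B array of smoothed depth maps.
#' @param band_centers_nm band centers (taken from `products` if absent).
#' @return object of class `processed_cube`: list(values (H x W x 2B),
#'   band_centers_nm).
#' @export
assemble_cube <- function(products, depths, band_centers_nm = NULL) {
  albedo <- if (inherits(products, "photometric_products"))
    products$albedo_cube else products
  band_centers_nm <- band_centers_nm %||% products$band_centers_nm
  if (!identical(dim(albedo), dim(depths)))
    stop("albedo and depth band counts (or shapes) disagree")
  if (dim(albedo)[3] != length(band_centers_nm))
    stop("band_centers_nm length must match the band count")
  vals <- array(0, c(dim(albedo)[1:2], 2L * dim(albedo)[3]))
  vals[, , seq_len(dim(albedo)[3])] <- albedo
  vals[, , dim(albedo)[3] + seq_len(dim(albedo)[3])] <- depths
  structure(list(values = vals, band_centers_nm = band_centers_nm),
            class = "processed_cube")
}

#' RGB reconstruction from three albedo channels
#'
#' @param cube a `processed_cube`.
#' @param band_triplet indices (1-based, into the 33 albedo channels) used as
#'   R, G, B. Default: bands nearest 650, 550 and 480 nm.
#' @return H x W x 3 array in `[0, 1]` (per channel min-max scaled).
#' @export
render_rgb <- function(cube, band_triplet = NULL) {
  nb <- length(cube$band_centers_nm)
  band_triplet <- band_triplet %||% vapply(c(650, 550, 480), function(nm)
    nearest_band(cube$band_centers_nm, nm), integer(1))
  if (any(band_triplet < 1L | band_triplet > nb))
    stop("band_triplet indices must be within the albedo channels")
  out <- array(0, c(dim(cube$values)[1:2], 3L))
  for (i in 1:3) {
    ch <- cube$values[, , band_triplet[i]]
    rng <- range(ch)
    out[, , i] <- if (diff(rng) > 0) (ch - rng[1]) / diff(rng) else 0
  }
  out
}

#' Full raw-image pre-processing of one capture set
#'
#' Streams band by band (memory stays modest even at the device's full
#' 1605 x 1640 resolution): flat-field calibration of the three light
#' directions, per-band Lambertian photometric stereo, Frankot-Chellappa
#' depth integration, Gaussian smoothing, and assembly of the 66-channel
#' processed cube (33 albedo + 33 skin-surface model frames).
#'
#' @param capture a `raw_capture`.
#' @param sigma Gaussian smoothing of the depth maps (px).
#' @param boundary depth-integration boundary handling, see
#'   [integrate_depth()].
#' @return a `processed_cube` with attribute `shadow_fraction` (per-band
#'   fraction of shadow-flagged pixels).
#' @export
preprocess_capture <- function(capture, sigma = 2,
                               boundary = c("periodic", "mirror")) {
  boundary <- match.arg(boundary)
  sensor <- capture$sensor
  H <- sensor$height_px; W <- sensor$width_px
  nb <- length(sensor$wavelengths_nm)
  nvis <- sensor$vis_band_count
  L <- capture$light_geometry
  if (abs(det(L)) < 1e-10) stop("singular light matrix")
  Linv_t <- t(solve(L))
  vals <- array(0, c(H, W, 2L * nb))
  shadow_frac <- numeric(nb)
  for (b in seq_len(nb)) {
    grp <- if (b <= nvis) "vis" else "vnir"
    i <- if (b <= nvis) b else b - nvis
    I3 <- matrix(0, H * W, 3)
    for (l in 1:3) {
      rc <- calibrate_reflectance(capture$raw[[grp]][[l]][, , i],
                                  capture$dark_frame,
                                  capture$white_frames[[grp]][, , i])
      I3[, l] <- rc$values
    }
    s <- solve_ps_band(I3, Linv_t)
    vals[, , b] <- s$albedo
    shadow_frac[b] <- mean(s$shadow)
    normals <- array(s$normals, c(H, W, 3))
    z <- integrate_depth(normals, valid = matrix(!s$shadow, H, W),
                         boundary = boundary)
    vals[, , nb + b] <- smooth_depth(z, sigma)
  }
  out <- structure(list(values = vals,
                        band_centers_nm = sensor$wavelengths_nm),
                   class = "processed_cube")
  attr(out, "shadow_fraction") <- shadow_frac
  out
}
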