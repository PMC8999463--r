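#' Select the 34 machine-learning channels
#'
#' All 33 albedo channels plus the single most informative skin-surface
#' (depth) frame — the one whose band center is nearest `surface_band_nm`
#' (575 nm by default; ties go to the lower wavelength).
#'
#' @param cube a `processed_cube` (66 channels).
#' @param surface_band_nm wavelength of the surface frame to keep.
#' @return object of class `feature_cube`: list(values (H x W x 34),
#'   band_centers_nm, surface_band_nm, normalized = FALSE).
#' @export
select_channels <- function(cube, surface_band_nm = 575) {
  nb <- length(cube$band_centers_nm)
  if (dim(cube$values)[3] != 2L * nb || 2L * nb != 66L)
    stop("expected a 66-channel processed cube")
  k <- nearest_band(cube$band_centers_nm, surface_band_nm)
  vals <- array(0, c(dim(cube$values)[1:2], nb + 1L))
  vals[, , seq_len(nb)] <- cube$values[, , seq_len(nb)]
  vals[, , nb + 1L] <- cube$values[, , nb + k]
  structure(list(values = vals, band_centers_nm = cube$band_centers_nm,
                 surface_band_nm = cube$band_centers_nm[k],
                 normalized = FALSE),
            class = "feature_cube")
}

#' Normalize feature channels to \[0, 1\]
#'
#' Non-finite values are set to 0 first; channels are then min-max scaled
#' using the pixels inside the field of view (out-of-view pixels carry no
#' signal and would otherwise distort the range) and clamped to `[0, 1]`.
#' Constant channels become all zero.
#'
#' With `scope = "grouped"` (default) the 33 albedo channels share a single
#' min/max — they are physically commensurate reflectances, and a common
#' affine map preserves the inter-band spectral shape the classifier relies
#' on — while the surface-model channel (different units) is scaled on its
#' own. `scope = "per_channel"` scales every channel independently.
#'
#' @param fcube a `feature_cube`.
#' @param fov logical matrix; default all pixels.
#' @param scope `"grouped"` or `"per_channel"`.
#' @return the normalized `feature_cube` (`normalized = TRUE`).
#' @export
normalize_features <- function(fcube, fov = NULL,
                               scope = c("grouped", "per_channel")) {
  scope <- match.arg(scope)
  vals <- fcube$values
  vals[!is.finite(vals)] <- 0
  H <- dim(vals)[1]; W <- dim(vals)[2]
  nch <- dim(vals)[3]
  fov <- fov %||% matrix(TRUE, H, W)
  groups <- if (scope == "grouped" && nch == 34L)
    list(seq_len(33L), 34L) else as.list(seq_len(nch))
  for (chs in groups) {
    v <- vals[, , chs, drop = FALSE]
    sel <- array(fov, dim(v))
    rng <- range(v[sel])
    vals[, , chs] <- if (diff(rng) > 0)
      clamp((v - rng[1]) / diff(rng), 0, 1) else 0
  }
  fcube$values <- vals
  fcube$normalized <- TRUE
  fcube
}

#' Vertical train/test split through the lesion centroid
#'
#' The frame is sliced at the annotation's centroid column: columns left of
#' the slice form the training half, the slice column and everything right of
#' it the test half. Masks are sliced identically.
#'
#' @param fcube a `feature_cube`.
#' @param masks a `mask_set`.
#' @return list with elements `train` and `test`, each a list(cube, masks,
#'   side, cols).
#' @export
split_vertical <- function(fcube, masks) {
  if (!any(masks$lesion_core)) stop("lesion core is empty")
  slice <- round(mean(which(masks$annotation, arr.ind = TRUE)[, 2]))
  W <- dim(fcube$values)[2]
  if (slice < 2L || slice > W)
    stop("degenerate slice column; lesion touches the frame edge")
  halves <- list(train = seq_len(slice - 1L), test = slice:W)
  out <- lapply(names(halves), function(side) {
    cols <- halves[[side]]
    hc <- fcube
    hc$values <- fcube$values[, cols, , drop = FALSE]
    hm <- slice_mask_set(masks, cols)
    if (!any(hm$lesion_core))
      stop(sprintf("the %s half contains no lesion-core pixels", side))
    list(cube = hc, masks = hm, side = side, cols = cols)
  })
  names(out) <- names(halves)
  out
}
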