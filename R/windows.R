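# Window samples are stored compactly: a data frame of center coordinates,
# labels and flip codes, plus the feature cubes they index into. Patches are
# materialised on demand by get_patches(), which keeps cohort-scale training
# sets within desk memory.

new_window_set <- function(samples, cubes, window) {
  structure(list(samples = samples, cubes = cubes, window = as.integer(window)),
            class = "window_set")
}

#' Number of samples in a window set
#' @param ws a `window_set`.
#' @export
n_samples <- function(ws) nrow(ws$samples)

# Center convention for an even window side w: the "middle pixel" sits at
# 0-based offset (w/2, w/2) of the patch, i.e. the patch covers rows
# [r - w/2, r + w/2 - 1] (1-based, half-open upper side).
window_offset <- function(window) as.integer(floor(window / 2))

eligible_center_range <- function(n, window) {
  off <- window_offset(window)
  c(off + 1L, n - window + 1L + off)
}

#' Enumerate rolling-window centers over a frame
#'
#' Yields every field-of-view pixel whose `window` x `window` patch fits
#' inside the frame, in row-major order (stride 1).
#'
#' @param cube a `feature_cube` (or plain 3D array).
#' @param fov logical matrix.
#' @param window window side (default 30).
#' @return list(centers = n x 2 integer matrix (row, col), window).
#' @export
rolling_windows <- function(cube, fov, window = 30L) {
  vals <- if (inherits(cube, "feature_cube")) cube$values else cube
  H <- dim(vals)[1]; W <- dim(vals)[2]
  if (window > min(H, W)) stop("window larger than the frame")
  rr <- eligible_center_range(H, window)
  cr <- eligible_center_range(W, window)
  sub <- fov[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  idx <- which(t(sub))  # transpose => row-major enumeration
  nsc <- ncol(sub)
  centers <- cbind(row = (idx - 1L) %/% nsc + rr[1],
                   col = (idx - 1L) %% nsc + cr[1])
  list(centers = centers, window = as.integer(window))
}

# Extract one patch (with optional flip) from a cube.
extract_patch <- function(vals, r, c0, window, flip = "none") {
  off <- window_offset(window)
  p <- vals[(r - off):(r - off + window - 1L),
            (c0 - off):(c0 - off + window - 1L), , drop = FALSE]
  flip_patch(p, flip)
}

flip_patch <- function(p, flip) {
  if (flip %in% c("h", "hv")) p <- p[, dim(p)[2]:1, , drop = FALSE]
  if (flip %in% c("v", "hv")) p <- p[dim(p)[1]:1, , , drop = FALSE]
  p
}

#' Materialise the patches of a window set
#'
#' @param ws a `window_set`.
#' @param idx sample indices (default all).
#' @return window x window x channels x n array (flips applied).
#' @export
get_patches <- function(ws, idx = seq_len(n_samples(ws))) {
  w <- ws$window
  C <- dim(ws$cubes[[1]])[3]
  out <- array(0, c(w, w, C, length(idx)))
  for (i in seq_along(idx)) {
    s <- ws$samples[idx[i], ]
    out[, , , i] <- extract_patch(ws$cubes[[s$cube_id]], s$row, s$col, w, s$flip)
  }
  out
}

#' Random window sampling from the lesion core and healthy region
#'
#' Samples `n_lesion` lesion-core and `n_healthy` healthy-region center
#' pixels uniformly without replacement, among centers whose window fits
#' inside the (half-)frame. Deterministic given `seed`.
#'
#' @param half one element of [split_vertical()] output (list(cube, masks,
#'   side)).
#' @param lesion_label class label assigned to lesion-core samples.
#' @param n_lesion,n_healthy per-region quotas (defaults 250 / 100).
#' @param window window side (default 30).
#' @param seed integer.
#' @return a `window_set` whose samples carry label, center and side.
#' @export
sample_windows <- function(half, lesion_label, n_lesion = 250L,
                           n_healthy = 100L, window = 30L, seed = 1L) {
  vals <- half$cube$values
  H <- dim(vals)[1]; W <- dim(vals)[2]
  rr <- eligible_center_range(H, window)
  cr <- eligible_center_range(W, window)
  fits <- matrix(FALSE, H, W)
  fits[rr[1]:rr[2], cr[1]:cr[2]] <- TRUE
  pick <- function(region, n, what) {
    elig <- which(region & fits)
    if (length(elig) < n)
      stop(sprintf("insufficient eligible %s centers: need %d, have %d (short by %d)",
                   what, n, length(elig), n - length(elig)))
    with_seed(seed + match(what, c("lesion", "healthy")),
              sort(sample(elig, n)))
  }
  li <- pick(half$masks$lesion_core, n_lesion, "lesion")
  hi <- pick(half$masks$healthy_region, n_healthy, "healthy")
  samples <- data.frame(
    cube_id = 1L,
    row = c((li - 1L) %% H + 1L, (hi - 1L) %% H + 1L),
    col = c((li - 1L) %/% H + 1L, (hi - 1L) %/% H + 1L),
    label = c(rep(lesion_label, n_lesion), rep("healthy", n_healthy)),
    flip = "none",
    side = half$side,
    stringsAsFactors = FALSE)
  new_window_set(samples, list(vals), window)
}

#' Concatenate window sets (e.g. across lesions)
#' @param ws_list list of `window_set`s with equal window and channel count.
#' @return a single `window_set`.
#' @export
bind_window_sets <- function(ws_list) {
  stopifnot(length(ws_list) > 0)
  w <- ws_list[[1]]$window
  cubes <- list(); samples <- list()
  offset <- 0L
  for (k in seq_along(ws_list)) {
    ws <- ws_list[[k]]
    stopifnot(ws$window == w)
    s <- ws$samples
    s$cube_id <- s$cube_id + offset
    samples[[k]] <- s
    cubes <- c(cubes, ws$cubes)
    offset <- offset + length(ws$cubes)
  }
  new_window_set(do.call(rbind, samples), cubes, w)
}
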