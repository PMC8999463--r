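# Shared fixtures: desk-scale sensors, a flat scene for forward-model
# identities, and a small CNN config that keeps training tests fast.

desk_sensor <- function(size = 128L, noise_sd = NULL) {
  if (is.null(noise_sd)) sensor_config(size, size)
  else sensor_config(size, size, noise_sd = noise_sd)
}

# A flat phantom with constant albedo and full field of view.
flat_phantom <- function(size = 64L, albedo = 1, nb = 33L) {
  wl <- default_wavelengths()
  scene_phantom(
    height_map = matrix(0, size, size),
    lesion_mask = matrix(FALSE, size, size),
    fov_mask = matrix(TRUE, size, size),
    lesion_class = "MM",
    spectra = list(healthy = rep(albedo, nb), lesion = rep(albedo, nb)),
    class_weight = matrix(0, size, size),
    texture = matrix(1, size, size),
    wavelengths_nm = wl)
}

# Small dual-branch config: same structure as the default, fewer filters.
small_model_overrides <- function(...) {
  utils::modifyList(
    list(conv3d_spec = list(list(filters = 4L, kernel = c(3L, 3L, 7L)),
                            list(filters = 8L, kernel = c(3L, 3L, 5L))),
         conv2d_spec = list(list(filters = 4L, kernel = c(3L, 3L)),
                            list(filters = 8L, kernel = c(3L, 3L))),
         dense_units = c(32L),
         max_epochs = 4L, patience = 4L),
    list(...))
}

# Constant-level separable toy patches (3 classes by mean level).
toy_patches <- function(n_per_class, levels = c(0.2, 0.5, 0.8),
                        labels = c("MM", "PN", "healthy"), sd = 0.02,
                        seed = 7) {
  k <- length(levels)
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    x <- array(0, c(30, 30, 34, k * n_per_class))
    for (i in seq_len(k))
      x[, , , (i - 1) * n_per_class + seq_len(n_per_class)] <-
        rnorm(30 * 30 * 34 * n_per_class, mean = levels[i], sd = sd)
    list(patches = x, labels = rep(labels, each = n_per_class))
  })
}

# Deterministic shuffle + split of a toy set.
toy_split <- function(toy, n_train, seed = 3) {
  set.seed(seed)
  idx <- sample(length(toy$labels))
  tr <- idx[seq_len(n_train)]
  va <- idx[(n_train + 1):length(idx)]
  list(train = list(patches = toy$patches[, , , tr, drop = FALSE],
                    labels = toy$labels[tr]),
       val = list(patches = toy$patches[, , , va, drop = FALSE],
                  labels = toy$labels[va]))
}

# Cohort config used by the scaled-down end-to-end tests (128 px frames).
desk_cohort_config <- function(sensor, ...) {
  cohort_config(sensor = sensor, n_lesion_px = 60L, n_healthy_px = 24L,
                model = small_model_overrides(...))
}
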