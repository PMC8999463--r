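disk_mask <- function(n, r, cy = n / 2, cx = n / 2) {
  yy <- matrix(seq_len(n), n, n) - cy
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  sqrt(yy^2 + xx^2) <= r
}

sqdist_near <- function(mask, r) {
  # brute-force "within r of the mask" via the package-independent route
  d2 <- r^2
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -r:r) {
    w <- floor(sqrt(d2 - dr^2))
    for (dc in -w:w) {
      rr <- pmin(pmax(idx[, 1] + dr, 1), nrow(mask))
      cc <- pmin(pmax(idx[, 2] + dc, 1), ncol(mask))
      out[cbind(rr, cc)] <- TRUE
    }
  }
  out
}

test_that("mask construction enforces the sampling-region geometry", {
  n <- 320
  ann <- disk_mask(n, 100)
  fov <- disk_mask(n, 155)
  expect_error(build_masks(matrix(FALSE, n, n), fov), "empty")
  expect_error(build_masks(ann, disk_mask(n, 50)), "field of view")
  expect_error(build_masks(disk_mask(n, 20), fov, erosion_px = 30),
               "smaller erosion")

  ms <- build_masks(ann, fov, erosion_px = 30, margin_px = 60,
                    annulus_outer_px = 200)
  # erosion by 30 of a radius-100 disk ~ radius-70 disk
  expect_lt(abs(sum(ms$lesion_core) - pi * 70^2) / (pi * 70^2), 0.05)

  # no healthy pixel within 60 px of the annotation boundary
  near <- sqdist_near(ann, 60)
  expect_false(any(ms$healthy_region & near))
  # disjointness
  expect_false(any(ms$lesion_core & ms$healthy_region))
  expect_false(any(ms$exclusion_band & ms$lesion_core))
  expect_false(any(ms$exclusion_band & ms$healthy_region))
  expect_true(all(ms$healthy_region <= fov))

  # annulus clipped by the fov edge stays disjoint from the exclusion band
  ann2 <- disk_mask(n, 60, cy = 120, cx = 120)
  ms2 <- build_masks(ann2, fov, erosion_px = 20, margin_px = 40,
                     annulus_outer_px = 500)
  expect_false(any(ms2$exclusion_band & ms2$healthy_region))
  expect_true(any(ms2$healthy_region))
})

fake_cube <- function(H, W, fill = NULL) {
  wl <- default_wavelengths()
  v <- if (is.null(fill)) array(stats::runif(H * W * 66), c(H, W, 66))
  else array(fill, c(H, W, 66))
  structure(list(values = v, band_centers_nm = wl), class = "processed_cube")
}

test_that("channel selection keeps 33 albedos plus the 575 nm surface frame", {
  set.seed(5)
  cube <- fake_cube(12, 12)
  fc <- select_channels(cube)
  expect_equal(dim(fc$values)[3], 34L)
  k <- which.min(abs(cube$band_centers_nm - 575))
  expect_identical(fc$values[, , 34], cube$values[, , 33 + k])
  expect_identical(fc$values[, , 1:33], cube$values[, , 1:33])
  expect_equal(fc$surface_band_nm, cube$band_centers_nm[k])

  fc2 <- select_channels(cube, surface_band_nm = 891)
  expect_identical(fc2$values[, , 34], cube$values[, , 66])

  bad <- cube; bad$values <- bad$values[, , 1:40]
  expect_error(select_channels(bad), "66-channel")
})

test_that("normalization maps to [0,1] and zeroes non-finite input", {
  wl <- default_wavelengths()
  v <- array(0, c(4, 4, 34))
  v[, , 1] <- matrix(c(2, 3, 4, 2, 3, 4, 2, 3, 4, 2, 3, 4, 2, 3, 4, 2), 4, 4)
  v[1, 1, 2] <- NaN; v[2, 2, 2] <- Inf; v[3, 3, 2] <- 4
  v[, , 34] <- matrix(seq_len(16), 4, 4)
  fc <- structure(list(values = v, band_centers_nm = wl,
                       surface_band_nm = 575, normalized = FALSE),
                  class = "feature_cube")

  # per-channel scope: {2,3,4} -> {0, 0.5, 1}; non-finites zeroed first
  npc <- normalize_features(fc, scope = "per_channel")
  expect_equal(sort(unique(as.vector(npc$values[, , 1]))), c(0, 0.5, 1))
  expect_equal(npc$values[1, 1, 2], 0)
  expect_equal(npc$values[2, 2, 2], 0)
  expect_equal(npc$values[3, 3, 2], 1)
  expect_equal(max(abs(npc$values[, , 3])), 0)  # constant channel -> zeros
  expect_true(all(npc$values >= 0 & npc$values <= 1))

  # grouped scope: albedo channels share one affine map
  ng <- normalize_features(fc)
  expect_true(ng$normalized)
  expect_equal(range(ng$values[, , 1:33]), c(0, 1))
  expect_equal(range(ng$values[, , 34]), c(0, 1))
  # shape preserved up to a single affine map
  expect_equal(stats::cor(as.vector(ng$values[, , 1]), as.vector(v[, , 1])), 1)
})

test_that("vertical slicing partitions the frame through the lesion centroid", {
  n <- 96
  ann <- disk_mask(n, 20)
  fov <- disk_mask(n, 44)
  ms <- build_masks(ann, fov, erosion_px = 3, margin_px = 6,
                    annulus_outer_px = 16)
  wl <- default_wavelengths()
  v <- array(stats::runif(n * n * 34), c(n, n, 34))
  fc <- structure(list(values = v, band_centers_nm = wl,
                       surface_band_nm = 575, normalized = TRUE),
                  class = "feature_cube")
  halves <- split_vertical(fc, ms)
  expect_identical(halves$train$side, "train")
  # symmetric disk: halves have nearly equal lesion-core areas
  a1 <- sum(halves$train$masks$lesion_core)
  a2 <- sum(halves$test$masks$lesion_core)
  expect_lte(abs(a1 - a2), max(colSums(ms$lesion_core)))  # +/- 1 column
  # partition: disjoint and reassembles to the original
  expect_equal(ncol(halves$train$cube$values) + ncol(halves$test$cube$values), n)
  reassembled <- array(0, dim(v))
  reassembled[, halves$train$cols, ] <- halves$train$cube$values
  reassembled[, halves$test$cols, ] <- halves$test$cube$values
  expect_identical(reassembled, v)
})

test_that("rolling windows enumerate exactly the in-frame centers", {
  v <- array(stats::runif(100 * 100 * 3), c(100, 100, 3))
  fov <- matrix(TRUE, 100, 100)
  rw <- rolling_windows(v, fov, window = 30L)
  expect_equal(nrow(rw$centers), 71L * 71L)
  expect_equal(range(rw$centers[, 1]), c(16L, 86L))
  # row-major order
  expect_identical(rw$centers[1:3, 2], c(16L, 17L, 18L))
  expect_identical(rw$centers[1:3, 1], c(16L, 16L, 16L))

  # fov-restricted: no out-of-fov centers
  fov2 <- disk_mask(100, 20)
  rw2 <- rolling_windows(v, fov2, window = 30L)
  expect_true(all(fov2[rw2$centers]))
  expect_equal(nrow(rw2$centers), sum(fov2[16:86, 16:86]))

  # identical patches at identical centers
  p1 <- hsiderm:::extract_patch(v, 40, 50, 30L)
  p2 <- hsiderm:::extract_patch(v, 40, 50, 30L)
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(30L, 30L, 3L))
  expect_error(rolling_windows(v, fov, window = 101L), "larger")
})

# build one split lesion half for the sampling tests
make_half <- function(seed = 1) {
  set.seed(seed)
  n <- 128
  ann <- disk_mask(n, 26)
  fov <- disk_mask(n, 60)
  ms <- build_masks(ann, fov, erosion_px = 4, margin_px = 8,
                    annulus_outer_px = 30)
  wl <- default_wavelengths()
  fc <- structure(list(values = array(stats::runif(n * n * 34), c(n, n, 34)),
                       band_centers_nm = wl, surface_band_nm = 575,
                       normalized = TRUE), class = "feature_cube")
  split_vertical(fc, ms)
}

test_that("window sampling honours quotas, regions and determinism", {
  halves <- make_half()
  ws <- sample_windows(halves$train, "MM", n_lesion = 40, n_healthy = 16,
                       seed = 7)
  expect_equal(n_samples(ws), 56L)
  expect_equal(sum(ws$samples$label == "MM"), 40L)
  expect_equal(sum(ws$samples$label == "healthy"), 16L)

  # labels match the mask region of each center
  for (i in seq_len(n_samples(ws))) {
    s <- ws$samples[i, ]
    reg <- if (s$label == "MM") halves$train$masks$lesion_core
    else halves$train$masks$healthy_region
    expect_true(reg[s$row, s$col])
  }
  # no sampled center inside the exclusion band
  expect_false(any(halves$train$masks$exclusion_band[
    cbind(ws$samples$row, ws$samples$col)]))

  # patches fit the frame and are 30 x 30 x 34
  pat <- get_patches(ws, 1:3)
  expect_identical(dim(pat), c(30L, 30L, 34L, 3L))

  ws2 <- sample_windows(halves$train, "MM", n_lesion = 40, n_healthy = 16,
                        seed = 7)
  expect_identical(ws$samples, ws2$samples)

  expect_error(sample_windows(halves$train, "MM", n_lesion = 1e5),
               "short by")
})

test_that("over-sampling balances counts by duplicating existing rows", {
  halves <- make_half(2)
  ws <- sample_windows(halves$train, "PN", n_lesion = 50, n_healthy = 20,
                       seed = 3)
  # make a third class by relabelling a slice (counts 30/20/20)
  ws$samples$label[1:20] <- "MM"
  ws$samples$label[21:50] <- "PN"
  bal <- balance_oversample(ws, seed = 9)
  expect_equal(unname(table(bal$samples$label)), rep(30L, 3),
               ignore_attr = TRUE)
  # all added rows duplicate existing (cube_id, row, col, label) tuples
  key <- function(df) paste(df$cube_id, df$row, df$col, df$label)
  expect_true(all(key(bal$samples) %in% key(ws$samples)))

  bal2 <- balance_oversample(bal, seed = 1)       # already balanced
  expect_identical(sort(key(bal2$samples)), sort(key(bal$samples)))

  one <- ws; one$samples$label <- "MM"
  expect_error(balance_oversample(one), "two classes")
})

test_that("flip augmentation triples samples and is an involution", {
  halves <- make_half(3)
  ws <- sample_windows(halves$train, "BCC", n_lesion = 10, n_healthy = 5,
                       seed = 2)
  aug <- augment_flips(ws)
  expect_equal(n_samples(aug), 3L * n_samples(ws))
  expect_equal(as.vector(table(aug$samples$label)),
               3L * as.vector(table(ws$samples$label)))

  p <- get_patches(ws, 1)[, , , 1]
  expect_identical(hsiderm:::flip_patch(hsiderm:::flip_patch(
    array(p, c(30, 30, 34)), "h"), "h"), array(p, c(30, 30, 34)))
  # flipped patches really are spatial flips (channels untouched)
  ph <- hsiderm:::flip_patch(array(p, c(30, 30, 34)), "h")
  expect_identical(ph[, 30:1, ], array(p, c(30, 30, 34)))

  # double augmentation composes flips correctly (hv appears)
  aug2 <- augment_flips(aug)
  expect_setequal(unique(aug2$samples$flip), c("none", "h", "v", "hv"))
})

test_that("validation split is stratified, disjoint and deterministic", {
  halves <- make_half(4)
  ws <- sample_windows(halves$train, "SCC", n_lesion = 50, n_healthy = 20,
                       seed = 5)
  sp <- make_validation_split(ws, 0.2, seed = 6)
  expect_equal(n_samples(sp$validation), 14L)  # 10 + 4
  expect_equal(sum(sp$validation$samples$label == "SCC"), 10L)
  key <- function(df) paste(df$row, df$col, df$label)
  expect_length(intersect(key(sp$train$samples), key(sp$validation$samples)), 0L)
  sp2 <- make_validation_split(ws, 0.2, seed = 6)
  expect_identical(sp$validation$samples, sp2$validation$samples)
  expect_error(make_validation_split(ws, 0.001), "empty stratum")
  expect_error(make_validation_split(ws, 1.2), "in \\(0, 1\\)")
})
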