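#' Cohort-level pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Morphology radii default to
#' the full-resolution values (30 / 60 / 200 px at 1605 x 1640, 24 um/px)
#' scaled by `height_px / 1605`, i.e. the same physical millimetres at any
#' frame size.
#'
#' @param sensor a [sensor_config()].
#' @param lights a [light_geometry()].
#' @param erosion_px,margin_px,annulus_outer_px mask radii; `NULL` = scaled
#'   defaults.
#' @param sigma depth smoothing (px).
#' @param boundary depth-integration boundary mode.
#' @param surface_band_nm surface frame wavelength (575).
#' @param n_lesion_px,n_healthy_px per-half sampling quotas (250 / 100).
#' @param window window side (30).
#' @param val_fraction stratified validation fraction (0.2).
#' @param model list of [model_config()] overrides (e.g. smaller filters for
#'   desk-scale runs).
#' @param lesion_radius_px phantom lesion radius; `NULL` = [make_phantom()]
#'   default.
#' @param phantom see [phantom_params()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(sensor = sensor_config(), lights = light_geometry(),
                          erosion_px = NULL, margin_px = NULL,
                          annulus_outer_px = NULL, sigma = 2,
                          boundary = "periodic", surface_band_nm = 575,
                          n_lesion_px = 250L, n_healthy_px = 100L,
                          window = 30L, val_fraction = 0.2,
                          model = list(), lesion_radius_px = NULL,
                          phantom = phantom_params()) {
  scale <- sensor$height_px / 1605
  structure(list(
    sensor = sensor, lights = lights,
    erosion_px = erosion_px %||% max(1L, round(30 * scale)),
    margin_px = margin_px %||% max(2L, round(60 * scale)),
    annulus_outer_px = annulus_outer_px %||% max(4L, round(200 * scale)),
    sigma = sigma, boundary = boundary, surface_band_nm = surface_band_nm,
    n_lesion_px = as.integer(n_lesion_px),
    n_healthy_px = as.integer(n_healthy_px),
    window = as.integer(window), val_fraction = val_fraction,
    model = model, lesion_radius_px = lesion_radius_px, phantom = phantom),
    class = "cohort_config")
}

group_classes <- function(classifier_group) {
  switch(classifier_group,
         pigmented = c("MM", "PN", "healthy"),
         nonpigmented = c("BCC", "SCC", "ID", "healthy"),
         stop("classifier_group must be 'pigmented' or 'nonpigmented'"))
}

# Pre-process one lesion down to normalized train/test halves + window sets.
prep_lesion <- function(lesion, config, seed) {
  cube <- preprocess_capture(lesion$capture, sigma = config$sigma,
                             boundary = config$boundary)
  fov <- lesion$phantom$fov_mask %||%
    (r_center_dist(dim(cube$values)[1], dim(cube$values)[2]) <=
       min(dim(cube$values)[1:2]) / 2 - 4)
  masks <- build_masks(lesion$annotation, fov,
                       erosion_px = config$erosion_px,
                       margin_px = config$margin_px,
                       annulus_outer_px = config$annulus_outer_px)
  fc <- normalize_features(select_channels(cube, config$surface_band_nm), fov)
  halves <- split_vertical(fc, masks)
  seeds <- derive_seeds(seed, 2L)
  list(
    halves = halves,
    train_ws = sample_windows(halves$train, lesion$label,
                              config$n_lesion_px, config$n_healthy_px,
                              config$window, seeds[1]),
    test_ws = sample_windows(halves$test, lesion$label,
                             config$n_lesion_px, config$n_healthy_px,
                             config$window, seeds[2]))
}

#' End-to-end synthetic cohort run
#'
#' Orchestrates the full pipeline on a cohort: photometric pre-processing,
#' mask construction, channel selection and normalization, vertical
#' train/test split, window sampling, stratified validation split, random
#' over-sampling, flip augmentation, CNN training, pixel-wise test metrics,
#' and per-lesion majority voting over annotated test-half pixels. Fully
#' seeded and deterministic (single-threaded).
#'
#' @param cohort output of [make_cohort()] (or a list with the same fields).
#' @param classifier_group `"pigmented"` (MM / PN / healthy) or
#'   `"nonpigmented"` (BCC / SCC / ID / healthy).
#' @param config a [cohort_config()].
#' @param seed integer.
#' @return object of class `cohort_report`: list(metrics (a
#'   `metrics_report`), lesions (per-lesion votes), model, class_order, seed,
#'   counts).
#' @export
run_cohort <- function(cohort, classifier_group, config = cohort_config(),
                       seed = 1L) {
  class_order <- group_classes(classifier_group)
  lesion_types <- setdiff(class_order, "healthy")
  labels <- vapply(cohort, `[[`, character(1), "label")
  if (!all(labels %in% lesion_types))
    stop("cohort labels outside the ", classifier_group, " group: ",
         paste(setdiff(labels, lesion_types), collapse = ", "))
  seeds <- derive_seeds(seed, length(cohort) + 3L)

  preps <- lapply(seq_along(cohort), function(i)
    prep_lesion(cohort[[i]], config, seeds[i]))

  train_all <- bind_window_sets(lapply(preps, `[[`, "train_ws"))
  test_all <- bind_window_sets(lapply(preps, `[[`, "test_ws"))

  sp <- make_validation_split(train_all, config$val_fraction,
                              seed = seeds[length(cohort) + 1L])
  trn <- augment_flips(balance_oversample(sp$train,
                                          seed = seeds[length(cohort) + 2L]))

  margs <- utils::modifyList(
    list(n_classes = length(class_order), seed = seeds[length(cohort) + 3L]),
    config$model)
  model <- build_model(do.call(model_config, margs), class_order)
  model <- train_model(model, trn, sp$validation)

  probs <- predict(model, test_all)
  pred <- class_order[max.col(probs)]
  metrics <- pixelwise_metrics(pred, test_all$samples$label, class_order)

  lesions <- lapply(seq_along(cohort), function(i) {
    h <- preps[[i]]$halves$test
    map <- classification_map(model, h$cube, h$masks$fov_mask,
                              region = h$masks$annotation,
                              window = config$window)
    mv <- majority_vote(map, h$masks$annotation, lesion_types)
    list(id = cohort[[i]]$id, true_label = cohort[[i]]$label,
         majority_label = mv$label, counts = mv$counts,
         correct = mv$label == cohort[[i]]$label, map = map)
  })

  structure(list(
    metrics = metrics, lesions = lesions, model = model,
    class_order = class_order, seed = seed,
    counts = c(n_lesions = length(cohort),
               n_train_windows = n_samples(train_all),
               n_test_windows = n_samples(test_all),
               n_validation = n_samples(sp$validation),
               n_train_final = n_samples(trn)),
    votes_correct = sum(vapply(lesions, `[[`, logical(1), "correct"))),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d lesions, %d test windows\n",
              x$counts["n_lesions"], x$counts["n_test_windows"]))
  cat(sprintf("Pixel-wise weighted: sens %.3f spec %.3f ppv %.3f f1 %.3f\n",
              x$metrics$weighted["sensitivity"],
              x$metrics$weighted["specificity"],
              x$metrics$weighted["ppv"], x$metrics$weighted["f1"]))
  cat(sprintf("Majority voting: %d / %d lesions correct\n",
              x$votes_correct, x$counts["n_lesions"]))
  invisible(x)
}
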