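test_that("pixelwise metrics match a brute-force tally exactly", {
  classes <- c("MM", "PN", "healthy")
  expect_error(pixelwise_metrics(c("MM"), c("MM", "PN"), classes),
               "equal length")
  expect_error(pixelwise_metrics(c("XX"), c("MM"), classes), "outside")

  # perfect prediction => all rates 1
  t0 <- rep(classes, times = c(5, 3, 2))
  mp <- pixelwise_metrics(t0, t0, classes)
  expect_equal(unname(mp$weighted), rep(1, 4))
  expect_true(all(mp$per_class[, c("sensitivity", "specificity", "ppv", "f1")] == 1))

  # hand-computed 2x2 case: confusion [[50,10],[5,35]] => weighted sens 0.85
  pred <- c(rep("A", 50), rep("B", 10), rep("A", 5), rep("B", 35))
  truth <- c(rep("A", 60), rep("B", 40))
  # (needs a 3/4-class-free path: metrics are class-count agnostic)
  m2 <- pixelwise_metrics(pred, truth, c("A", "B"))
  expect_equal(unname(m2$weighted["sensitivity"]), 0.85)
  expect_equal(unname(m2$confusion["A", "B"]), 10)
  expect_equal(sum(m2$confusion), 100)

  # single-class truth => specificity undefined (flagged, reported 0)
  m1 <- pixelwise_metrics(rep("A", 5), rep("A", 5), c("A", "B"))
  expect_true(m1$per_class$undefined[m1$per_class$class == "A"])
  expect_equal(m1$per_class$specificity[m1$per_class$class == "A"], 0)

  # oracle equivalence: 10 seeds x 1000 random labels, exact agreement
  for (s in 1:10) {
    set.seed(s)
    truth <- sample(classes, 1000, replace = TRUE)
    pred <- ifelse(runif(1000) < 0.7, truth, sample(classes, 1000, TRUE))
    rep_m <- pixelwise_metrics(pred, truth, classes)
    orc <- oracle_metrics(pred, truth, classes)
    expect_identical(unname(rep_m$per_class$support), unname(orc[, "support"]))
    expect_identical(unname(rep_m$per_class$sensitivity), unname(orc[, "sens"]))
    expect_identical(unname(rep_m$per_class$specificity), unname(orc[, "spec"]))
    expect_identical(unname(rep_m$per_class$ppv), unname(orc[, "ppv"]))
    expect_identical(unname(rep_m$per_class$f1), unname(orc[, "f1"]))
    # confusion conservation + weighted sensitivity == overall accuracy
    expect_identical(unname(rowSums(rep_m$confusion)),
                     unname(orc[, "support"]))
    expect_equal(unname(rep_m$weighted["sensitivity"]), mean(pred == truth))
    w <- orc[, "support"] / 1000
    expect_equal(unname(rep_m$weighted["f1"]), sum(w * orc[, "f1"]))
  }
})

fake_map <- function(labels_mat, class_order) {
  cm <- matrix(match(labels_mat, class_order), nrow(labels_mat))
  conf <- ifelse(is.na(cm), NA_real_, 0.9)
  structure(list(class_map = cm, confidence_map = conf,
                 class_order = class_order),
            class = "classification_map")
}

test_that("majority voting counts lesion classes and breaks ties by malignancy", {
  co <- c("MM", "PN", "healthy")
  ann <- matrix(TRUE, 40, 25)

  m <- fake_map(matrix(rep(c("MM", "PN", "healthy"),
                           times = c(600, 399, 1)), 40, 25), co)
  v <- majority_vote(m, ann)
  expect_identical(v$label, "MM")
  expect_equal(unname(v$counts["MM"]), 600)
  expect_equal(v$n_voted, 999)  # healthy recorded but excluded from the vote

  # ties: malignancy priority MM > PN and SCC > BCC > ID
  co4 <- c("BCC", "SCC", "ID", "healthy")
  m4 <- fake_map(matrix(rep(c("SCC", "BCC", "ID"), times = c(10, 10, 3)),
                        1, 23), co4)
  expect_identical(majority_vote(m4, matrix(TRUE, 1, 23))$label, "SCC")
  m2 <- fake_map(matrix(rep(c("MM", "PN"), times = c(5, 5)), 1, 10), co)
  expect_identical(majority_vote(m2, matrix(TRUE, 1, 10))$label, "MM")

  # errors: nothing predicted / only healthy predictions
  none <- fake_map(matrix(NA_character_, 4, 4), co)
  expect_error(majority_vote(none, matrix(TRUE, 4, 4)), "no predictions")
  hl <- fake_map(matrix("healthy", 4, 4), co)
  expect_error(majority_vote(hl, matrix(TRUE, 4, 4)), "lesion-type")

  # determinism: identical maps => identical votes
  expect_identical(majority_vote(m, ann), majority_vote(m, ann))
})

test_that("classification maps cover exactly the eligible region", {
  # quick-to-train toy model on constant-level patches
  toy <- toy_patches(40, levels = c(0.2, 0.8), labels = c("MM", "healthy"))
  toy$labels <- c(toy$labels, "PN")  # keep 3 classes for the softmax
  toy$patches <- array(c(toy$patches,
                         array(0.5, c(30, 30, 34, 1))), c(30, 30, 34, 81))
  cfg <- do.call(model_config,
                 small_model_overrides(n_classes = 3L, seed = 3,
                                       max_epochs = 6L, patience = 6L))
  m <- train_model(build_model(cfg, c("MM", "PN", "healthy")),
                   list(patches = toy$patches, labels = toy$labels),
                   list(patches = toy$patches[, , , c(1:10, 41:50)],
                        labels = toy$labels[c(1:10, 41:50)]))

  expect_error(classification_map(build_model(cfg, c("MM", "PN", "healthy")),
                                  NULL, NULL), "trained")

  # constant healthy-level image => uniform class map inside the region
  n <- 72
  fc <- structure(list(values = array(0.8, c(n, n, 34)),
                       band_centers_nm = default_wavelengths(),
                       surface_band_nm = 575, normalized = TRUE),
                  class = "feature_cube")
  fov <- matrix(TRUE, n, n)
  cmap <- classification_map(m, fc, fov)
  inside <- !is.na(cmap$class_map)
  rr <- 16:(n - 14)
  expect_true(all(inside[rr, rr]))
  expect_true(all(is.na(cmap$class_map[1:15, ])))
  expect_equal(unique(cmap$class_map[inside]),
               match("healthy", m$class_order))
  expect_true(all(cmap$confidence_map[inside] >= 1 / 3))

  # restricted region: no predictions outside it
  region <- matrix(FALSE, n, n); region[30:40, 30:40] <- TRUE
  cm2 <- classification_map(m, fc, fov, region = region)
  expect_true(all(is.na(cm2$class_map[!region])))
})

test_that("reports round-trip through the report writer", {
  dir <- withr::local_tempdir()
  co <- c("MM", "PN", "healthy")
  pred <- rep(c("MM", "PN", "healthy"), times = c(30, 40, 30))
  truth <- rep(c("MM", "PN", "healthy"), times = c(35, 40, 25))
  metrics <- pixelwise_metrics(pred, truth, co)
  map <- fake_map(matrix(rep(c("MM", NA), 50), 10, 10), co)
  report <- structure(list(
    metrics = metrics, class_order = co, seed = 1,
    lesions = list(list(id = "lesion_01_MM", true_label = "MM",
                        majority_label = "MM", correct = TRUE,
                        counts = table(factor(c("MM", "MM", "PN"), levels = co)),
                        map = map)),
    counts = c(n_lesions = 1, n_test_windows = 100),
    votes_correct = 1), class = "cohort_report")
  write_report(report, dir)

  cm <- utils::read.csv(file.path(dir, "confusion.csv"), row.names = 1)
  expect_identical(unname(as.matrix(cm)), unname(unclass(metrics$confusion)))
  votes <- jsonlite::read_json(file.path(dir, "votes.json"),
                               simplifyVector = TRUE)
  expect_identical(votes$majority_label, "MM")
  expect_true(file.exists(file.path(dir, "map_lesion_01_MM.ppm")))
  legend <- jsonlite::read_json(file.path(dir, "map_legend.json"),
                                simplifyVector = TRUE)
  expect_length(legend$classes, length(co) + 1L)  # one per class + none
})

test_that("mask PGM files round-trip", {
  dir <- withr::local_tempdir()
  set.seed(4)
  m <- matrix(runif(32 * 48) > 0.5, 32, 48)
  f <- file.path(dir, "mask.pgm")
  write_mask_pgm(m, f)
  expect_identical(read_mask_pgm(f), m)
})

test_that("window sets and model checkpoints round-trip", {
  dir <- withr::local_tempdir()
  halves <- NULL
  # small window set over a random cube
  set.seed(9)
  wl <- default_wavelengths()
  ws <- hsiderm:::new_window_set(
    data.frame(cube_id = 1L, row = c(20L, 25L), col = c(22L, 30L),
               label = c("MM", "healthy"), flip = c("none", "h"),
               side = "train", stringsAsFactors = FALSE),
    list(array(runif(64 * 64 * 34), c(64, 64, 34))), 30L)
  write_window_set(ws, file.path(dir, "ws"))
  ws2 <- read_window_set(file.path(dir, "ws"))
  expect_identical(ws2$samples, ws$samples)
  expect_identical(get_patches(ws2), get_patches(ws))

  # model checkpoint: identical predictions after reload
  cfg <- do.call(model_config, small_model_overrides(n_classes = 3L, seed = 2))
  m <- build_model(cfg, c("MM", "PN", "healthy"))
  f <- file.path(dir, "model.rds")
  save_model(m, f)
  m2 <- load_model(f)
  x <- array(runif(30 * 30 * 34 * 4), c(30, 30, 34, 4))
  expect_identical(predict(m2, x), predict(m, x))
  manifest <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_identical(manifest$class_order, m$class_order)
  expect_identical(manifest$n_classes, 3L)
})
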