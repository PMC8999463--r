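# Plain binary PGM/PPM writers and readers. The production device stores
# captures as TIFF stacks; no TIFF/PNG codec is assumed here, so masks and
# maps use netpbm formats (lossless, universally readable) and numeric cubes
# round-trip through RDS, always with a JSON sidecar.

#' Write a binary mask as 8-bit PGM (255 = foreground)
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_pgm <- function(mask, path) {
  write_pgm(ifelse(mask, 255L, 0L), path, maxval = 255L)
}

#' Read an 8-bit PGM as a logical mask (> 127 = TRUE)
#' @param path PGM file.
#' @export
read_mask_pgm <- function(path) read_pgm(path) > 127

write_pgm <- function(img, path, maxval = 255L) {
  img <- round(img)
  if (any(img < 0 | img > maxval)) stop("pixel values outside [0, maxval]")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  vals <- as.integer(t(img))  # row-major per the format
  if (maxval < 256) writeBin(as.raw(vals), con)
  else writeBin(vals, con, size = 2, endian = "big")
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (magic != "P5") stop("only binary PGM (P5) is supported")
  hdr <- c()
  while (length(hdr) < 3) {
    ln <- readLines(con, n = 1)
    ln <- sub("#.*", "", ln)
    hdr <- c(hdr, as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  vals <- if (maxval < 256) as.integer(readBin(con, "raw", w * h))
  else readBin(con, "integer", w * h, size = 2, signed = FALSE, endian = "big")
  matrix(vals, h, w, byrow = TRUE)
}

write_ppm <- function(rgb, path) {
  # rgb: H x W x 3 in [0, 1]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(dim(rgb)[2], dim(rgb)[1]), "255"), con)
  v <- round(255 * clamp(rgb, 0, 1))
  inter <- aperm(v, c(3, 2, 1))  # channel fastest, then col, then row
  writeBin(as.raw(as.integer(inter)), con)
}

#' Persist a raw capture set
#'
#' Writes the six raw band stacks, the references and a JSON sidecar
#' (wavelengths, light vectors, reference levels) into a directory.
#' @param capture a `raw_capture`.
#' @param dir output directory (created).
#' @export
write_capture <- function(capture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(capture[c("raw", "dark_frame", "white_frames")],
          file.path(dir, "frames.rds"))
  sensor <- capture$sensor
  jsonlite::write_json(list(
    wavelengths_nm = sensor$wavelengths_nm,
    vis_band_count = sensor$vis_band_count,
    light_directions = unclass(capture$light_geometry),
    dark_level = sensor$dark_level, white_level = sensor$white_level,
    noise_sd = sensor$noise_sd, height_px = sensor$height_px,
    width_px = sensor$width_px, pixel_pitch_um = sensor$pixel_pitch_um),
    file.path(dir, "capture.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a persisted raw capture set
#' @param dir directory written by [write_capture()].
#' @export
read_capture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "capture.json"),
                              simplifyVector = TRUE)
  frames <- readRDS(file.path(dir, "frames.rds"))
  sensor <- sensor_config(meta$height_px, meta$width_px, meta$wavelengths_nm,
                          meta$vis_band_count, meta$dark_level,
                          meta$white_level, meta$noise_sd,
                          meta$pixel_pitch_um)
  structure(c(frames, list(light_geometry = meta$light_directions,
                           sensor = sensor)),
            class = "raw_capture")
}

#' Persist a processed cube (66 channels + sidecar)
#' @param cube a `processed_cube`.
#' @param path RDS path; a `.json` sidecar is written next to it.
#' @export
write_cube <- function(cube, path) {
  saveRDS(cube, path)
  jsonlite::write_json(list(band_centers_nm = cube$band_centers_nm,
                            channels = dim(cube$values)[3],
                            layout = "1..33 albedo, 34..66 surface model"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cohort report to disk
#'
#' Metrics and confusion matrices as CSV, per-lesion votes as JSON, and the
#' per-lesion class maps as indexed PPM images with a JSON colour legend.
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics$per_class,
                   file.path(dir, "metrics_per_class.csv"), row.names = FALSE)
  utils::write.csv(data.frame(metric = names(report$metrics$weighted),
                              value = as.numeric(report$metrics$weighted)),
                   file.path(dir, "metrics_weighted.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame.matrix(report$metrics$confusion),
                   file.path(dir, "confusion.csv"))
  votes <- lapply(report$lesions, function(l)
    list(id = l$id, true_label = l$true_label,
         majority_label = l$majority_label,
         correct = l$correct,
         counts = as.list(setNames(as.integer(l$counts), names(l$counts)))))
  jsonlite::write_json(votes, file.path(dir, "votes.json"),
                       auto_unbox = TRUE, digits = NA)
  # indexed class maps: palette entry per class + background for NA
  palette <- rbind(c(0, 0, 0),            # no prediction
                   t(grDevices::col2rgb(
                     grDevices::hcl.colors(length(report$class_order),
                                           "Dark 3")) / 255))
  jsonlite::write_json(
    list(classes = c("(none)", report$class_order),
         rgb = apply(round(palette * 255), 1, paste, collapse = ",")),
    file.path(dir, "map_legend.json"), auto_unbox = TRUE)
  for (l in report$lesions) {
    cm <- l$map$class_map
    idx <- ifelse(is.na(cm), 1L, cm + 1L)
    rgb <- array(0, c(nrow(cm), ncol(cm), 3))
    for (ch in 1:3) rgb[, , ch] <- matrix(palette[idx, ch], nrow(cm))
    write_ppm(rgb, file.path(dir, paste0("map_", l$id, ".ppm")))
  }
  invisible(dir)
}

#' Persist a window-sample set
#'
#' Patches stay compact (center coordinates + the cubes they index); the JSON
#' manifest records labels, centers, flips, sides and the window size.
#'
#' @param ws a `window_set`.
#' @param dir output directory (created).
#' @export
write_window_set <- function(ws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ws$cubes, file.path(dir, "cubes.rds"))
  utils::write.csv(ws$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(window = ws$window, n = n_samples(ws),
                            labels = as.list(table(ws$samples$label)),
                            channels = dim(ws$cubes[[1]])[3]),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read back a persisted window-sample set
#' @param dir directory written by [write_window_set()].
#' @export
read_window_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             stringsAsFactors = FALSE)
  new_window_set(samples, readRDS(file.path(dir, "cubes.rds")),
                 manifest$window)
}

#' Save a (trained) model checkpoint
#'
#' Weights go to RDS next to a JSON manifest describing the architecture and
#' class order.
#'
#' @param model an `hsi_cnn`.
#' @param path RDS path; `<path>.json` is written alongside.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$config
  jsonlite::write_json(list(
    n_classes = cfg$n_classes, class_order = model$class_order,
    trained = model$trained, input_shape = cfg$input_shape,
    conv3d = lapply(cfg$conv3d_spec, function(l)
      list(filters = l$filters, kernel = l$kernel)),
    conv2d = lapply(cfg$conv2d_spec, function(l)
      list(filters = l$filters, kernel = l$kernel)),
    dense_units = cfg$dense_units, leaky_slope = cfg$leaky_slope,
    learning_rate = cfg$learning_rate, seed = cfg$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path RDS path written by [save_model()].
#' @export
load_model <- function(path) readRDS(path)
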