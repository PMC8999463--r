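# Binary disk morphology via the exact Euclidean distance transform.

dilate_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  sqdist_transform_cpp(mask) <= r^2
}

erode_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  sqdist_transform_cpp(!mask) > r^2
}

#' Sampling-region masks from a lesion annotation
#'
#' Reproduces the ground-truth mask construction: the annotation is eroded by
#' `erosion_px` into the lesion binary map (drops uncertainly labelled border
#' pixels), a `margin_px`-wide band around the lesion border is excluded from
#' all sampling, and healthy skin is drawn from an annular region between the
#' margin and `annulus_outer_px` beyond the lesion, inside the eroded field
#' of view (peripheral image areas have the worst surface-model quality).
#' Defaults are the full-resolution (1605 x 1640, 24 um/px) values; scale
#' them with the frame for desk-size syntheses (see [cohort_config()]).
#'
#' @param annotation logical matrix, ground-truth lesion annotation.
#' @param fov logical matrix, field-of-view mask.
#' @param erosion_px disk radius of the annotation erosion (default 30).
#' @param margin_px excluded band at the lesion border (default 60).
#' @param annulus_outer_px outer reach of the healthy annulus beyond the
#'   annotation (default 200).
#' @return object of class `mask_set`: list(annotation, lesion_core,
#'   exclusion_band, healthy_region, fov_mask, params).
#' @export
build_masks <- function(annotation, fov, erosion_px = 30L, margin_px = 60L,
                        annulus_outer_px = 200L) {
  stopifnot(is.logical(annotation) || all(annotation %in% c(0, 1)))
  annotation <- annotation > 0
  fov <- fov > 0
  if (!any(annotation)) stop("annotation is empty")
  if (any(annotation & !fov))
    stop("annotation must be contained in the field of view")
  lesion_core <- erode_disk(annotation, erosion_px)
  if (!any(lesion_core))
    stop(sprintf(paste0("lesion core is empty after erosion by %d px; use a ",
                        "smaller erosion radius or a larger lesion"),
                 erosion_px))
  dil_margin <- dilate_disk(annotation, margin_px)
  exclusion_band <- dil_margin & !lesion_core
  healthy_region <- dilate_disk(annotation, annulus_outer_px) &
    !dil_margin & erode_disk(fov, erosion_px)
  structure(list(annotation = annotation, lesion_core = lesion_core,
                 exclusion_band = exclusion_band,
                 healthy_region = healthy_region, fov_mask = fov,
                 params = list(erosion_px = erosion_px, margin_px = margin_px,
                               annulus_outer_px = annulus_outer_px)),
            class = "mask_set")
}

# Subset every mask in a mask_set to a column range.
slice_mask_set <- function(masks, cols) {
  out <- masks
  for (f in c("annotation", "lesion_core", "exclusion_band",
              "healthy_region", "fov_mask"))
    out[[f]] <- masks[[f]][, cols, drop = FALSE]
  out
}
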