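#' Pixel-wise classification and confidence maps
#'
#' Runs the rolling-window extractor over the field of view (optionally
#' restricted further by `region`) and predicts every eligible center pixel.
#' The class map holds the argmax label index, the confidence map the maximum
#' softmax probability; pixels without a prediction carry `NA`. Restricting
#' to the field of view avoids the accuracy bias from out-of-view pixels.
#'
#' @param model a trained `hsi_cnn`.
#' @param fcube a normalized `feature_cube` (34 channels).
#' @param fov logical matrix.
#' @param region optional logical matrix to restrict the predicted pixels
#'   (e.g. the annotated lesion area when only a majority vote is needed).
#' @param window window side (default 30).
#' @param batch_size forward-pass batch size.
#' @return object of class `classification_map`: list(class_map (integer
#'   matrix, `NA` = no prediction), confidence_map, class_order).
#' @export
classification_map <- function(model, fcube, fov, region = NULL,
                               window = 30L, batch_size = 512L) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  if (isFALSE(fcube$normalized))
    warning("feature cube does not appear to be normalized")
  mask <- if (is.null(region)) fov else (fov & region)
  rw <- rolling_windows(fcube, mask, window)
  H <- dim(fcube$values)[1]; W <- dim(fcube$values)[2]
  class_map <- matrix(NA_integer_, H, W)
  conf_map <- matrix(NA_real_, H, W)
  n <- nrow(rw$centers)
  if (n > 0) {
    for (k in seq_len(ceiling(n / batch_size))) {
      idx <- ((k - 1) * batch_size + 1):min(k * batch_size, n)
      patches <- array(0, c(window, window, dim(fcube$values)[3], length(idx)))
      for (i in seq_along(idx))
        patches[, , , i] <- extract_patch(fcube$values, rw$centers[idx[i], 1],
                                          rw$centers[idx[i], 2], window)
      pr <- predict(model, patches)
      ci <- max.col(pr)
      lin <- rw$centers[idx, 1] + (rw$centers[idx, 2] - 1L) * H
      class_map[lin] <- ci
      conf_map[lin] <- pr[cbind(seq_along(idx), ci)]
    }
  }
  structure(list(class_map = class_map, confidence_map = conf_map,
                 class_order = model$class_order),
            class = "classification_map")
}

# clinical tie-break priority: over-calling malignancy is the safer error
malignancy_priority <- function() c(MM = 5, SCC = 4, BCC = 3, PN = 2, ID = 1)

#' Majority-vote lesion diagnosis
#'
#' Tallies the predicted classes over annotated lesion pixels (test half).
#' Only lesion-type classes enter the vote; healthy-skin predictions are
#' recorded for diagnostics but excluded. Ties are broken by malignancy
#' priority (MM > PN; SCC > BCC > ID).
#'
#' @param map a `classification_map`.
#' @param annotation logical matrix of annotated lesion pixels (same frame).
#' @param lesion_classes_used lesion-type labels eligible for the vote.
#' @return list(label, counts (all classes incl. healthy), n_voted).
#' @export
majority_vote <- function(map, annotation,
                          lesion_classes_used = intersect(map$class_order,
                                                          lesion_classes())) {
  sel <- annotation & !is.na(map$class_map)
  if (!any(sel)) stop("no predictions inside the annotated region")
  labs <- map$class_order[map$class_map[sel]]
  counts <- table(factor(labs, levels = map$class_order))
  vote <- counts[lesion_classes_used]
  if (sum(vote) == 0) stop("no lesion-type predictions inside the annotated region")
  best <- which(vote == max(vote))
  if (length(best) > 1) {
    pr <- malignancy_priority()[names(vote)[best]]
    best <- best[which.max(pr)]
  }
  list(label = names(vote)[best], counts = counts, n_voted = sum(vote))
}
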