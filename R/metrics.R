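#' One-vs-rest classification metrics with confusion matrices
#'
#' Per class (one-vs-rest): sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)`, and
#' `F1 = 2*PPV*Sens/(PPV+Sens)`. Weighted aggregates are support-weighted
#' means (support = truth counts); note that "weighted specificity" is a
#' definition of this package, not a standard library aggregate. Ratios with
#' a zero denominator are reported as 0 and flagged.
#'
#' @param predictions,truth character/factor vectors of equal length with
#'   levels inside `class_order`.
#' @param class_order class labels fixing row/column order.
#' @return object of class `metrics_report`: list(per_class data.frame,
#'   weighted named vector, confusion (counts, rows = truth), confusion_norm
#'   (row-normalized), n).
#' @export
pixelwise_metrics <- function(predictions, truth, class_order) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  bad <- setdiff(unique(c(as.character(predictions), as.character(truth))),
                 class_order)
  if (length(bad)) stop("labels outside class_order: ", paste(bad, collapse = ", "))
  p <- factor(predictions, levels = class_order)
  t0 <- factor(truth, levels = class_order)
  cm <- table(truth = t0, predicted = p)
  n <- length(truth)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  ppv <- safe(tp, tp + fp)
  f1 <- safe(2 * ppv * sens, ppv + sens)
  flagged <- (tp + fn == 0) | (tn + fp == 0) | (tp + fp == 0) | (ppv + sens == 0)
  per_class <- data.frame(class = class_order, support = as.numeric(rowSums(cm)),
                          sensitivity = as.numeric(sens),
                          specificity = as.numeric(spec),
                          ppv = as.numeric(ppv), f1 = as.numeric(f1),
                          undefined = as.logical(flagged),
                          row.names = NULL)
  wsupport <- rowSums(cm) / n
  weighted <- c(sensitivity = sum(wsupport * sens),
                specificity = sum(wsupport * spec),
                ppv = sum(wsupport * ppv),
                f1 = sum(wsupport * f1))
  cm_norm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  structure(list(per_class = per_class, weighted = weighted,
                 confusion = unclass(cm), confusion_norm = unclass(cm_norm),
                 n = n),
            class = "metrics_report")
}
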