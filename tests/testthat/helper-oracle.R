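# Brute-force one-vs-rest metrics oracle: plain loops over label pairs.
oracle_metrics <- function(pred, truth, classes) {
  n <- length(truth)
  out <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fn <- sum(pred != cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
    c(support = tp + fn, sens = sens, spec = spec, ppv = ppv, f1 = f1)
  })
  do.call(rbind, out)
}

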