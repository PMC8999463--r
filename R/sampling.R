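#' Random over-sampling to balance class counts
#'
#' Duplicates randomly chosen minority-class samples until every class count
#' equals the majority count (the classic random over-sampler). Deterministic
#' given `seed`.
#'
#' @param ws a `window_set` (training side).
#' @param seed integer.
#' @return a balanced `window_set`; every added row duplicates an existing one.
#' @export
balance_oversample <- function(ws, seed = 1L) {
  counts <- table(ws$samples$label)
  if (length(counts) < 2L)
    stop("over-sampling needs at least two classes")
  maj <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      need <- maj - counts[[cl]]
      if (need == 0) return(integer(0))
      rows <- which(ws$samples$label == cl)
      sample(rows, need, replace = TRUE)
    }))
  })
  ws$samples <- rbind(ws$samples, ws$samples[extra, , drop = FALSE])
  rownames(ws$samples) <- NULL
  ws
}

flip_compose <- function(a, b) {
  # composition table of the flip group {none, h, v, hv}
  m <- matrix(c("none", "h",  "v",  "hv",
                "h",  "none", "hv", "v",
                "v",  "hv", "none", "h",
                "hv", "v",  "h",  "none"),
              4, 4, byrow = TRUE,
              dimnames = list(c("none", "h", "v", "hv"),
                              c("none", "h", "v", "hv")))
  m[cbind(a, b)]
}

#' Flip augmentation
#'
#' Output = originals plus their vertical flips plus their horizontal flips
#' (spatial axes only; the channel order is untouched), tripling the sample
#' count. Labels and centers are preserved.
#'
#' @param ws a `window_set`.
#' @return a `window_set` with `3 * n` samples.
#' @export
augment_flips <- function(ws) {
  s <- ws$samples
  sh <- s; sh$flip <- flip_compose(s$flip, "h")
  sv <- s; sv$flip <- flip_compose(s$flip, "v")
  ws$samples <- rbind(s, sv, sh)
  rownames(ws$samples) <- NULL
  ws
}

#' Stratified validation split
#'
#' Splits a training window set by class into train/validation parts before
#' any balancing or augmentation (so no duplicate can leak into validation).
#' Deterministic given `seed`.
#'
#' @param ws a `window_set`.
#' @param fraction validation fraction in (0, 1); 0.2 reproduces the printed
#'   1400-of-7000 and 1540-of-7700 validation sizes.
#' @param seed integer.
#' @return list(train, validation), both `window_set`s.
#' @export
make_validation_split <- function(ws, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  labs <- ws$samples$label
  val_idx <- with_seed(seed, {
    unlist(lapply(unique(labs), function(cl) {
      rows <- which(labs == cl)
      nv <- round(length(rows) * fraction)
      if (nv == 0 || nv == length(rows))
        stop(sprintf("fraction %.3f yields an empty stratum for class %s",
                     fraction, cl))
      sample(rows, nv)
    }))
  })
  val <- ws; val$samples <- ws$samples[val_idx, , drop = FALSE]
  trn <- ws; trn$samples <- ws$samples[-val_idx, , drop = FALSE]
  rownames(val$samples) <- rownames(trn$samples) <- NULL
  list(train = trn, validation = val)
}
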