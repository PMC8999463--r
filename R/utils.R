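`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds (< 2^31) deterministically from a parent seed.
derive_seeds <- function(seed, n) with_seed(seed, sample.int(.Machine$integer.max - 1L, n))

# Index of the band center nearest `nm`; ties go to the lower wavelength.
nearest_band <- function(band_centers_nm, nm) {
  d <- abs(band_centers_nm - nm)
  which(d == min(d))[1L]
}
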