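# Internal neural-network plumbing: branch forward/backward passes over the
# compiled im2col convolution and pooling kernels, dense layers, softmax
# cross-entropy, and Adam. All tensors are R arrays dim c(H, W, D, C, B).

# Dense-layer activations (small matrices; the conv branches use the fused
# in-place C++ kernels instead).
leaky <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
leaky_grad <- function(x, slope) slope + (1 - slope) * (x > 0)

conv_weight <- function(kh, kw, kd, cin, filters) {
  k <- kh * kw * kd * cin
  W <- matrix(stats::rnorm(k * filters, sd = sqrt(2 / k)), k, filters)
  attr(W, "kdim") <- c(kh, kw, kd)
  W
}

# Forward through one conv branch; returns output + cache for backprop.
# Activations are applied in place on the freshly allocated conv output; the
# cached post-activation tensor `a` determines the LeakyReLU gradient
# (a > 0 <=> pre-activation > 0 for slope > 0).
branch_forward <- function(x, layers, pools, slope) {
  cache <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    a <- conv3d_fw_cpp(x, dim(x), layers[[i]]$W, layers[[i]]$b)
    leaky_inplace_cpp(a, slope)
    mp <- maxpool_fw_cpp(a, dim(a), pools[[i]])
    cache[[i]] <- list(x = x, a = a, argmax = mp$argmax)
    x <- mp$y
  }
  list(out = x, cache = cache)
}

branch_backward <- function(dout, layers, pools, slope, cache) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    cc <- cache[[i]]
    dy <- maxpool_bw_cpp(dout, cc$argmax, dim(cc$a))
    leaky_gradmul_cpp(dy, cc$a, slope)
    bw <- conv3d_bw_cpp(cc$x, dim(cc$x), layers[[i]]$W, dy)
    grads[[i]] <- list(W = bw$dW, b = bw$db)
    dout <- bw$dx
  }
  list(grads = grads, dx = dout)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass. patches: (w, w, 34, B). Returns probs (+ cache).
nn_forward <- function(params, cfg, patches, want_cache = FALSE) {
  if (length(dim(patches)) == 3L)
    patches <- array(patches, c(dim(patches), 1L))
  d <- dim(patches)
  B <- d[4]
  nb <- d[3] - 1L
  x3 <- array(patches[, , seq_len(nb), ], c(d[1], d[2], nb, 1L, B))
  x2 <- array(patches[, , nb + 1L, ], c(d[1], d[2], 1L, 1L, B))
  f3 <- branch_forward(x3, params$b3, cfg$pool3d, cfg$leaky_slope)
  f2 <- branch_forward(x2, params$b2, cfg$pool2d, cfg$leaky_slope)
  flat <- cbind(t(matrix(f3$out, ncol = B)), t(matrix(f2$out, ncol = B)))
  acts <- list(flat)
  zs <- list()
  a <- flat
  nd <- length(params$dense)
  for (i in seq_len(nd)) {
    z <- sweep(a %*% params$dense[[i]]$W, 2, params$dense[[i]]$b, "+")
    zs[[i]] <- z
    a <- if (i < nd) leaky(z, cfg$leaky_slope) else z
    acts[[i + 1L]] <- a
  }
  probs <- softmax_rows(a)
  if (!want_cache) return(probs)
  list(probs = probs,
       cache = list(f3 = f3, f2 = f2, acts = acts, zs = zs,
                    n3 = ncol(flat) - prod(dim(f2$out)[1:4]),
                    d3 = dim(f3$out), d2 = dim(f2$out), B = B))
}

# Backward pass; y_onehot: B x K. Returns gradients shaped like params.
nn_backward <- function(params, cfg, fw, y_onehot) {
  cc <- fw$cache
  B <- cc$B
  dz <- (fw$probs - y_onehot) / B
  nd <- length(params$dense)
  dgrads <- vector("list", nd)
  for (i in rev(seq_len(nd))) {
    a_prev <- cc$acts[[i]]
    dgrads[[i]] <- list(W = crossprod(a_prev, dz), b = colSums(dz))
    da <- dz %*% t(params$dense[[i]]$W)
    if (i > 1L) dz <- da * leaky_grad(cc$zs[[i - 1L]], cfg$leaky_slope)
  }
  dflat <- da
  n3 <- cc$n3
  d3 <- cc$d3; d2 <- cc$d2
  dout3 <- array(t(dflat[, seq_len(n3), drop = FALSE]), d3)
  dout2 <- array(t(dflat[, (n3 + 1L):ncol(dflat), drop = FALSE]), d2)
  g3 <- branch_backward(dout3, params$b3, cfg$pool3d, cfg$leaky_slope, cc$f3$cache)
  g2 <- branch_backward(dout2, params$b2, cfg$pool2d, cfg$leaky_slope, cc$f2$cache)
  list(b3 = g3$grads, b2 = g2$grads, dense = dgrads)
}

# --- flat parameter-list helpers (for Adam) ---------------------------------

flatten_params <- function(p) {
  out <- list()
  for (br in c("b3", "b2"))
    for (i in seq_along(p[[br]]))
      for (nm in c("W", "b"))
        out[[paste(br, i, nm, sep = ".")]] <- p[[br]][[i]][[nm]]
  for (i in seq_along(p$dense))
    for (nm in c("W", "b"))
      out[[paste("dense", i, nm, sep = ".")]] <- p$dense[[i]][[nm]]
  out
}

assign_flat <- function(p, flat) {
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[2])
    attr_save <- attr(p[[parts[1]]][[i]][[parts[3]]], "kdim")
    p[[parts[1]]][[i]][[parts[3]]] <- flat[[key]]
    if (!is.null(attr_save)) attr(p[[parts[1]]][[i]][[parts[3]]], "kdim") <- attr_save
  }
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(flat)) {
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    flat[[key]] <- flat[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}
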