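#' Dual-branch CNN configuration
#'
#' The classifier mirrors the published architecture sketch: a 3D-convolution
#' branch over the 33-band albedo patch (spectral + spatial features), a
#' 2D-convolution branch over the 575 nm skin-surface frame, LeakyReLU
#' activations and max pooling in both branches, then flatten, concatenate,
#' dense hidden layers and a softmax output with 3 (pigmented) or 4
#' (non-pigmented) classes. Exact layer counts and filter numbers are not
#' published; the defaults are a CPU-sized instantiation of that structure
#' and everything is configurable.
#'
#' @param n_classes 3 or 4.
#' @param conv3d_spec list of 3D conv layers, each `list(filters, kernel =
#'   c(h, w, bands))`.
#' @param pool3d list of 3D max-pool sizes, one per conv layer.
#' @param conv2d_spec,pool2d same for the 2D branch (`kernel = c(h, w)`).
#' @param dense_units hidden dense layer widths.
#' @param leaky_slope LeakyReLU negative slope (default 0.1).
#' @param learning_rate,batch_size,max_epochs,patience Adam learning rate
#'   (default parameters: 0.001, beta1 0.9, beta2 0.999), minibatch size,
#'   epoch cap and early-stopping patience on validation loss.
#' @param seed integer; fixes weight initialisation and batch shuffling.
#' @param input_shape patch shape c(height, width, channels); channel count
#'   must be bands + 1.
#' @return object of class `hsi_model_config`.
#' @export
model_config <- function(n_classes = 3L,
                         conv3d_spec = list(list(filters = 8L, kernel = c(3L, 3L, 7L)),
                                            list(filters = 16L, kernel = c(3L, 3L, 5L))),
                         pool3d = list(c(2L, 2L, 2L), c(2L, 2L, 2L)),
                         conv2d_spec = list(list(filters = 8L, kernel = c(3L, 3L)),
                                            list(filters = 16L, kernel = c(3L, 3L))),
                         pool2d = list(c(2L, 2L), c(2L, 2L)),
                         dense_units = c(128L, 64L),
                         leaky_slope = 0.1, learning_rate = 1e-3,
                         batch_size = 64L, max_epochs = 50L, patience = 10L,
                         seed = 1L, input_shape = c(30L, 30L, 34L)) {
  if (!n_classes %in% c(3L, 4L)) stop("n_classes must be 3 or 4")
  stopifnot(length(conv3d_spec) == length(pool3d),
            length(conv2d_spec) == length(pool2d))
  cfg <- list(n_classes = as.integer(n_classes),
              conv3d_spec = conv3d_spec,
              pool3d = lapply(pool3d, as.integer),
              conv2d_spec = conv2d_spec,
              pool2d = lapply(pool2d, function(p) as.integer(c(p, 1L))),
              dense_units = as.integer(dense_units),
              leaky_slope = leaky_slope, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed),
              input_shape = as.integer(input_shape))
  # promote 2D kernels to depth-1 3D kernels
  cfg$conv2d_spec <- lapply(cfg$conv2d_spec, function(l) {
    l$kernel <- as.integer(c(l$kernel, 1L)); l
  })
  cfg$conv3d_spec <- lapply(cfg$conv3d_spec, function(l) {
    l$kernel <- as.integer(l$kernel); l
  })
  # shape check: walk both branches
  cfg$flat3 <- check_branch(c(input_shape[1:2], input_shape[3] - 1L, 1L),
                            cfg$conv3d_spec, cfg$pool3d, "3D")
  cfg$flat2 <- check_branch(c(input_shape[1:2], 1L, 1L),
                            cfg$conv2d_spec, cfg$pool2d, "2D")
  structure(cfg, class = "hsi_model_config")
}

check_branch <- function(shape, spec, pools, what) {
  for (i in seq_along(spec)) {
    k <- spec[[i]]$kernel
    if (any(shape[1:3] < k))
      stop(sprintf("%s branch layer %d: kernel (%s) exceeds input dims (%s)",
                   what, i, paste(k, collapse = "x"),
                   paste(shape[1:3], collapse = "x")))
    shape <- c(shape[1:3] - k + 1L, spec[[i]]$filters)
    p <- pools[[i]]
    if (any(shape[1:3] < p))
      stop(sprintf("%s branch layer %d: pool (%s) exceeds conv output (%s)",
                   what, i, paste(p, collapse = "x"),
                   paste(shape[1:3], collapse = "x")))
    shape <- c(shape[1:3] %/% p, shape[4])
  }
  prod(shape)
}

#' Build an untrained dual-branch CNN
#'
#' @param config a [model_config()].
#' @param class_order character vector of class labels defining the softmax
#'   column order (length `n_classes`). The group conventions are
#'   `c("MM", "PN", "healthy")` and `c("BCC", "SCC", "ID", "healthy")`.
#' @return object of class `hsi_cnn` (untrained; `$trained = FALSE`).
#' @export
build_model <- function(config, class_order = paste0("class", seq_len(config$n_classes))) {
  if (length(class_order) != config$n_classes)
    stop("class_order length must equal n_classes")
  params <- with_seed(config$seed, {
    mk_branch <- function(spec, cin) {
      lapply(spec, function(l) {
        W <- conv_weight(l$kernel[1], l$kernel[2], l$kernel[3], cin, l$filters)
        cin <<- l$filters
        list(W = W, b = numeric(l$filters))
      })
    }
    b3 <- mk_branch(config$conv3d_spec, 1L)
    b2 <- mk_branch(config$conv2d_spec, 1L)
    sizes <- c(config$flat3 + config$flat2, config$dense_units,
               config$n_classes)
    dense <- lapply(seq_len(length(sizes) - 1L), function(i) {
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                   sd = sqrt(2 / sizes[i])),
                      sizes[i], sizes[i + 1]),
           b = numeric(sizes[i + 1]))
    })
    list(b3 = b3, b2 = b2, dense = dense)
  })
  structure(list(config = config, class_order = class_order, params = params,
                 trained = FALSE, training_log = NULL),
            class = "hsi_cnn")
}

# Normalise training inputs: window_set or list(patches, labels).
as_training_data <- function(x) {
  if (inherits(x, "window_set")) {
    list(n = n_samples(x),
         labels = x$samples$label,
         batch = function(idx) get_patches(x, idx))
  } else if (is.list(x) && !is.null(x$patches)) {
    d <- dim(x$patches)
    stopifnot(length(d) == 4L)
    list(n = d[4], labels = x$labels,
         batch = function(idx) x$patches[, , , idx, drop = FALSE])
  } else stop("training data must be a window_set or list(patches, labels)")
}

#' Train the dual-branch CNN
#'
#' Minimises categorical cross-entropy with Adam (default parameters), early
#' stopping on validation loss, deterministic given the config seed
#' (single-threaded BLAS assumed). The best-validation-loss weights are
#' restored on return.
#'
#' @param model an untrained (or trained) `hsi_cnn`.
#' @param train,val training and validation data: `window_set`s or
#'   `list(patches = 30 x 30 x 34 x N array, labels = character)`.
#' @param quiet suppress per-epoch messages.
#' @return the trained `hsi_cnn` with `$training_log` (per-epoch loss and
#'   accuracy) and `$trained = TRUE`.
#' @export
train_model <- function(model, train, val, quiet = TRUE) {
  cfg <- model$config
  tr <- as_training_data(train)
  va <- as_training_data(val)
  if (tr$n == 0 || va$n == 0) stop("train and validation sets must be non-empty")
  bad <- setdiff(unique(c(tr$labels, va$labels)), model$class_order)
  if (length(bad))
    stop("labels outside class_order: ", paste(bad, collapse = ", "))
  K <- cfg$n_classes
  onehot <- function(labs)
    diag(K)[match(labs, model$class_order), , drop = FALSE]
  y_tr <- onehot(tr$labels)

  flat <- flatten_params(model$params)
  state <- adam_init(flat)
  params <- model$params
  shuffle_seeds <- derive_seeds(cfg$seed + 1L, cfg$max_epochs)
  best <- list(loss = Inf, flat = flat, log = NULL)
  wait <- 0L
  log <- data.frame()

  eval_data <- function(dat, p) {
    nb <- ceiling(dat$n / 256)
    loss <- 0; correct <- 0
    yy <- onehot(dat$labels)
    for (k in seq_len(nb)) {
      idx <- ((k - 1) * 256 + 1):min(k * 256, dat$n)
      pr <- nn_forward(p, cfg, dat$batch(idx))
      loss <- loss - sum(log(pmax(pr[cbind(seq_along(idx),
                                           max.col(yy[idx, , drop = FALSE]))],
                                  1e-12)))
      correct <- correct + sum(max.col(pr) == max.col(yy[idx, , drop = FALSE]))
    }
    c(loss = loss / dat$n, acc = correct / dat$n)
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(shuffle_seeds[epoch], sample.int(tr$n))
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, tr$n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, tr$n)]
      xb <- tr$batch(idx)
      yb <- y_tr[idx, , drop = FALSE]
      fw <- nn_forward(params, cfg, xb, want_cache = TRUE)
      grads <- nn_backward(params, cfg, fw, yb)
      upd <- adam_step(flatten_params(params), flatten_params(grads),
                       state, cfg$learning_rate)
      state <- upd$state
      params <- assign_flat(params, upd$flat)
      ep_loss <- ep_loss -
        sum(log(pmax(fw$probs[cbind(seq_along(idx), max.col(yb))], 1e-12)))
      ep_correct <- ep_correct + sum(max.col(fw$probs) == max.col(yb))
    }
    vm <- eval_data(va, params)
    row <- data.frame(epoch = epoch, train_loss = ep_loss / tr$n,
                      train_acc = ep_correct / tr$n,
                      val_loss = vm[["loss"]], val_acc = vm[["acc"]])
    log <- rbind(log, row)
    if (!quiet)
      message(sprintf("epoch %d: loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, row$train_loss, row$train_acc,
                      row$val_loss, row$val_acc))
    if (vm[["loss"]] < best$loss - 1e-12) {
      best <- list(loss = vm[["loss"]], flat = flatten_params(params))
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- assign_flat(model$params, best$flat)
  model$training_log <- log
  model$trained <- TRUE
  model
}

#' Class probabilities for window patches
#'
#' @param object a trained `hsi_cnn`.
#' @param newdata a `window_set`, a `30 x 30 x 34 x N` array, or a single
#'   `30 x 30 x 34` patch.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return N x n_classes probability matrix (rows sum to 1), columns named by
#'   `class_order`, rows ordered as the input.
#' @export
predict.hsi_cnn <- function(object, newdata, batch_size = 256L, ...) {
  cfg <- object$config
  if (inherits(newdata, "window_set")) {
    dat <- as_training_data(newdata)
  } else {
    if (length(dim(newdata)) == 3L)
      newdata <- array(newdata, c(dim(newdata), 1L))
    d <- dim(newdata)
    if (length(d) != 4L || !all(d[1:3] == cfg$input_shape))
      stop(sprintf("patches must be %s (got %s)",
                   paste(cfg$input_shape, collapse = "x"),
                   paste(d[seq_len(min(3, length(d)))], collapse = "x")))
    dat <- list(n = d[4],
                batch = function(idx) newdata[, , , idx, drop = FALSE])
  }
  out <- matrix(0, dat$n, cfg$n_classes,
                dimnames = list(NULL, object$class_order))
  for (k in seq_len(ceiling(dat$n / batch_size))) {
    idx <- ((k - 1) * batch_size + 1):min(k * batch_size, dat$n)
    out[idx, ] <- nn_forward(object$params, cfg, dat$batch(idx))
  }
  out
}
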