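#' Segmentation network configuration
#'
#' The package's segmentation model is fully convolutional and compact
#' enough to train on a CPU in seconds: a fixed multi-scale feature pyramid
#' (per-pixel RGB plus dilated average-pooling context and local-contrast
#' channels at each rate in `aspp_rates`, in the spirit of atrous spatial
#' pyramid pooling) feeds a trainable two-layer 1 x 1 convolutional head
#' (hidden ReLU layer, 2-channel softmax classifier). Transfer learning
#' keeps the pyramid fixed and retrains the head, warm-starting from a
#' previous stage's weights.
#'
#' @param backbone only `"tiny"` (the pyramid + 1x1-conv head above) is
#'   provided; other values raise an error.
#' @param aspp_rates strictly increasing dilation radii (px) of the context
#'   pooling windows; window size is `2 * rate + 1`.
#' @param num_classes fixed at 2 (fruit / background).
#' @param input_size nominal (height, width) of training frames; the model
#'   is fully convolutional and accepts any size at inference.
#' @param hidden_units width of the trainable hidden 1x1-conv layer.
#' @param pretrained_weights optional path to a saved model whose hidden
#'   layer initialises the new model (the final classifier layer is always
#'   re-initialised, giving the 2-class head).
#' @return A `network_config` object.
#' @export
network_config <- function(backbone = "tiny", aspp_rates = c(1, 2, 4, 8),
                           num_classes = 2L, input_size = c(96L, 96L),
                           hidden_units = 16L, pretrained_weights = NULL) {
  if (!identical(backbone, "tiny"))
    stopf("backbone '%s' is not available; this package provides 'tiny'",
          backbone)
  if (length(aspp_rates) == 0L || any(diff(aspp_rates) <= 0) ||
      any(aspp_rates < 1))
    stopf("aspp_rates must be non-empty, strictly increasing, >= 1")
  if (!identical(as.integer(num_classes), 2L))
    stopf("num_classes is fixed at 2 (fruit / background)")
  if (hidden_units < 2L) stopf("hidden_units must be >= 2")
  structure(list(backbone = backbone, aspp_rates = as.integer(aspp_rates),
                 num_classes = 2L, input_size = as.integer(input_size),
                 hidden_units = as.integer(hidden_units),
                 pretrained_weights = pretrained_weights),
            class = "network_config")
}

#' Training hyperparameters
#'
#' @param epochs passes over the sampled training pixels (>= 1).
#' @param batch_size pixels per gradient step (>= 1).
#' @param learning_rate Adam step size.
#' @param loss only `"pixelwise-cross-entropy"` is provided.
#' @param seed RNG seed for pixel sampling, shuffling and (fresh) weights.
#' @param validation_fraction fraction of training images held out for a
#'   per-epoch validation loss, in \[0, 1).
#' @param pixels_per_image pixels sampled per training image.
#' @return A `train_hyperparams` object.
#' @export
train_hyperparams <- function(epochs = 40L, batch_size = 1024L,
                              learning_rate = 0.01,
                              loss = "pixelwise-cross-entropy",
                              seed = 0L, validation_fraction = 0,
                              pixels_per_image = 600L) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (!identical(loss, "pixelwise-cross-entropy"))
    stopf("loss must be 'pixelwise-cross-entropy'")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stopf("validation_fraction must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 pixels_per_image = as.integer(pixels_per_image)),
            class = "train_hyperparams")
}

n_features <- function(config) 3L + 4L * length(config$aspp_rates)

# Fixed feature pyramid: per-pixel RGB, plus (per dilation rate) pooled RGB
# context and local luminance contrast. Returns an (H*W) x d matrix in
# column-major pixel order.
pyramid_features <- function(image, config) {
  check_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  x <- image / 255
  lum <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  cols <- vector("list", n_features(config))
  k <- 0L
  for (ch in 1:3) { k <- k + 1L; cols[[k]] <- as.vector(x[, , ch]) }
  for (r in config$aspp_rates) {
    for (ch in 1:3) {
      k <- k + 1L
      cols[[k]] <- as.vector(box_mean(x[, , ch], r))
    }
    m1 <- box_mean(lum, r)
    m2 <- box_mean(lum^2, r)
    k <- k + 1L
    cols[[k]] <- as.vector(sqrt(pmax(m2 - m1^2, 0)))
  }
  matrix(unlist(cols), nrow = h * w, ncol = k)
}

init_head <- function(d, hidden, seed) {
  with_rng(seed, list(
    W1 = matrix(rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(rnorm(hidden * 2, 0, sqrt(2 / hidden)), hidden, 2),
    b2 = rep(0, 2)))
}

#' Build a (untrained) segmentation model
#'
#' @param config a [network_config()].
#' @param seed seed for weight initialisation; two builds with the same
#'   config and seed have identical parameters.
#' @return A `pomseg_model` with `trained = FALSE`. When
#'   `config$pretrained_weights` names a saved model, every layer except
#'   the final classifier is initialised from it.
#' @export
build_model <- function(config = network_config(), seed = 0L) {
  if (!inherits(config, "network_config")) stopf("config must be a network_config")
  d <- n_features(config)
  weights <- init_head(d, config$hidden_units, seed)
  if (!is.null(config$pretrained_weights)) {
    if (!file.exists(config$pretrained_weights))
      stopf("pretrained weights file not found: %s", config$pretrained_weights)
    prev <- readRDS(config$pretrained_weights)
    if (!inherits(prev, "pomseg_model") ||
        !identical(dim(prev$weights$W1), dim(weights$W1)))
      stopf("incompatible pretrained weights in %s", config$pretrained_weights)
    weights$W1 <- prev$weights$W1   # all layers except the final classifier
    weights$b1 <- prev$weights$b1
  }
  structure(list(config = config, weights = weights, stage_tag = "manual",
                 trained = FALSE, training_manifest_hash = "",
                 loss_log = numeric(0)),
            class = "pomseg_model")
}

forward_scores <- function(weights, X) {
  Z <- X %*% weights$W1
  Z <- sweep(Z, 2, weights$b1, "+")
  Z[Z < 0] <- 0
  S <- Z %*% weights$W2
  list(Z = Z, S = sweep(S, 2, weights$b2, "+"))
}

softmax_ce <- function(S, y) {
  # y in {0 (background), 1 (fruit)}; returns loss and dL/dS
  m <- pmax(S[, 1], S[, 2])
  e1 <- exp(S[, 1] - m); e2 <- exp(S[, 2] - m)
  z <- e1 + e2
  p2 <- e2 / z
  loss <- mean(ifelse(y == 1, -log(pmax(p2, 1e-12)),
                      -log(pmax(1 - p2, 1e-12))))
  dS <- cbind((1 - p2) - (1 - y), p2 - y) / length(y)
  list(loss = loss, dS = dS)
}

adam_state <- function(weights) {
  lapply(weights, function(w) list(m = w * 0, v = w * 0))
}

adam_update <- function(weights, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (nm in names(weights)) {
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(weights = weights, state = state)
}

sample_training_pixels <- function(dataset, config, pixels_per_image) {
  Xs <- vector("list", length(dataset))
  ys <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    feats <- pyramid_features(s$image, config)
    n <- nrow(feats)
    take <- sample.int(n, min(pixels_per_image, n))
    Xs[[i]] <- feats[take, , drop = FALSE]
    ys[[i]] <- as.vector(s$mask)[take]
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

#' Train the segmentation model with pixel-wise cross-entropy
#'
#' Samples `pixels_per_image` pixels from every training sample, then runs
#' minibatch Adam on the trainable head for `epochs` passes. Training
#' continues from the model's current weights (transfer learning across
#' cascade stages warm-starts each stage from its predecessor). The
#' per-epoch mean loss is logged and must stay finite; a non-finite loss
#' aborts with a divergence error.
#'
#' @param model a `pomseg_model` from [build_model()] (or a trained one).
#' @param dataset non-empty list of [labeled_sample]s.
#' @param hp a [train_hyperparams()].
#' @param stage_tag tag recorded on the returned model: one of
#'   `"first_ce"`, `"ce"`, `"tna"`, `"fia"`, `"manual"`.
#' @return The trained `pomseg_model`, with `loss_log` (per-epoch training
#'   loss) and `training_manifest_hash` filled in.
#' @export
train_model <- function(model, dataset, hp = train_hyperparams(),
                        stage_tag = "manual") {
  if (!inherits(model, "pomseg_model")) stopf("model must be a pomseg_model")
  if (!is.list(dataset) || length(dataset) == 0L)
    stopf("dataset must be a non-empty list of labeled samples")
  stage_tag <- match.arg(stage_tag, c("first_ce", "ce", "tna", "fia", "manual"))
  weights <- model$weights
  log_tr <- numeric(hp$epochs)
  log_val <- rep(NA_real_, hp$epochs)
  with_rng(hp$seed, {
    n_val <- floor(hp$validation_fraction * length(dataset))
    val_idx <- if (n_val > 0) sample.int(length(dataset), n_val) else integer(0)
    tr_set <- if (n_val > 0) dataset[-val_idx] else dataset
    if (length(tr_set) == 0L) stopf("validation_fraction leaves no training data")
    tr <- sample_training_pixels(tr_set, model$config, hp$pixels_per_image)
    va <- if (n_val > 0)
      sample_training_pixels(dataset[val_idx], model$config,
                             hp$pixels_per_image) else NULL
    n <- nrow(tr$X)
    state <- adam_state(weights)
    t <- 0L
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = hp$batch_size)) {
        idx <- ord[start:min(start + hp$batch_size - 1L, n)]
        X <- tr$X[idx, , drop = FALSE]
        y <- tr$y[idx]
        fw <- forward_scores(weights, X)
        ce <- softmax_ce(fw$S, y)
        if (!is.finite(ce$loss))
          stopf("training diverged: non-finite loss at epoch %d", ep)
        dZ <- ce$dS %*% t(weights$W2)
        dZ[fw$Z <= 0] <- 0
        grads <- list(W1 = t(X) %*% dZ, b1 = colSums(dZ),
                      W2 = t(fw$Z) %*% ce$dS, b2 = colSums(ce$dS))
        t <- t + 1L
        upd <- adam_update(weights, grads, state, hp$learning_rate, t)
        weights <- upd$weights
        state <- upd$state
        losses <- c(losses, ce$loss)
      }
      log_tr[ep] <- mean(losses)
      if (!is.null(va)) {
        fw <- forward_scores(weights, va$X)
        log_val[ep] <- softmax_ce(fw$S, va$y)$loss
      }
    }
  })
  model$weights <- weights
  model$trained <- TRUE
  model$stage_tag <- stage_tag
  model$loss_log <- log_tr
  model$val_loss_log <- log_val
  ids <- paste(vapply(dataset, function(s) s$sample_id, character(1)),
               collapse = "|")
  model$training_manifest_hash <- as.character(hash_string(ids))
  model
}

#' Predict a binary fruit mask for one image
#'
#' Per-pixel argmax over the two score channels; score ties break toward
#' background (class 0), the conservative choice for precision.
#'
#' @param model a trained `pomseg_model`.
#' @param image H x W x 3 array of 8-bit RGB intensities (any size).
#' @return Binary H x W mask.
#' @export
predict_mask <- function(model, image) {
  if (!inherits(model, "pomseg_model")) stopf("model must be a pomseg_model")
  if (!isTRUE(model$trained)) stopf("model has not been trained")
  check_rgb_image(image)
  X <- pyramid_features(image, model$config)
  S <- forward_scores(model$weights, X)$S
  matrix((S[, 2] > S[, 1]) + 0, dim(image)[1], dim(image)[2])
}

#' Save / load a model (weights plus JSON sidecar)
#'
#' The RDS file round-trips the model bit-exactly; the sidecar
#' `<path>.json` records the config, stage tag and training manifest hash
#' for human inspection.
#'
#' @param model a `pomseg_model`.
#' @param path output file path.
#' @return `save_model`: invisibly, `path`; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "pomseg_model")) stopf("model must be a pomseg_model")
  saveRDS(model, path)
  side <- list(backbone = model$config$backbone,
               aspp_rates = model$config$aspp_rates,
               num_classes = model$config$num_classes,
               hidden_units = model$config$hidden_units,
               stage_tag = model$stage_tag,
               trained = model$trained,
               training_manifest_hash = model$training_manifest_hash)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pomseg_model")) stopf("%s is not a saved model", path)
  model
}
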