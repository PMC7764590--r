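#' Build a UNet-Mini model
#'
#' A miniature fully-convolutional encoder-decoder for 3-class semantic
#' segmentation.  The encoder has four stages (3x3 convolution, stride 1,
#' batch normalization, ReLU, 2x2 max-pool) with 16, 32, 64 and 64
#' kernels; the decoder mirrors it with x2 nearest upsampling, 3x3
#' convolutions of 64, 32, 16 and 16 kernels and element-wise additive
#' skip connections from the encoder (leading channels where the encoder
#' is wider).  A final 1x1 convolution with softmax yields the three class
#' probability maps.  Spatial extent is preserved for inputs divisible by
#' 16; total trainable parameters: 123,219.
#'
#' @param seed Integer seed for the weight initialization (He normal).
#' @return A `UNetMini` model object.
#' @export
unet_mini <- function(seed = 1L) {
  structure(list(ptr = .cpp_unet_create(as.integer(seed)),
                 seed = as.integer(seed),
                 encoder_widths = c(16L, 32L, 64L, 64L),
                 decoder_widths = c(64L, 32L, 16L, 16L),
                 n_classes = 3L),
            class = "UNetMini")
}

#' Count the trainable parameters of a model
#'
#' Counts every independently trainable scalar: convolution weights and
#' biases plus batch-normalization scale and shift.  Running BN statistics
#' are not trainable and are excluded.
#'
#' @param model A `UNetMini`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "UNetMini"))
  .cpp_unet_nparams(model$ptr)
}

#' Training configuration
#'
#' The reference schedule trains for 35 epochs with mini-batch size 32 and
#' either Adam with standard parameters (lr 1e-3, betas 0.9/0.999,
#' eps 1e-8) or plain SGD with starting learning rate 0.01 decayed by
#' a factor 0.1 every 10 epochs.  The loss is cross-entropy over pixels,
#' ignoring label code 0 (padding).
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param epochs,batch_size Schedule parameters.
#' @param lr Starting learning rate (default 1e-3 for adam, 0.01 for sgd).
#' @param sgd_decay,sgd_decay_every Step-decay factor and period (epochs)
#'   for SGD.
#' @param seed RNG seed for shuffling.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), epochs = 35L,
                         batch_size = 32L, lr = NULL, sgd_decay = 0.1,
                         sgd_decay_every = 10L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 1e-3 else 0.01
  structure(list(optimizer = optimizer, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 sgd_decay = sgd_decay,
                 sgd_decay_every = as.integer(sgd_decay_every),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch under a training configuration
#'
#' For SGD this is the step-decay schedule (`lr * decay^(epoch %/% every)`);
#' Adam keeps its learning rate constant.
#'
#' @param cfg A [train_config()].
#' @param epoch 0-based epoch index.
#' @return Learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (cfg$optimizer == "sgd")
    signif(cfg$lr * cfg$sgd_decay^(epoch %/% cfg$sgd_decay_every), 12)
  else cfg$lr
}

crops_to_arrays <- function(crops) {
  n <- length(crops)
  h <- nrow(crops[[1]]$image); w <- ncol(crops[[1]]$image)
  imgs <- array(0, dim = c(h, w, n))
  labs <- array(0L, dim = c(h, w, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- crops[[i]]$image
    labs[, , i] <- crops[[i]]$label
  }
  list(imgs = imgs, labs = labs)
}

#' Train a UNet-Mini on a crop dataset
#'
#' Runs mini-batch gradient descent with the configured optimizer on the
#' training crops; after each epoch the mean training loss, the learning
#' rate and (if a dev set is present) the dev pixel accuracy against the
#' crops' own labels are recorded.
#'
#' @param model A `UNetMini` (modified in place; also returned).
#' @param split A `DatasetSplit` from [split_by_scan()], or a plain list of
#'   crops used as the training set.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` and `history` (data frame with one row per
#'   epoch: `epoch`, `loss`, `lr`, `dev_accuracy`).
#' @export
train_unet <- function(model, split, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "UNetMini"))
  train <- if (inherits(split, "DatasetSplit")) split$train else split
  dev <- if (inherits(split, "DatasetSplit")) split$dev else list()
  if (length(train) == 0L) stop("empty training set")
  bad <- vapply(train, function(cr) any(!cr$label %in% 0:3), logical(1))
  if (any(bad)) stop("label codes outside 0..3 in training crops")

  tr <- crops_to_arrays(train)
  dv <- if (length(dev) > 0L) crops_to_arrays(dev) else NULL
  n <- dim(tr$imgs)[3]
  adam <- cfg$optimizer == "adam"
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                        dev_accuracy = numeric())
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        loss <- .cpp_unet_backward(model$ptr,
                                   tr$imgs[, , idx, drop = FALSE],
                                   tr$labs[, , idx, drop = FALSE])
        .cpp_unet_step(model$ptr, lr, adam, 0.9, 0.999, 1e-8)
        losses <- c(losses, loss)
      }
      dev_acc <- NA_real_
      if (!is.null(dv)) {
        probs <- .cpp_unet_forward(model$ptr, dv$imgs)
        pred <- apply(probs, c(1, 2, 4), which.max)  # H x W x N
        keep <- dv$labs != 0L
        dev_acc <- mean(pred[keep] == dv$labs[keep])
      }
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), lr, dev_acc)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f lr %g dev acc %s", epoch,
                        mean(losses), lr,
                        ifelse(is.na(dev_acc), "-", sprintf("%.4f", dev_acc))))
    }
  })
  list(model = model, history = history)
}

# pad a grayscale matrix to multiples of 16 by edge replication
pad_to_16 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  H <- 16L * ceiling(h / 16L); W <- 16L * ceiling(w / 16L)
  if (H == h && W == w) return(list(m = m, h = h, w = w))
  out <- matrix(0, H, W)
  out[1:h, 1:w] <- m
  if (H > h) out[(h + 1):H, 1:w] <- matrix(m[h, ], H - h, w, byrow = TRUE)
  if (W > w) out[, (w + 1):W] <- out[, w]
  list(m = out, h = h, w = w)
}

#' Predict class probabilities for grayscale crops
#'
#' Inference-mode forward pass (running batch-norm statistics).  Inputs
#' whose extent is not a multiple of 16 are edge-padded internally and the
#' output cropped back.
#'
#' @param model A trained `UNetMini`.
#' @param img H x W grayscale matrix in \[0,1\].
#' @return H x W x 3 array of class probabilities (softmax, rows sum to 1).
#' @export
predict_unet <- function(model, img) {
  stopifnot(inherits(model, "UNetMini"))
  p <- pad_to_16(img)
  probs <- .cpp_unet_forward(model$ptr,
                             array(p$m, dim = c(nrow(p$m), ncol(p$m), 1L)))
  probs[1:p$h, 1:p$w, , 1]
}

#' Whole-slide inference with tile stitching
#'
#' Tiles the scan into `tile` x `tile` crops with `overlap` pixels of
#' overlap, predicts each tile and stitches the probability maps by
#' averaging in the overlap regions; classes are the per-pixel argmax
#' (ties to the lowest code).  A scan smaller than one tile is predicted
#' directly.
#'
#' @param model A trained `UNetMini`.
#' @param scan H x W grayscale matrix in \[0,1\].
#' @param tile,overlap Tiling geometry (defaults 224 / 100).
#' @return A `SegmentationMap`: list with `classes` (H x W), `posteriors`
#'   (H x W x 3) and `pixel_size_um` (`NA`; set by the caller if known).
#' @export
predict_slide_cnn <- function(model, scan, tile = 224L, overlap = 100L) {
  if (length(scan) == 0L) stop("empty scan")
  h <- nrow(scan); w <- ncol(scan)
  if (h < tile || w < tile) {
    post <- predict_unet(model, scan)
  } else {
    acc <- array(0, dim = c(h, w, 3L))
    cnt <- matrix(0, h, w)
    grid <- make_tile_grid(h, w, tile, overlap)
    for (i in seq_len(nrow(grid$origins))) {
      r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
      rows <- (r0 + 1):(r0 + tile); cols <- (c0 + 1):(c0 + tile)
      probs <- predict_unet(model, scan[rows, cols])
      acc[rows, cols, ] <- acc[rows, cols, , drop = FALSE] + probs
      cnt[rows, cols] <- cnt[rows, cols] + 1
    }
    post <- acc / as.vector(cnt)
  }
  flat <- matrix(post, h * w, 3)
  classes <- matrix(max.col(flat, ties.method = "first"), h, w)
  list(classes = classes, posteriors = post, pixel_size_um = NA_real_)
}

#' Save a UNet-Mini checkpoint
#'
#' Writes trainable parameters, running batch-norm statistics, the
#' architecture configuration and the initialization seed as JSON.
#'
#' @param model A `UNetMini`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_unet <- function(model, path) {
  jsonlite::write_json(list(params = .cpp_unet_get_params(model$ptr),
                            running = .cpp_unet_get_running(model$ptr),
                            encoder_widths = model$encoder_widths,
                            decoder_widths = model$decoder_widths,
                            n_classes = model$n_classes, seed = model$seed),
                       path, digits = NA)
  invisible(path)
}

#' Load a UNet-Mini checkpoint saved by [save_unet()]
#' @param path JSON path.
#' @return A `UNetMini`.
#' @export
load_unet <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- unet_mini(seed = d$seed[1])
  .cpp_unet_set_params(model$ptr, as.numeric(d$params))
  .cpp_unet_set_running(model$ptr, as.numeric(d$running))
  model
}
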