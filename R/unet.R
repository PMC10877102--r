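#' Configuration of a semantic segmentation U-net
#'
#' The full-scale recipe follows the targeted assay: nuclei are segmented
#' at 512x512 after downsampling (batch 32), foci at native resolution
#' (batch 8); both train for 200 epochs with Adam at learning rate 1e-3
#' minimizing a soft Jaccard loss, with dihedral (8 flips/rotations) and
#' contrast (factors 0.8 / 1.2) augmentation, keeping the weights of the
#' epoch with the lowest validation loss. Reduced settings (smaller
#' `input_size`, `epochs`) train desk-scale models on synthetic scenes.
#'
#' @param channel `"nuclei"` or `"foci"`; sets the mode defaults.
#' @param input_size `(h, w)` the network operates at; both must be
#'   divisible by `2^depth`.
#' @param depth number of pooling stages.
#' @param base_filters filters of the first encoder level (doubling per
#'   level).
#' @param downsample_input resample images to `input_size` before the net
#'   (nuclei mode) or require native resolution (foci mode).
#' @param batch_size,epochs,learning_rate training recipe.
#' @param contrast_factors augmentation contrast factors (1.0 is always
#'   included); `dihedral` toggles the 8 flips/rotations.
#' @param dihedral logical.
#' @param threshold probability cut for binarization.
#' @param seed controls weight init, shuffling and augmentation draws.
#' @return A `unet_config` list.
#' @export
unet_config <- function(channel = c("nuclei", "foci"),
                        input_size = if (channel == "nuclei") c(512L, 512L) else NULL,
                        depth = 4L, base_filters = 16L,
                        downsample_input = channel == "nuclei",
                        batch_size = if (channel == "nuclei") 32L else 8L,
                        epochs = 200L, learning_rate = 1e-3,
                        contrast_factors = c(0.8, 1.2),
                        dihedral = TRUE,
                        threshold = 0.5, seed = 1L) {
  channel <- match.arg(channel)
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (any(contrast_factors <= 0)) stopf("contrast factors must be > 0")
  if (!is.null(input_size)) {
    if (any(input_size %% 2L^depth != 0L))
      stopf("input size %dx%d is not divisible by 2^depth = %d",
            input_size[1], input_size[2], 2L^depth)
  }
  structure(list(channel = channel, input_size = input_size, depth = depth,
                 base_filters = base_filters,
                 downsample_input = isTRUE(downsample_input),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 loss = "soft_jaccard",
                 augmentation = list(dihedral = isTRUE(dihedral),
                                     contrast_factors = contrast_factors),
                 checkpoint_policy = "best_validation_loss",
                 threshold = threshold, seed = as.integer(seed)),
            class = "unet_config")
}

#' Build an (untrained) U-net
#'
#' Ronneberger-style encoder-decoder with skip connections, per-image
#' min-max normalization in front of the first layer, padded 3x3
#' convolutions with batch normalization after every convolution (before
#' the ReLU), 2x2 max-pooling, nearest-neighbor upsampling followed by a
#' convolution, and a single-channel sigmoid output at input resolution.
#'
#' @param config a [unet_config()].
#' @return A `unet_model` (untrained; `$trained` is `FALSE`).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  P <- local_seed(config$seed,
                  unet_init_params(config$depth, config$base_filters))
  structure(list(config = config,
                 params = P,
                 state = unet_init_state(config$depth, config$base_filters),
                 history = NULL, trained = FALSE),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(ls(x$params), function(nm) length(get(nm, envir = x$params)),
                   numeric(1)))
  cat(sprintf("<unet %s: depth %d, base %d, %s parameters, %s>\n",
              x$config$channel, x$config$depth, x$config$base_filters,
              format(np, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of parameters of a model
#' @param model a `unet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(ls(model$params),
             function(nm) length(get(nm, envir = model$params)), numeric(1)))
}

#' Soft Jaccard (IoU) loss
#'
#' `1 - (sum(p*t) + eps) / (sum(p) + sum(t) - sum(p*t) + eps)` with
#' `eps = 1e-6`; 0 for a perfect binary prediction, approaching 1 for a
#' disjoint one. Differentiable in the probabilities.
#'
#' @param pred probability raster (values in `[0, 1]`).
#' @param target binary raster of the same shape.
#' @param eps stabilizer.
#' @return The loss (scalar).
#' @export
soft_jaccard_loss <- function(pred, target, eps = 1e-6) {
  if (!all(dim(pred) == dim(target))) stopf("pred and target shapes differ")
  if (any(pred < 0) || any(pred > 1)) stopf("pred must lie in [0, 1]")
  I <- sum(pred * target)
  U <- sum(pred) + sum(target) - I
  1 - (I + eps) / (U + eps)
}

#' Apply one of the eight dihedral transforms
#'
#' `k = 1` identity, 2-4 rotations by 90/180/270 degrees, 5 horizontal
#' flip, 6 vertical flip, 7 transpose, 8 anti-transpose.
#'
#' @param m a matrix.
#' @param k transform index 1..8.
#' @param inverse apply the inverse transform instead.
#' @return The transformed matrix.
#' @export
dihedral_transform <- function(m, k, inverse = FALSE) {
  if (inverse) k <- c(1L, 4L, 3L, 2L, 5L, 6L, 7L, 8L)[k]
  switch(k,
         m,
         t(m)[, nrow(m):1, drop = FALSE][, , drop = FALSE],   # 90 ccw? see tests
         m[nrow(m):1, ncol(m):1, drop = FALSE],
         t(m)[ncol(m):1, , drop = FALSE],
         m[, ncol(m):1, drop = FALSE],
         m[nrow(m):1, , drop = FALSE],
         t(m),
         t(m[nrow(m):1, ncol(m):1, drop = FALSE]))
}

#' Paired augmentation of an image and its mask
#'
#' Applies one dihedral transform (drawn uniformly) identically to image
#' and mask, then multiplies the image by a contrast factor drawn
#' uniformly from `contrast_factors` plus 1.0, clipping to the image's
#' original value range. Draws come from the current RNG stream.
#'
#' @param image,mask matrices of the same shape.
#' @param augmentation list with `dihedral` and `contrast_factors` (as in
#'   [unet_config()]).
#' @return A list with `image` and `mask`.
#' @export
augment_pair <- function(image, mask,
                         augmentation = list(dihedral = TRUE,
                                             contrast_factors = c(0.8, 1.2))) {
  stopifnot(all(dim(image) == dim(mask)))
  if (isTRUE(augmentation$dihedral)) {
    k <- sample.int(8L, 1L)
    image <- dihedral_transform(image, k)
    mask <- dihedral_transform(mask, k)
  }
  fac <- c(augmentation$contrast_factors, 1)
  f <- fac[sample.int(length(fac), 1L)]
  if (f != 1) {
    lo <- min(image); hi <- max(image)
    image <- pmin(pmax(image * f, lo), hi)
  }
  list(image = image, mask = mask)
}

prepare_pair <- function(image, mask, config) {
  if (config$downsample_input && !is.null(config$input_size)) {
    image <- resample_image(image, config$input_size[1], config$input_size[2])
    if (!is.null(mask))
      mask <- resample_mask(mask, config$input_size[1], config$input_size[2])
  }
  if (any(dim(image) %% 2L^config$depth != 0L))
    stopf("image size %dx%d is not divisible by 2^depth = %d",
          nrow(image), ncol(image), 2L^config$depth)
  list(image = image, mask = mask)
}

batch_tensor <- function(images) {
  B <- length(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  X <- matrix(0, B * H * W, 1L)
  for (b in seq_len(B))
    X[((b - 1L) * H * W + 1L):(b * H * W), 1L] <- as.vector(images[[b]])
  X
}

#' Mean validation loss of a model over image/mask pairs
#'
#' Soft Jaccard loss in inference mode (running batch-norm statistics),
#' averaged over the pairs. Works for untrained models too, providing the
#' baseline that training must beat.
#'
#' @param model a `unet_model`.
#' @param pairs list of `list(image=, mask=)` pairs (matrices).
#' @return Mean loss.
#' @export
unet_validation_loss <- function(model, pairs) {
  cfg <- model$config
  losses <- vapply(pairs, function(pr) {
    pp <- prepare_pair(pr$image, pr$mask, cfg)
    H <- nrow(pp$image); W <- ncol(pp$image)
    X <- matrix(as.vector(normalize_image(pp$image)), ncol = 1L)
    out <- unet_forward(model$params, model$state, X, 1L, H, W, cfg$depth,
                        training = FALSE, with_tape = FALSE)
    soft_jaccard_loss(out$prob, matrix(as.vector(pp$mask), ncol = 1L))
  }, numeric(1))
  mean(losses)
}

#' Train a U-net on image/mask pairs
#'
#' Mini-batch Adam on the soft Jaccard loss with paired augmentation; in
#' nuclei mode images and masks are resampled to `input_size` first (mask
#' binarization by >= 0.5 block coverage), in foci mode native resolution
#' is kept. After every epoch the validation loss is evaluated and the
#' parameters of the best epoch are restored at the end
#' (lowest-validation-loss checkpointing).
#'
#' @param model a `unet_model` from [build_unet()].
#' @param train_pairs,val_pairs non-empty lists of `list(image=, mask=)`.
#' @param verbose print per-epoch losses.
#' @return The trained `unet_model` with a `history` data frame.
#' @export
train_unet <- function(model, train_pairs, val_pairs, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  cfg <- model$config
  if (length(train_pairs) == 0L || length(val_pairs) == 0L)
    stopf("training and validation sets must be non-empty")
  train_prep <- lapply(train_pairs, function(pr)
    prepare_pair(pr$image, pr$mask, cfg))
  P <- model$params; S <- model$state
  st <- adam_new(P)
  best <- list(loss = Inf, P = NULL, S = NULL, epoch = NA_integer_)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  local_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(train_prep))
      batch_losses <- c()
      bstarts <- seq(1L, length(ord), by = cfg$batch_size)
      for (bs in bstarts) {
        sel <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
        imgs <- list(); msks <- list()
        for (ii in seq_along(sel)) {
          aug <- augment_pair(train_prep[[sel[ii]]]$image,
                              train_prep[[sel[ii]]]$mask, cfg$augmentation)
          imgs[[ii]] <- normalize_image(aug$image)
          msks[[ii]] <- aug$mask
        }
        B <- length(imgs)
        H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
        X <- batch_tensor(imgs)
        Tg <- batch_tensor(msks)
        out <- unet_forward(P, S, X, B, H, W, cfg$depth, training = TRUE)
        loss <- soft_jaccard_loss(out$prob, Tg)
        batch_losses <- c(batch_losses, loss)
        grads <- new.env(parent = emptyenv())
        grads$P_env <- P
        grads$skip_stack <- list()
        dP <- soft_jaccard_grad(out$prob, Tg)
        unet_backward(out$tape, dP, grads)
        adam_step(P, grads, st, cfg$learning_rate)
      }
      tmp_model <- structure(list(config = cfg, params = P, state = S,
                                  trained = TRUE), class = "unet_model")
      vl <- unet_validation_loss(tmp_model, val_pairs)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(batch_losses),
                                     val_loss = vl))
      if (vl < best$loss)
        best <- list(loss = vl, P = env_snapshot(P), S = env_snapshot(S),
                     epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        mean(batch_losses), vl))
    }
  })
  structure(list(config = cfg, params = best$P, state = best$S,
                 history = hist, trained = TRUE,
                 best_epoch = best$epoch), class = "unet_model")
}

#' Predict a semantic mask for one image
#'
#' Nuclei mode: the image is resampled to the configured input size,
#' probabilities are thresholded, and the mask is upsampled
#' (nearest-neighbor) back to the input geometry with the original pixel
#' size. Foci mode: native resolution throughout.
#'
#' @param model a trained `unet_model`.
#' @param image a [plane_image] (or bare matrix plus `pixel_size_um`).
#' @param threshold probability cut (default from the config).
#' @param pixel_size_um required when `image` is a bare matrix.
#' @return A [semantic_mask] at the geometry of `image`.
#' @export
predict_mask <- function(model, image, threshold = NULL,
                         pixel_size_um = NULL) {
  stopifnot(inherits(model, "unet_model"))
  if (!model$trained) stopf("model is untrained")
  if (inherits(image, "plane_image")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$raster
  }
  check_calibration(pixel_size_um)
  if (is.null(threshold)) threshold <- model$config$threshold
  cfg <- model$config
  H0 <- nrow(image); W0 <- ncol(image)
  pp <- prepare_pair(image, NULL, cfg)
  H <- nrow(pp$image); W <- ncol(pp$image)
  X <- matrix(as.vector(normalize_image(pp$image)), ncol = 1L)
  out <- unet_forward(model$params, model$state, X, 1L, H, W, cfg$depth,
                      training = FALSE, with_tape = FALSE)
  m <- matrix((out$prob >= threshold) * 1L, H, W)
  if (H != H0 || W != W0) m <- resample_mask(m, H0, W0)
  semantic_mask(m, pixel_size_um)
}

#' Save / load a trained model directory
#'
#' The directory holds the weights, the batch-norm state, the config and
#' the training history.
#'
#' @param model a `unet_model`.
#' @param dir model directory.
#' @return `dir` (save) / the model (load).
#' @export
save_unet <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = model$config,
               params = as.list(model$params),
               state = as.list(model$state),
               history = model$history,
               trained = model$trained,
               best_epoch = model$best_epoch),
          file.path(dir, "model.rds"))
  jsonlite::write_json(model$history, file.path(dir, "history.json"),
                       dataframe = "columns", auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_unet
#' @export
load_unet <- function(dir) {
  x <- readRDS(file.path(dir, "model.rds"))
  P <- list2env(x$params, parent = emptyenv())
  S <- list2env(x$state, parent = emptyenv())
  structure(list(config = x$config, params = P, state = S,
                 history = x$history, trained = x$trained,
                 best_epoch = x$best_epoch), class = "unet_model")
}
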