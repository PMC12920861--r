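#' Network architecture configuration
#'
#' All three pose-estimation approaches share a MobileNetV2 encoder (an
#' initial stride-2 convolution with 32 filters followed by 17 inverted
#' residual blocks whose expansion widths grow from 32 to 576 at width 1).
#' The `heatmap` variant attaches a U-Net decoder of four blocks (each
#' upsamples by 2, concatenates the resolution-matched encoder feature map
#' and applies two 3x3 conv + batch-norm + ReLU layers) and a head of
#' three convolutions, the last sigmoid-activated, producing one heatmap
#' channel per keypoint at the input resolution. The `segmentation`
#' variant is the same architecture with a single sigmoid channel. The
#' `direct` variant replaces the decoder by two separable convolutions and
#' a 6-value sigmoid coordinate head (normalized x, y per keypoint).
#'
#' @param variant `"heatmap"`, `"direct"` or `"segmentation"`.
#' @param input_size Input side length in pixels; must be divisible by 32
#'   (default 224).
#' @param width Encoder/decoder width multiplier; 1 reproduces the
#'   32-to-576 channel progression, smaller values give desk-scale
#'   networks.
#' @param pretrained_encoder If `TRUE`, encoder weights must be supplied
#'   through `init_state` in [vf_train()]; no weights are shipped.
#' @return A list of class `vf_model_config`.
#' @export
model_config <- function(variant = c("heatmap", "direct", "segmentation"),
                         input_size = 224, width = 1.0,
                         pretrained_encoder = FALSE) {
  variant <- match.arg(variant)
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  if (width <= 0) stop("width must be positive")
  structure(list(variant = variant, input_size = as.integer(input_size),
                 width = width, pretrained_encoder = pretrained_encoder),
            class = "vf_model_config")
}

#' Training protocol configuration
#'
#' Adam optimization with an initial learning rate of 0.001 and batch size
#' 8, for at most 200 epochs with early stopping once the validation loss
#' has not improved for 10 consecutive epochs; the best-validation-loss
#' weights are kept. The heatmap loss is the channel-weighted MSE with
#' weights (1.2, 1.2, 1.0) for (LV, RV, A).
#'
#' @param max_epochs,patience Early-stopping protocol; `patience` must be
#'   smaller than `max_epochs`.
#' @param learning_rate,batch_size Adam step size and minibatch size.
#' @param loss One of `"wmse"`, `"mse"`, `"weighted_l1"`, `"dice"`,
#'   `"coord_mse"`.
#' @param seed Integer seed controlling weight initialization, data order
#'   and augmentation.
#' @param channel_weights Heatmap channel weights (LV, RV, A).
#' @param sigma Ground-truth Gaussian spread in pixels; `NULL` scales the
#'   default 20 px (defined in 224-pixel space) with the input size.
#' @param augment Apply on-the-fly augmentation during training.
#' @param wl1_threshold,wl1_hi,wl1_lo Weighted-l1 parameters.
#' @return A list of class `vf_train_config`.
#' @export
train_config <- function(max_epochs = 200, patience = 10,
                         learning_rate = 0.001, batch_size = 8,
                         loss = c("wmse", "mse", "weighted_l1", "dice",
                                  "coord_mse"),
                         seed = 1, channel_weights = vfpose::channel_weights(),
                         sigma = NULL, augment = TRUE,
                         wl1_threshold = 0.5, wl1_hi = 2, wl1_lo = 1) {
  loss <- match.arg(loss)
  if (patience >= max_epochs) stop("patience must be smaller than max_epochs")
  if (batch_size < 1) stop("batch_size must be at least 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed), channel_weights = channel_weights,
                 sigma = sigma, augment = isTRUE(augment),
                 wl1_threshold = wl1_threshold, wl1_hi = wl1_hi,
                 wl1_lo = wl1_lo),
            class = "vf_train_config")
}

net_out_channels <- function(variant) {
  switch(variant, heatmap = 3L, segmentation = 1L, direct = 6L)
}

loss_spec <- function(tc, variant) {
  switch(tc$loss,
         wmse = list(name = "wmse", w = as.numeric(tc$channel_weights)),
         mse = list(name = "mse", w = numeric(0)),
         weighted_l1 = list(name = "wl1",
                            w = c(tc$wl1_threshold, tc$wl1_hi, tc$wl1_lo)),
         dice = list(name = "dice", w = numeric(0)),
         coord_mse = list(name = "mse", w = numeric(0)))
}

#' Build an untrained network
#'
#' Constructs the network for a given configuration with seeded He-normal
#' initialization and returns it as an (untrained) `vf_net` object.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `vf_net`.
#' @export
build_network <- function(config = model_config(), seed = 1) {
  ptr <- .net_build(config$variant, config$input_size, config$width,
                    net_out_channels(config$variant), as.integer(seed))
  structure(list(ptr = ptr, model_config = config, train_config = NULL,
                 state = .net_get_state(ptr), history = NULL,
                 best_epoch = NA_integer_, trained = FALSE, seed = seed),
            class = "vf_net")
}

# Revive the external pointer after deserialization (the pointer does not
# survive saveRDS; the weights in $state do).
net_ptr <- function(object) {
  if (is.null(object$ptr) || !.net_ptr_valid(object$ptr)) {
    cfg <- object$model_config
    ptr <- .net_build(cfg$variant, cfg$input_size, cfg$width,
                      net_out_channels(cfg$variant), as.integer(object$seed))
    .net_set_state(ptr, object$state)
    return(ptr)
  }
  object$ptr
}

#' Number of trainable parameters
#' @param object A `vf_net`.
#' @return Parameter count (numeric scalar).
#' @export
n_params <- function(object) .net_param_count(net_ptr(object))

# Pre-resize records to the network input resolution ([0,1] images, scaled
# triplets); mean removal happens per batch after augmentation.
prepare_records <- function(records, S) {
  lapply(records, function(r) {
    d <- dim(r$image)
    img <- if (d[1] == S && d[2] == S) r$image else .resize_bilinear(r$image, S, S)
    tri <- transform_triplet(r$triplet, diag(c(S / d[2], S / d[1])))
    list(image = img, triplet = tri, frame_id = r$frame_id,
         patient_id = r$patient_id, oncologic = r$oncologic)
  })
}

make_batch <- function(pre, idx, variant, S, sigma, augment) {
  n <- length(idx)
  x <- array(0, dim = c(S, S, 3, n))
  C <- net_out_channels(variant)
  y <- if (variant == "direct") array(0, dim = c(1, 1, 6, n))
       else array(0, dim = c(S, S, C, n))
  for (j in seq_len(n)) {
    p <- pre[[idx[j]]]
    img <- p$image; tri <- p$triplet
    if (augment) {
      aug <- augment_frame(img, tri)
      img <- aug$image; tri <- aug$triplet
    }
    for (k in 1:3) x[, , k, j] <- img[, , k] - mean(img[, , k])
    if (variant == "heatmap") {
      y[, , , j] <- encode_heatmaps(tri, S, S, sigma)
    } else if (variant == "segmentation") {
      y[, , 1, j] <- triangle_mask(tri, S, S)
    } else {
      m <- as.matrix(tri)
      y[1, 1, , j] <- c(m["LV", ], m["RV", ], m["A", ]) / (S - 1)
    }
  }
  list(x = x, y = y)
}

#' Fit a vocal-fold pose-estimation network
#'
#' Trains the configured network on preprocessed frames: images are
#' bilinearly resized to the input resolution, augmented on the fly
#' (when enabled), zero-meaned per channel, and supervised with the
#' variant's target (Gaussian heatmaps, the glottal triangle mask, or
#' normalized coordinates). Optimization follows [train_config()]: Adam,
#' early stopping on the validation loss, best-epoch checkpointing. The
#' run is fully seeded (weight initialization, data order, augmentation)
#' and therefore reproducible.
#'
#' @param train_records,val_records Non-empty lists of [vf_frame()]
#'   records.
#' @param config A [model_config()].
#' @param control A [train_config()].
#' @param init_state Optional network state (from a previous fit's
#'   `$state`) used as warm start, e.g. a pretrained encoder hook.
#' @param verbose Print per-epoch losses.
#' @return An object of class `vf_net` with elements `history` (data frame
#'   of per-epoch train/val losses), `best_epoch`, `state` (best weights)
#'   and the configurations. Methods: [predict.vf_net()], `print`,
#'   `summary`, `plot`, `coef`.
#' @export
vf_train <- function(train_records, val_records, config = model_config(),
                     control = train_config(), init_state = NULL,
                     verbose = FALSE) {
  if (length(train_records) == 0 || length(val_records) == 0)
    stop("empty training or validation split")
  if (config$pretrained_encoder && is.null(init_state))
    stop("pretrained_encoder = TRUE requires init_state (no weights shipped)")
  S <- config$input_size
  sigma <- control$sigma %||% (20 * S / 224)
  object <- build_network(config, seed = control$seed)
  if (!is.null(init_state)) .net_set_state(object$ptr, init_state)
  ls <- loss_spec(control, config$variant)
  pre_tr <- prepare_records(train_records, S)
  pre_va <- prepare_records(val_records, S)
  n_tr <- length(pre_tr)
  bs <- control$batch_size
  va_batches <- split(seq_along(pre_va), ceiling(seq_along(pre_va) / bs))
  val_loss_of <- function() {
    tot <- 0
    for (ib in va_batches) {
      b <- make_batch(pre_va, ib, config$variant, S, sigma, augment = FALSE)
      tot <- tot + length(ib) * .net_eval_loss(object$ptr, b$x, b$y, ls$name, ls$w)
    }
    tot / length(pre_va)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_state <- NULL; best_epoch <- NA_integer_; wait <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    tr_loss <- with_seed(control$seed + 101L * epoch, {
      ord <- sample.int(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / bs))
      tot <- 0
      for (ib in batches) {
        b <- make_batch(pre_tr, ib, config$variant, S, sigma,
                        augment = control$augment)
        l <- tryCatch(
          .net_step(object$ptr, b$x, b$y, ls$name, ls$w,
                    control$learning_rate, TRUE),
          error = function(e) stop("training aborted at epoch ", epoch, ": ",
                                   conditionMessage(e)))
        tot <- tot + length(ib) * l
      }
      tot / n_tr
    })
    vl <- val_loss_of()
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tr_loss, vl))
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_state <- .net_get_state(object$ptr)
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  if (!is.null(best_state)) .net_set_state(object$ptr, best_state)
  object$state <- .net_get_state(object$ptr)
  .net_release_activations(object$ptr)   # drop large activation buffers
  object$history <- history
  object$best_epoch <- best_epoch
  object$trained <- TRUE
  object$train_config <- control
  object$sigma <- sigma
  object
}

#' Predict pose from frames
#'
#' Runs batched inference and decodes the variant's raw output into
#' keypoint triplets in input-resolution pixel space: heatmaps are decoded
#' at their per-channel maxima; direct-regression coordinates are
#' de-normalized; segmentation probabilities are thresholded at 0.5 and
#' decoded through the minimum enclosing triangle of the predicted mask
#' (undecodable masks -- empty or degenerate -- yield `NULL` triplets and
#' are counted).
#'
#' @param object A fitted `vf_net`.
#' @param newdata List of [vf_frame()] records (any resolution; frames are
#'   resized to the network input size).
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return A list of class `vf_predictions`: `triplets` (list of
#'   [vf_triplet()] or `NULL`), `raw` (per-frame network output), `masks`
#'   (segmentation only), `n_undecodable`, `variant`, `input_size`.
#' @export
predict.vf_net <- function(object, newdata, batch_size = 8, ...) {
  cfg <- object$model_config
  S <- cfg$input_size
  ptr <- net_ptr(object)
  pre <- prepare_records(newdata, S)
  raw <- vector("list", length(pre))
  batches <- split(seq_along(pre), ceiling(seq_along(pre) / batch_size))
  for (ib in batches) {
    x <- array(0, dim = c(S, S, 3, length(ib)))
    for (j in seq_along(ib)) {
      img <- pre[[ib[j]]]$image
      for (k in 1:3) x[, , k, j] <- img[, , k] - mean(img[, , k])
    }
    out <- .net_forward(ptr, x, FALSE)
    for (j in seq_along(ib)) raw[[ib[j]]] <- out[, , , j, drop = TRUE]
  }
  .net_release_activations(ptr)
  triplets <- vector("list", length(pre))
  masks <- NULL
  n_und <- 0L
  if (cfg$variant == "heatmap") {
    triplets <- lapply(raw, decode_heatmaps)
  } else if (cfg$variant == "direct") {
    triplets <- lapply(raw, function(v) {
      v <- as.numeric(v) * (S - 1)
      vf_triplet(LV = v[1:2], RV = v[3:4], A = v[5:6])
    })
  } else {
    masks <- lapply(raw, function(p) (p >= 0.5) * 1L)
    for (i in seq_along(masks)) {
      tri <- tryCatch(
        label_triangle_vertices(min_enclosing_triangle(masks[[i]])$vertices),
        error = function(e) NULL)
      if (is.null(tri)) n_und <- n_und + 1L
      triplets[[i]] <- tri
    }
  }
  structure(list(variant = cfg$variant, input_size = S, triplets = triplets,
                 raw = raw, masks = masks, n_undecodable = n_und,
                 frame_ids = vapply(pre, `[[`, "", "frame_id")),
            class = "vf_predictions")
}

#' @export
print.vf_predictions <- function(x, ...) {
  cat(sprintf("%s predictions for %d frames (%d undecodable)\n", x$variant,
              length(x$triplets), x$n_undecodable))
  invisible(x)
}

#' @export
print.vf_net <- function(x, ...) {
  cfg <- x$model_config
  cat(sprintf("Vocal-fold pose network (%s variant)\n", cfg$variant))
  cat(sprintf("  input %dx%d, width %.2f, %s parameters\n", cfg$input_size,
              cfg$input_size, cfg$width,
              format(n_params(x), big.mark = ",")))
  if (x$trained) {
    cat(sprintf("  trained %d epochs (best epoch %d, val loss %.5f)\n",
                nrow(x$history), x$best_epoch,
                min(x$history$val_loss)))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.vf_net <- function(object, ...) {
  print(object)
  if (object$trained) {
    h <- object$history
    cat(sprintf("  train loss %.5f -> %.5f; val loss %.5f -> %.5f\n",
                h$train_loss[1], h$train_loss[nrow(h)], h$val_loss[1],
                h$val_loss[nrow(h)]))
  }
  invisible(object)
}

#' @export
plot.vf_net <- function(x, ...) {
  if (!x$trained) stop("nothing to plot: untrained network")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
coef.vf_net <- function(object, ...) object$state$weights

#' Save / load a fitted network
#'
#' The weights are written in R's native serialization with a JSON sidecar
#' recording the configuration, seed and best epoch.
#'
#' @param object A `vf_net`.
#' @param path Output path (`.rds`); the sidecar is `path` + `.json`.
#' @return `save_vf_net` returns `path` invisibly; `load_vf_net` the
#'   restored `vf_net`.
#' @export
save_vf_net <- function(object, path) {
  object$ptr <- NULL
  saveRDS(object, path)
  side <- list(variant = object$model_config$variant,
               input_size = object$model_config$input_size,
               width = object$model_config$width, seed = object$seed,
               best_epoch = object$best_epoch,
               n_params = length(unlist(object$state$weights)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vf_net
#' @export
load_vf_net <- function(path) {
  object <- readRDS(path)
  cfg <- object$model_config
  object$ptr <- .net_build(cfg$variant, cfg$input_size, cfg$width,
                           net_out_channels(cfg$variant),
                           as.integer(object$seed))
  .net_set_state(object$ptr, object$state)
  object
}
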