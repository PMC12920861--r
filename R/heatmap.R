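#' Default channel weights for the weighted-MSE loss
#'
#' The heatmap channels are ordered (LV, RV, A). The free-border landmarks
#' LV and RV carry more weight than the anterior commissure, reflecting
#' their role in delineating the vocal-fold free border.
#'
#' @return Named numeric vector `c(LV = 1.2, RV = 1.2, A = 1)`.
#' @export
channel_weights <- function() c(LV = 1.2, RV = 1.2, A = 1.0)

#' Encode a keypoint triplet as Gaussian heatmaps
#'
#' Each keypoint is represented by an unnormalized isotropic Gaussian
#' centered at the keypoint,
#' `f(x, y) = exp(-((x - xc)^2 + (y - yc)^2) / (2 sigma^2))`,
#' evaluated at every pixel center of the full grid (no truncation, no
#' renormalization), so the peak value is 1 at the pixel nearest the
#' keypoint. Channels are in fixed order (LV, RV, A). Occluded keypoints
#' (visibility 1) receive a standard Gaussian like visible ones.
#'
#' @param triplet A [vf_triplet()] with keypoints inside
#'   `[0, width) x [0, height)`.
#' @param height,width Heatmap dimensions in pixels.
#' @param sigma Gaussian spread in pixels (default 20, in 224-pixel space).
#' @return A `height x width x 3` array with values in `[0, 1]` and
#'   attribute `sigma`.
#' @export
encode_heatmaps <- function(triplet, height, width, sigma = 20) {
  stopifnot(inherits(triplet, "vf_triplet"))
  if (sigma <= 0) stop("sigma must be positive")
  m <- as.matrix(triplet)
  if (any(m[, "x"] < 0 | m[, "x"] >= width | m[, "y"] < 0 | m[, "y"] >= height))
    stop("keypoint outside the frame; clamp or skip during augmentation")
  xs <- 0:(width - 1)
  ys <- 0:(height - 1)
  out <- array(0, dim = c(height, width, 3))
  for (k in 1:3) {
    dx2 <- (xs - m[k, "x"])^2
    dy2 <- (ys - m[k, "y"])^2
    out[, , k] <- exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  }
  attr(out, "sigma") <- sigma
  out
}

#' Decode keypoints from a heatmap stack
#'
#' Per channel, returns the (x, y) of the maximum activation; ties are
#' broken by row-major scan order (first occurrence, scanning each row left
#' to right from the top). An all-constant channel is flagged with a
#' warning as a low-confidence prediction but still decoded.
#'
#' @param stack A `H x W x 3` heatmap array (channels LV, RV, A).
#' @return A [vf_triplet()] with visibility 2.
#' @export
decode_heatmaps <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1)
    stop("stack must be a non-empty H x W x 3 array")
  pts <- matrix(0, 3, 2)
  for (k in 1:3) {
    ch <- stack[, , k]
    if (max(ch) == min(ch))
      warning("all-constant heatmap channel ", k, ": low-confidence decode")
    # row-major order: scan y = 0, 1, ... and x left to right within a row
    rm_idx <- which(t(ch) == max(ch))[1] - 1
    W <- d[2]
    pts[k, ] <- c(rm_idx %% W, rm_idx %/% W)
  }
  vf_triplet(LV = pts[1, ], RV = pts[2, ], A = pts[3, ])
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("prediction and target shapes differ")
}

#' Heatmap training losses
#'
#' `wmse_loss` is the channel-weighted mean squared error: per channel the
#' squared differences are averaged over all pixels (and, for batched 4-d
#' input, over the batch), multiplied by the channel weight, and the
#' weighted channel means are summed. `mse_loss` is the plain global mean
#' squared error. `weighted_l1_loss` is the mean absolute error with each
#' element weighted by `w_hi` where the target is at least `threshold` and
#' `w_lo` elsewhere. `dice_loss` is the soft Dice loss
#' `1 - 2 sum(p t) / (sum(p) + sum(t) + eps)`; on binarized inputs it
#' equals `1 - 2TP / (2TP + FP + FN)` up to the smoothing `eps`.
#'
#' @param pred,true Arrays of identical shape (`H x W x C` or
#'   `H x W x C x N`); for `dice_loss`, a real-valued prediction in
#'   `[0, 1]` and a 0/1 mask.
#' @param w Positive channel weights in channel order (LV, RV, A).
#' @param threshold,w_hi,w_lo Weighted-l1 parameters: elements whose target
#'   value is `>= threshold` are weighted `w_hi`, others `w_lo`.
#' @param eps Smoothing constant guarding empty masks.
#' @return A non-negative scalar loss.
#' @export
wmse_loss <- function(pred, true, w = channel_weights()) {
  check_same_shape(pred, true)
  d <- dim(pred)
  if (is.null(d) || length(d) < 3) stop("expected an H x W x C (x N) array")
  C <- d[3]
  if (length(w) != C || any(w <= 0)) stop("need ", C, " positive channel weights")
  total <- 0
  for (k in seq_len(C)) {
    if (length(d) == 4) {
      dif <- pred[, , k, , drop = FALSE] - true[, , k, , drop = FALSE]
    } else {
      dif <- pred[, , k] - true[, , k]
    }
    total <- total + w[k] * mean(dif^2)
  }
  unname(total)
}

#' @rdname wmse_loss
#' @export
mse_loss <- function(pred, true) {
  check_same_shape(pred, true)
  mean((pred - true)^2)
}

#' @rdname wmse_loss
#' @export
weighted_l1_loss <- function(pred, true, threshold = 0.5, w_hi = 2, w_lo = 1) {
  check_same_shape(pred, true)
  wmap <- ifelse(true >= threshold, w_hi, w_lo)
  mean(abs(pred - true) * wmap)
}

#' @rdname wmse_loss
#' @export
dice_loss <- function(pred, true, eps = 1e-7) {
  check_same_shape(pred, true)
  1 - 2 * sum(pred * true) / (sum(pred) + sum(true) + eps)
}

#' Persist a heatmap stack losslessly
#'
#' Writes an `H x W x C` stack to a simple array container: a JSON header
#' line `{"dims": [H, W, C], "sigma": s}` terminated by a newline,
#' followed by the values as little-endian float64 in R's native
#' column-major order. The round trip is exact.
#'
#' @param stack A numeric array (e.g. from [encode_heatmaps()]).
#' @param path File path (conventionally `.hms`).
#' @return `write_heatmap_stack` returns `path` invisibly;
#'   `read_heatmap_stack` returns the array with its `sigma` attribute.
#' @export
write_heatmap_stack <- function(stack, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(dims = dim(stack),
                               sigma = attr(stack, "sigma")),
                          auto_unbox = FALSE, digits = NA, null = "null")
  writeLines(as.character(hdr), con)
  writeBin(as.numeric(stack), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_heatmap_stack
#' @export
read_heatmap_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1))
  vals <- readBin(con, "numeric", n = prod(hdr$dims), size = 8,
                  endian = "little")
  out <- array(vals, dim = hdr$dims)
  if (!is.null(hdr$sigma)) attr(out, "sigma") <- hdr$sigma
  out
}
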