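#' Construct a frame record
#'
#' A `vf_frame` bundles one laryngoscopy frame with its annotation and
#' study metadata: the RGB image (`H x W x 3` array in `[0, 1]`), the
#' keypoint triplet, an opaque patient identifier (used for grouped
#' cross-validation), the oncologic flag, the imaging modality and an
#' opaque frame identifier.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param triplet A [vf_triplet()] with keypoints inside the image bounds.
#' @param patient_id,frame_id Non-empty strings.
#' @param oncologic Logical: frame from a patient with squamous cell
#'   carcinoma.
#' @param modality `"white_light"` or `"narrow_band"`.
#' @return An object of class `vf_frame`.
#' @export
vf_frame <- function(image, triplet, patient_id, frame_id,
                     oncologic = FALSE, modality = "white_light") {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be an H x W x 3 array")
  stopifnot(inherits(triplet, "vf_triplet"))
  m <- as.matrix(triplet)
  if (any(m[, "x"] < 0 | m[, "x"] > d[2] - 1 | m[, "y"] < 0 | m[, "y"] > d[1] - 1))
    stop("keypoints outside image bounds for frame ", frame_id)
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  modality <- match.arg(modality, c("white_light", "narrow_band"))
  structure(list(image = image, triplet = triplet,
                 patient_id = as.character(patient_id),
                 frame_id = as.character(frame_id),
                 oncologic = isTRUE(oncologic), modality = modality),
            class = "vf_frame")
}

#' @export
print.vf_frame <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Frame %s  patient %s  %dx%d  %s%s\n", x$frame_id, x$patient_id,
              d[2], d[1], x$modality, if (x$oncologic) "  [oncologic]" else ""))
  invisible(x)
}

#' Load a COCO-keypoint laryngoscopy dataset
#'
#' Reads a COCO Keypoint JSON annotation file together with its image
#' directory. The category must define the three keypoints LV, RV, A (in
#' any order); each annotation carries flat `[x, y, v]` triples with COCO
#' visibility flags. Keypoints with visibility 0 (absent) are rejected by
#' default because they cannot supervise pose estimation.
#'
#' @param images_dir Directory containing the image files.
#' @param annotations_path Path to the COCO JSON file.
#' @param allow_absent If `TRUE`, visibility-0 keypoints are kept instead
#'   of raising an error.
#' @return A list of [vf_frame()] records.
#' @export
load_dataset <- function(images_dir, annotations_path, allow_absent = FALSE) {
  if (!file.exists(annotations_path))
    stop("annotation file not found: ", annotations_path)
  coco <- tryCatch(jsonlite::read_json(annotations_path),
                   error = function(e) stop("malformed COCO JSON: ",
                                            conditionMessage(e)))
  for (field in c("images", "annotations", "categories"))
    if (is.null(coco[[field]])) stop("malformed COCO JSON: missing '", field, "'")
  kp_names <- unlist(coco$categories[[1]]$keypoints)
  if (!setequal(kp_names, c("LV", "RV", "A")))
    stop("COCO category must define keypoints LV, RV, A")
  ann_by_img <- split(coco$annotations,
                      vapply(coco$annotations, function(a) a$image_id, numeric(1)))
  records <- vector("list", length(coco$images))
  for (i in seq_along(coco$images)) {
    im <- coco$images[[i]]
    frame_id <- sub("\\.[^.]+$", "", im$file_name)
    path <- file.path(images_dir, im$file_name)
    if (!file.exists(path))
      stop("image file missing for frame ", frame_id, ": ", path)
    anns <- ann_by_img[[as.character(im$id)]]
    if (is.null(anns) || length(anns) != 1)
      stop("frame ", frame_id, " must have exactly one annotation")
    kp <- unlist(anns[[1]]$keypoints)
    if (length(kp) != 9)
      stop("frame ", frame_id, " must have exactly 3 keypoints (9 values)")
    xyz <- matrix(kp, ncol = 3, byrow = TRUE,
                  dimnames = list(kp_names, c("x", "y", "v")))
    if (!allow_absent && any(xyz[, "v"] == 0))
      stop("frame ", frame_id, " has an absent (visibility 0) keypoint")
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    tri <- vf_triplet(LV = xyz["LV", 1:2], RV = xyz["RV", 1:2],
                      A = xyz["A", 1:2],
                      visibility = as.integer(xyz[c("LV", "RV", "A"), "v"]))
    records[[i]] <- vf_frame(img, tri,
                             patient_id = im$patient_id %||% stop(
                               "frame ", frame_id, " lacks a patient_id"),
                             frame_id = frame_id,
                             oncologic = isTRUE(im$oncologic),
                             modality = im$modality %||% "white_light")
  }
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write frame records as a COCO-keypoint dataset
#'
#' Writes one PNG per frame plus an `annotations.json` in COCO Keypoint
#' format (with `patient_id`, `oncologic` and `modality` carried as extra
#' image fields), readable back by [load_dataset()] without loss of the
#' keypoint coordinates.
#'
#' @param records List of [vf_frame()] records.
#' @param dir Output directory (created if missing).
#' @return The annotation file path, invisibly.
#' @export
write_coco_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  images <- list(); annotations <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    d <- dim(r$image)
    fn <- paste0(r$frame_id, ".png")
    png::writePNG(r$image, file.path(dir, fn))
    images[[i]] <- list(id = i, file_name = fn, width = d[2], height = d[1],
                        patient_id = r$patient_id, oncologic = r$oncologic,
                        modality = r$modality)
    m <- as.matrix(r$triplet)
    v <- r$triplet$visibility
    annotations[[i]] <- list(
      id = i, image_id = i, category_id = 1, num_keypoints = 3,
      keypoints = as.numeric(t(cbind(m, v[rownames(m)]))))
  }
  coco <- list(
    images = images, annotations = annotations,
    categories = list(list(id = 1, name = "glottis",
                           keypoints = list("LV", "RV", "A"),
                           skeleton = list(c(1, 3), c(2, 3)))))
  path <- file.path(dir, "annotations.json")
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Preprocess a frame for the network
#'
#' Bilinearly resizes the image to `target x target` (anisotropically: x is
#' scaled by `target/width` and y by `target/height`), rescales the
#' keypoints with the same factors, optionally applies an augmentation
#' function on the resized `[0, 1]` image, and finally removes the
#' per-channel mean intensity. The channel means that were subtracted are
#' attached as attribute `channel_means`.
#'
#' @param record A [vf_frame()], or a list with elements `image` and
#'   `triplet`.
#' @param target Output side length in pixels (default 224).
#' @param augment Optional function `(image, triplet) -> list(image, triplet)`
#'   applied after resizing and before mean removal (see [augment_frame()]).
#' @return A list with `image` (zero-mean `target x target x 3` array) and
#'   `triplet` (rescaled [vf_triplet()]).
#' @export
preprocess_frame <- function(record, target = 224, augment = NULL) {
  img <- record$image
  tri <- record$triplet
  d <- dim(img)
  sx <- target / d[2]; sy <- target / d[1]
  if (d[1] != target || d[2] != target)
    img <- .resize_bilinear(img, target, target)
  tri <- transform_triplet(tri, diag(c(sx, sy)))
  if (!is.null(augment)) {
    aug <- augment(img, tri)
    img <- aug$image; tri <- aug$triplet
  }
  mu <- apply(img, 3, mean)
  for (k in 1:3) img[, , k] <- img[, , k] - mu[k]
  out <- list(image = img, triplet = tri)
  attr(out$image, "channel_means") <- mu
  out
}

# vectorized HSV -> RGB for n columns (h, s, v in [0, 1])
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' On-the-fly training augmentation
#'
#' Applies, each independently with probability 0.5: horizontal flip
#' (which also swaps the LV and RV labels, since mirroring reverses
#' anatomical left/right), vertical flip, random rotation about the image
#' center in `[-30, 30]` degrees, random brightness shift in
#' `[-0.1, 0.1]`, random hue rotation in `[-0.2, 0.2]` (fractions of the
#' hue wheel) and random saturation scaling in `[0.5, 1.5]`. Keypoints are
#' transformed with the same geometric maps. If a rotation would move any
#' keypoint outside the frame it is resampled up to 5 times and then
#' skipped. Results are deterministic under a seeded R RNG.
#'
#' @param image `H x W x 3` array in `[0, 1]` (resized, before mean
#'   removal).
#' @param triplet The matching [vf_triplet()].
#' @param rotation_range Maximum absolute rotation in degrees.
#' @param prob Per-transform application probability.
#' @param color If `FALSE`, only the geometric transforms are applied
#'   (used when augmenting non-photometric stacks such as heatmaps).
#' @param swap_channels_on_hflip If `TRUE`, a horizontal flip also swaps
#'   image channels 1 and 2. RGB frames must keep their channels
#'   (`FALSE`, the default), but a (LV, RV, A) heatmap stack must swap its
#'   first two channels when the LV/RV labels swap.
#' @return A list with augmented `image` and `triplet`.
#' @export
augment_frame <- function(image, triplet, rotation_range = 30, prob = 0.5,
                          color = TRUE, swap_channels_on_hflip = FALSE) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (stats::runif(1) < prob) {  # horizontal flip: x -> W-1-x, swap LV/RV
    image <- image[, W:1, , drop = FALSE]
    if (swap_channels_on_hflip) image <- image[, , c(2, 1, 3), drop = FALSE]
    triplet <- vf_triplet(LV = c(W - 1 - triplet$RV["x"], triplet$RV["y"]),
                          RV = c(W - 1 - triplet$LV["x"], triplet$LV["y"]),
                          A = c(W - 1 - triplet$A["x"], triplet$A["y"]),
                          visibility = triplet$visibility[c(2, 1, 3)])
  }
  if (stats::runif(1) < prob) {  # vertical flip: y -> H-1-y
    image <- image[H:1, , , drop = FALSE]
    f <- function(p) c(p["x"], H - 1 - p["y"])
    triplet <- vf_triplet(f(triplet$LV), f(triplet$RV), f(triplet$A),
                          visibility = triplet$visibility)
  }
  if (stats::runif(1) < prob) {  # rotation about the image center
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    for (attempt in 1:5) {
      ang <- stats::runif(1, -rotation_range, rotation_range) * pi / 180
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      tri2 <- transform_triplet(triplet, R, c(cx, cy) - R %*% c(cx, cy))
      m <- as.matrix(tri2)
      inside <- all(m[, "x"] >= 0 & m[, "x"] <= W - 1 &
                      m[, "y"] >= 0 & m[, "y"] <= H - 1)
      if (inside) {
        # inverse map for the image warp
        Ri <- t(R)
        off <- c(cx, cy) - Ri %*% c(cx, cy)
        image <- .affine_warp(image, c(Ri[1, 1], Ri[1, 2], off[1],
                                       Ri[2, 1], Ri[2, 2], off[2]), 0)
        triplet <- tri2
        break
      }
    }
  }
  if (color) {
    if (stats::runif(1) < prob) {  # brightness
      image <- pmin(pmax(image + stats::runif(1, -0.1, 0.1), 0), 1)
    }
    do_hue <- stats::runif(1) < prob
    do_sat <- stats::runif(1) < prob
    if (do_hue || do_sat) {
      dh <- if (do_hue) stats::runif(1, -0.2, 0.2) else 0
      ds <- if (do_sat) stats::runif(1, 0.5, 1.5) else 1
      rgb <- matrix(image, ncol = 3)
      hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
      rgb2 <- hsv_to_rgb((hsv[, 1] + dh) %% 1, pmin(pmax(hsv[, 2] * ds, 0), 1),
                         hsv[, 3])
      image <- array(pmin(pmax(rgb2, 0), 1), dim = d)
    }
  }
  list(image = image, triplet = triplet)
}

#' Patient-grouped cross-validation folds
#'
#' Shuffles the patients with the given seed and partitions them into `k`
#' near-equal test groups (sizes differing by at most one patient). Within
#' each fold, a fraction of the remaining training patients is held out as
#' a validation set for early stopping. No patient ever appears in more
#' than one of the train+validation and test sides of a fold.
#'
#' @param records List of [vf_frame()] records.
#' @param k Number of folds (default 5).
#' @param val_fraction Fraction of training patients held out for
#'   validation (default 0.2).
#' @param seed Integer seed for the patient shuffle.
#' @return A list of `k` fold splits, each of class `vf_fold_split` with
#'   elements `fold_index` (0-based), `train_ids`, `val_ids`, `test_ids`
#'   (frame identifiers) and the corresponding `*_patients` sets.
#' @export
make_patient_folds <- function(records, k = 5, val_fraction = 0.2, seed = 1) {
  pid <- vapply(records, function(r) r$patient_id, character(1))
  fid <- vapply(records, function(r) r$frame_id, character(1))
  patients <- unique(pid)
  if (k > length(patients))
    stop("k = ", k, " exceeds the number of patients (", length(patients), ")")
  shuffled <- with_seed(seed, sample(patients))
  groups <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    test_p <- groups[[i]]
    rest <- setdiff(shuffled, test_p)
    n_val <- max(1L, round(val_fraction * length(rest)))
    val_p <- with_seed(seed + 1000L + i, sample(rest, n_val))
    train_p <- setdiff(rest, val_p)
    folds[[i]] <- structure(list(
      fold_index = i - 1L,
      train_ids = fid[pid %in% train_p],
      val_ids = fid[pid %in% val_p],
      test_ids = fid[pid %in% test_p],
      train_patients = train_p, val_patients = val_p, test_patients = test_p),
      class = "vf_fold_split")
  }
  folds
}

#' @export
print.vf_fold_split <- function(x, ...) {
  cat(sprintf("Fold %d: %d train / %d val / %d test frames (%d/%d/%d patients)\n",
              x$fold_index, length(x$train_ids), length(x$val_ids),
              length(x$test_ids), length(x$train_patients),
              length(x$val_patients), length(x$test_patients)))
  invisible(x)
}

#' Export fold assignments as CSV
#'
#' @param folds Result of [make_patient_folds()].
#' @param records The records the folds were built from.
#' @param path Output CSV path with columns frame_id, patient_id, fold, role.
#' @return The path, invisibly.
#' @export
export_folds_csv <- function(folds, records, path) {
  pid <- stats::setNames(vapply(records, function(r) r$patient_id, character(1)),
                         vapply(records, function(r) r$frame_id, character(1)))
  rows <- do.call(rbind, lapply(folds, function(f) {
    do.call(rbind, lapply(c("train", "val", "test"), function(role) {
      ids <- f[[paste0(role, "_ids")]]
      if (!length(ids)) return(NULL)
      data.frame(frame_id = ids, patient_id = unname(pid[ids]),
                 fold = f$fold_index, role = role)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
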