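#' Three-keypoint annotation of a laryngoscopy frame
#'
#' A `vf_triplet` holds the three anatomical landmarks used for vocal-fold
#' pose estimation: the posterior angle of the left vocal fold (`LV`), the
#' posterior angle of the right vocal fold (`RV`), and the anterior
#' commissure (`A`). Coordinates are 0-based pixel centers with x growing
#' rightward and y growing downward (image convention). Visibility flags
#' follow the COCO keypoint convention: 0 = absent, 1 = present but not
#' visible (occluded), 2 = visible.
#'
#' @param LV,RV,A Numeric length-2 vectors `c(x, y)`.
#' @param visibility Integer length-3 vector of COCO flags for LV, RV, A.
#' @return An object of class `vf_triplet`: a list with elements `LV`,
#'   `RV`, `A` (named numeric `c(x, y)` vectors) and `visibility`.
#' @examples
#' tri <- vf_triplet(LV = c(90, 40), RV = c(134, 40), A = c(112, 200))
#' compute_aga(tri)
#' @export
vf_triplet <- function(LV, RV, A, visibility = c(2L, 2L, 2L)) {
  pts <- list(LV = LV, RV = RV, A = A)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2L || !all(is.finite(p)))
      stop("keypoint ", nm, " must be a finite numeric (x, y) pair")
    pts[[nm]] <- c(x = p[1L], y = p[2L])
  }
  visibility <- as.integer(visibility)
  if (length(visibility) != 3L || !all(visibility %in% 0:2))
    stop("visibility flags must be three values in {0, 1, 2}")
  structure(c(pts, list(visibility = stats::setNames(visibility, c("LV", "RV", "A")))),
            class = "vf_triplet")
}

#' @export
print.vf_triplet <- function(x, ...) {
  cat("Vocal-fold keypoint triplet (pixels, 0-based)\n")
  for (nm in c("LV", "RV", "A"))
    cat(sprintf("  %-2s (%8.3f, %8.3f)  visibility %d\n",
                nm, x[[nm]]["x"], x[[nm]]["y"], x$visibility[[nm]]))
  invisible(x)
}

#' @export
as.matrix.vf_triplet <- function(x, ...) {
  m <- rbind(LV = x$LV, RV = x$RV, A = x$A)
  colnames(m) <- c("x", "y")
  m
}

#' Apply an affine map to the keypoints of a triplet
#'
#' Internal helper: transforms each keypoint by `p' = M %*% c(x, y) + t`.
#' @noRd
transform_triplet <- function(triplet, M, t = c(0, 0)) {
  f <- function(p) as.numeric(M %*% p[1:2] + t)
  vf_triplet(f(triplet$LV), f(triplet$RV), f(triplet$A),
             visibility = triplet$visibility)
}

#' Write / read keypoint triplets as JSON
#'
#' Vertices are stored as records `{"LV": [x, y], "RV": [x, y], "A": [x, y]}`.
#'
#' @param triplet A [vf_triplet()].
#' @param path File path.
#' @return `write_triplet_json` returns `path` invisibly;
#'   `read_triplet_json` returns a [vf_triplet()].
#' @export
write_triplet_json <- function(triplet, path) {
  stopifnot(inherits(triplet, "vf_triplet"))
  obj <- list(LV = unname(triplet$LV), RV = unname(triplet$RV),
              A = unname(triplet$A))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_triplet_json
#' @export
read_triplet_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vf_triplet(obj$LV, obj$RV, obj$A)
}
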