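#' Anterior glottic angle from a keypoint triplet
#'
#' The anterior glottic angle (AGA) is the angle at the anterior commissure
#' `A` between the two vocal-fold free borders, i.e. between the vector from
#' `A` to `LV` and the vector from `A` to `RV`. It is computed with the
#' two-argument arctangent of the (cross, dot) products of the two vectors
#' and reported as an unsigned magnitude in degrees, in `[0, 180]` --
#' clinical AGA is a magnitude, so the sign of the oriented angle is
#' discarded.
#'
#' @param triplet A [vf_triplet()].
#' @return The AGA in degrees (numeric scalar in `[0, 180]`).
#' @examples
#' compute_aga(vf_triplet(LV = c(1, 0), RV = c(0, 1), A = c(0, 0)))  # 90
#' @export
compute_aga <- function(triplet) {
  stopifnot(inherits(triplet, "vf_triplet"))
  u <- triplet$LV[1:2] - triplet$A[1:2]
  v <- triplet$RV[1:2] - triplet$A[1:2]
  if (sum(u^2) == 0 || sum(v^2) == 0)
    stop("degenerate triplet: a keypoint coincides with the anterior commissure")
  cross <- u[[1]] * v[[2]] - u[[2]] * v[[1]]
  dot <- sum(u * v)
  unname(abs(atan2(cross, dot)) * 180 / pi)
}

#' Rasterize the glottal triangle as a binary mask
#'
#' Forms the triangle with vertices `LV`, `A`, `RV` and returns the binary
#' mask in which pixel centers strictly inside or on the triangle boundary
#' are 1 and all other pixels are 0. This is the ground-truth construction
#' for the glottal-segmentation baseline.
#'
#' @param triplet A [vf_triplet()].
#' @param height,width Mask dimensions in pixels.
#' @return An integer `height x width` matrix of 0/1 values.
#' @export
triangle_mask <- function(triplet, height, width) {
  stopifnot(inherits(triplet, "vf_triplet"))
  height <- as.integer(height); width <- as.integer(width)
  if (height <= 0 || width <= 0) stop("height and width must be positive")
  m <- as.matrix(triplet)
  .raster_triangle(m[c("LV", "A", "RV"), "x"], m[c("LV", "A", "RV"), "y"],
                   height, width)
}

# Support value of a point set for unit normals at angles theta (vectorized):
# h(theta) = max_p (p . n(theta)).
support_values <- function(P, theta) {
  N <- cbind(cos(theta), sin(theta))
  apply(N %*% t(P), 1L, max)
}

# Area and vertices of the triangle bounded by three supporting lines
# n_i . p = h_i. Returns NULL when the configuration is unbounded or
# degenerate.
tangent_triangle <- function(theta, h) {
  o <- order(theta)
  theta <- theta[o]; h <- h[o]
  gaps <- diff(c(theta, theta[1] + 2 * pi))
  if (any(gaps >= pi - 1e-12)) return(NULL)
  nx <- cos(theta); ny <- sin(theta)
  i <- c(1L, 2L, 3L); j <- c(2L, 3L, 1L)
  D <- nx[i] * ny[j] - ny[i] * nx[j]
  if (any(abs(D) < 1e-12)) return(NULL)
  px <- (h[i] * ny[j] - h[j] * ny[i]) / D
  py <- (nx[i] * h[j] - nx[j] * h[i]) / D
  area <- abs((px[2] - px[1]) * (py[3] - py[1]) -
                (py[2] - py[1]) * (px[3] - px[1])) / 2
  list(vertices = cbind(x = px, y = py), area = area)
}

#' Minimum enclosing triangle of a binary mask
#'
#' Computes the smallest-area triangle that contains every foreground pixel
#' center of `mask`. The convex hull of the foreground pixels is taken
#' first; candidate triangles are formed from supporting lines flush with
#' hull edges (a flush-side search over all edge-normal triples), and the
#' best candidate is then refined by Nelder-Mead over the three supporting
#' line orientations. This is how keypoints are decoded from a predicted
#' glottal segmentation mask.
#'
#' @param mask A 0/1 matrix (rows = y, columns = x), or an n x 2 matrix of
#'   `(x, y)` points when `points = TRUE`.
#' @param points If `TRUE`, `mask` is interpreted directly as point
#'   coordinates rather than as an image.
#' @return A list with `vertices` (3 x 2 matrix of unlabeled `(x, y)`
#'   vertices) and `area`. Use [label_triangle_vertices()] to assign
#'   LV/RV/A identities.
#' @seealso [label_triangle_vertices()]
#' @export
min_enclosing_triangle <- function(mask, points = FALSE) {
  if (points) {
    P <- as.matrix(mask)
  } else {
    idx <- which(mask != 0, arr.ind = TRUE)
    if (nrow(idx) == 0)
      stop("undecodable mask: no foreground pixels")
    P <- cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
  }
  if (nrow(P) < 3)
    stop("undecodable mask: fewer than 3 foreground points")
  hull <- grDevices::chull(P[, 1], P[, 2])
  H <- P[hull, , drop = FALSE]
  m <- nrow(H)
  if (m < 3) stop("undecodable mask: foreground points are collinear")
  # orientation-independent outward edge normals
  cx <- mean(H[, 1]); cy <- mean(H[, 2])
  e <- H[c(2:m, 1), , drop = FALSE] - H
  keep <- rowSums(e^2) > 0
  e <- e[keep, , drop = FALSE]
  mids <- (H + H[c(2:m, 1), , drop = FALSE])[keep, , drop = FALSE] / 2
  n1 <- cbind(e[, 2], -e[, 1])
  flip <- (n1[, 1] * (mids[, 1] - cx) + n1[, 2] * (mids[, 2] - cy)) < 0
  n1[flip, ] <- -n1[flip, ]
  theta <- sort(unique(round(atan2(n1[, 2], n1[, 1]), 12)))
  k <- length(theta)
  if (k < 3) stop("undecodable mask: foreground points are collinear")
  hv <- support_values(H, theta)
  combos <- utils::combn(k, 3L)
  t1 <- theta[combos[1, ]]; t2 <- theta[combos[2, ]]; t3 <- theta[combos[3, ]]
  # boundedness: successive angular gaps all < pi (angles already sorted)
  g1 <- t2 - t1; g2 <- t3 - t2; g3 <- 2 * pi - (t3 - t1)
  ok <- g1 < pi - 1e-12 & g2 < pi - 1e-12 & g3 < pi - 1e-12
  if (!any(ok)) stop("undecodable mask: no bounded enclosing triangle found")
  besta <- Inf; best <- NULL
  idx_ok <- which(ok)
  h1 <- hv[combos[1, idx_ok]]; h2 <- hv[combos[2, idx_ok]]; h3 <- hv[combos[3, idx_ok]]
  a1 <- t1[idx_ok]; a2 <- t2[idx_ok]; a3 <- t3[idx_ok]
  # vertices of each candidate (vectorized over candidates)
  vert <- function(ta, tb, ha, hb) {
    D <- cos(ta) * sin(tb) - sin(ta) * cos(tb)
    cbind((ha * sin(tb) - hb * sin(ta)) / D,
          (cos(ta) * hb - cos(tb) * ha) / D)
  }
  v12 <- vert(a1, a2, h1, h2); v23 <- vert(a2, a3, h2, h3); v31 <- vert(a3, a1, h3, h1)
  areas <- abs((v23[, 1] - v12[, 1]) * (v31[, 2] - v12[, 2]) -
                 (v23[, 2] - v12[, 2]) * (v31[, 1] - v12[, 1])) / 2
  b <- which.min(areas)
  besta <- areas[b]
  best_theta <- c(a1[b], a2[b], a3[b])
  # continuous refinement of the three supporting-line orientations
  obj <- function(th) {
    tt <- tangent_triangle(th, support_values(H, th))
    if (is.null(tt)) return(Inf)
    tt$area
  }
  opt <- stats::optim(best_theta, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  if (is.finite(opt$value) && opt$value < besta) {
    tt <- tangent_triangle(opt$par, support_values(H, opt$par))
    return(list(vertices = tt$vertices, area = tt$area))
  }
  tt <- tangent_triangle(best_theta, c(h1[b], h2[b], h3[b]))
  list(vertices = tt$vertices, area = besta)
}

#' Assign LV/RV/A identities to unlabeled triangle vertices
#'
#' The glottal triangle is elongated with its apex at the anterior
#' commissure, so the vertex with the smallest interior angle is labeled
#' `A`. The remaining two vertices are assigned so that the cross product
#' `(LV - A) x (RV - A)` is positive in image coordinates (y downward),
#' which places `LV` on the image right -- the anatomical left under the
#' endoscopic viewing convention. For an equilateral tie the apex is the
#' tied vertex with the lowest y, then the lowest x.
#'
#' @param vertices A 3 x 2 matrix of `(x, y)` vertices.
#' @return A [vf_triplet()] with visibility 2.
#' @export
label_triangle_vertices <- function(vertices) {
  V <- as.matrix(vertices)
  if (nrow(V) != 3 || ncol(V) != 2) stop("vertices must be a 3 x 2 matrix")
  ang <- numeric(3)
  for (i in 1:3) {
    u <- V[setdiff(1:3, i)[1], ] - V[i, ]
    v <- V[setdiff(1:3, i)[2], ] - V[i, ]
    cr <- u[1] * v[2] - u[2] * v[1]
    if (abs(cr) < 1e-12 * (sum(u^2) + sum(v^2)))
      stop("collinear vertices cannot be labeled")
    ang[i] <- abs(atan2(cr, sum(u * v)))
  }
  tol <- 1e-9
  cand <- which(ang <= min(ang) + tol)
  if (length(cand) > 1) {  # tie: lowest y, then lowest x
    cand <- cand[order(V[cand, 2], V[cand, 1])]
  }
  ai <- cand[1]
  rest <- setdiff(1:3, ai)
  p <- V[rest[1], ]; q <- V[rest[2], ]; a <- V[ai, ]
  cr <- (p[1] - a[1]) * (q[2] - a[2]) - (p[2] - a[2]) * (q[1] - a[1])
  if (cr > 0) {
    lv <- p; rv <- q
  } else {
    lv <- q; rv <- p
  }
  vf_triplet(LV = lv, RV = rv, A = a)
}

#' Read and write binary masks as single-channel PNG
#'
#' Masks are stored with foreground 255 and background 0.
#'
#' @param mask A 0/1 integer matrix.
#' @param path File path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a 0/1 integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- (img > 0.5) * 1L
  storage.mode(m) <- "integer"
  m
}
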