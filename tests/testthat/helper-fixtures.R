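# Shared fixtures built in code. Heavier objects are memoized so several
# test files can reuse them within one run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, expr, envir = fixture_env)
  get(key, envir = fixture_env)
}

# Small rendered synthetic dataset (low resolution, a handful of patients).
tiny_dataset <- function() {
  memo("tiny_dataset", {
    cfg <- synth_config(n_patients = 12, width = 96, height = 96, seed = 404)
    generate_dataset(cfg)
  })
}

# Random non-degenerate keypoint triplet inside a frame.
random_triplet <- function(w = 224, h = 224, margin = 6) {
  repeat {
    m <- cbind(runif(3, margin, w - 1 - margin), runif(3, margin, h - 1 - margin))
    cr <- (m[1, 1] - m[3, 1]) * (m[2, 2] - m[3, 2]) -
      (m[1, 2] - m[3, 2]) * (m[2, 1] - m[3, 1])
    if (abs(cr) > 1e-3) break
  }
  vf_triplet(LV = m[1, ], RV = m[2, ], A = m[3, ])
}

# Law-of-cosines oracle for the anterior glottic angle.
aga_oracle <- function(triplet) {
  u <- triplet$LV[1:2] - triplet$A[1:2]
  v <- triplet$RV[1:2] - triplet$A[1:2]
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Random convex polygon with n vertices (points on a noisy ellipse).
random_hull <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    th <- sort(runif(n, 0, 2 * pi))
    r <- runif(n, 8, 30)
    P <- cbind(x = 40 + r * cos(th), y = 40 + 0.7 * r * sin(th))
    P <- P[grDevices::chull(P), , drop = FALSE]
    if (nrow(P) == n) return(P)
  }
}

# Smallest triangle with every side tangent at angles from a fine grid:
# brute-force oracle for the minimum enclosing triangle.
grid_enclosing_area <- function(P, k = 72) {
  theta <- (seq_len(k) - 1) / k * 2 * pi
  h <- apply(cbind(cos(theta), sin(theta)) %*% t(P), 1, max)
  best <- Inf
  combos <- utils::combn(k, 3)
  for (j in seq_len(ncol(combos))) {
    tt <- vfpose:::tangent_triangle(theta[combos[, j]], h[combos[, j]])
    if (!is.null(tt) && tt$area < best) best <- tt$area
  }
  best
}

# Direct sum-of-squares oracle for the repeated-measures ANOVA, written as
# explicit loops (independent of the implementation's vectorized form).
rm_anova_oracle <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  grand <- sum(mat) / (n * m)
  ssm <- 0
  for (j in seq_len(m)) ssm <- ssm + n * (mean(mat[, j]) - grand)^2
  sss <- 0
  for (i in seq_len(n)) sss <- sss + m * (mean(mat[i, ]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) sst <- sst + (mat[i, j] - grand)^2
  sse <- sst - ssm - sss
  Fv <- (ssm / (m - 1)) / (sse / ((m - 1) * (n - 1)))
  list(F = Fv, eta_sq = ssm / sst)
}
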