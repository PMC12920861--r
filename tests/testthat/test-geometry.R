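test_that("anterior glottic angle matches closed-form cases", {
  expect_equal(compute_aga(vf_triplet(LV = c(1, 0), RV = c(0, 1), A = c(0, 0))), 90)
  expect_equal(compute_aga(vf_triplet(LV = c(3, 0), RV = c(6, 0), A = c(0, 0))), 0)
  tri <- vf_triplet(LV = c(90, 40), RV = c(134, 40), A = c(112, 200))
  expect_lt(abs(compute_aga(tri) - aga_oracle(tri)), 1e-9)
  expect_error(compute_aga(vf_triplet(LV = c(5, 5), RV = c(9, 1), A = c(5, 5))),
               "degenerate")
})

test_that("AGA is invariant under translation, scaling and rotation", {
  set.seed(11)
  for (i in 1:200) {
    tri <- random_triplet()
    a0 <- compute_aga(tri)
    sh <- runif(2, -50, 50)
    s <- runif(1, 0.2, 5)
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    tri2 <- vfpose:::transform_triplet(tri, s * R, sh)
    expect_lt(abs(compute_aga(tri2) - a0), 1e-7)
  }
})

test_that("triangle rasterization covers the frame and tracks the shoelace area", {
  full <- triangle_mask(vf_triplet(c(-100, -100), c(300, -100), c(100, 400)),
                        50, 50)
  expect_true(all(full == 1))
  tri <- vf_triplet(LV = c(10, 10), RV = c(50, 10), A = c(30, 40))
  m <- triangle_mask(tri, 60, 70)
  shoelace <- abs((50 - 10) * (40 - 10) - (10 - 10) * (30 - 10)) / 2
  per <- 40 + 2 * sqrt(20^2 + 30^2)
  expect_lt(abs(sum(m) - shoelace), per)
  expect_error(triangle_mask(vf_triplet(c(1, 1), c(3, 3), c(5, 5)), 10, 10),
               "collinear")
  expect_error(triangle_mask(tri, 0, 10), "positive")
})

test_that("minimum enclosing triangle recovers a rasterized triangle", {
  tri <- vf_triplet(LV = c(60, 95), RV = c(20, 90), A = c(40, 12))
  m <- triangle_mask(tri, 110, 90)
  fit <- min_enclosing_triangle(m)
  truth <- as.matrix(tri)[c("LV", "RV", "A"), ]
  # match each recovered vertex to its nearest true vertex
  for (i in 1:3) {
    d <- sqrt(rowSums((truth - matrix(fit$vertices[i, ], 3, 2,
                                      byrow = TRUE))^2))
    expect_lt(min(d), 2)
  }
  # containment of every foreground pixel center
  idx <- which(m == 1, arr.ind = TRUE)
  P <- cbind(idx[, "col"] - 1, idx[, "row"] - 1)
  V <- fit$vertices
  s <- (V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
    (V[2, 2] - V[1, 2]) * (V[3, 1] - V[1, 1])
  inside <- rep(TRUE, nrow(P))
  for (e in 1:3) {
    a <- V[e, ]; b <- V[e %% 3 + 1, ]
    cr <- (b[1] - a[1]) * (P[, 2] - a[2]) - (b[2] - a[2]) * (P[, 1] - a[1])
    inside <- inside & (sign(s) * cr >= -1e-6 * abs(s))
  }
  expect_true(all(inside))
})

test_that("degenerate masks are rejected as undecodable", {
  expect_error(min_enclosing_triangle(matrix(0L, 10, 10)), "undecodable")
  two <- matrix(0L, 10, 10); two[2, 2] <- 1L; two[5, 7] <- 1L
  expect_error(min_enclosing_triangle(two), "undecodable")
  line <- matrix(0L, 10, 10); line[3, 2:8] <- 1L
  expect_error(min_enclosing_triangle(line), "collinear")
})

test_that("vertex labeling puts the apex at A with a fixed orientation", {
  # elongated isoceles triangle, apex angle ~20 degrees, apex at the top
  apex <- c(50, 10)
  base1 <- c(50 - 100 * tan(10 * pi / 180), 110)
  base2 <- c(50 + 100 * tan(10 * pi / 180), 110)
  lab <- label_triangle_vertices(rbind(base1, base2, apex))
  expect_equal(unname(lab$A), apex)
  # LV on the image right (cross product convention)
  expect_gt(lab$LV["x"], lab$RV["x"])
  # mirror flip swaps LV and RV
  mir <- cbind(100 - rbind(base1, base2, apex)[, 1],
               rbind(base1, base2, apex)[, 2])
  labm <- label_triangle_vertices(mir)
  expect_equal(unname(labm$LV), c(100 - lab$RV[["x"]], lab$RV[["y"]]))
  expect_equal(unname(labm$RV), c(100 - lab$LV[["x"]], lab$LV[["y"]]))
})

test_that("equilateral tie-break is deterministic across vertex orders", {
  eq <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
  outs <- lapply(list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2),
                      c(2, 1, 3), c(3, 2, 1)),
                 function(o) label_triangle_vertices(eq[o, ]))
  for (o in outs[-1]) expect_equal(as.matrix(o), as.matrix(outs[[1]]))
  # apex tie resolved to lowest y then lowest x
  expect_equal(unname(outs[[1]]$A), c(0, 0))
})

test_that("mask PNG and triplet JSON round trips are faithful", {
  tri <- vf_triplet(LV = c(12, 30), RV = c(4, 28), A = c(8, 5))
  m <- triangle_mask(tri, 40, 20)
  p1 <- tempfile(fileext = ".png")
  write_mask_png(m, p1)
  expect_identical(read_mask_png(p1), m)
  p2 <- tempfile(fileext = ".json")
  write_triplet_json(tri, p2)
  tri2 <- read_triplet_json(p2)
  expect_equal(as.matrix(tri2), as.matrix(tri))
  unlink(c(p1, p2))
})
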