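test_that("heatmap encoding matches the Gaussian closed form", {
  tri <- vf_triplet(LV = c(30, 40), RV = c(80, 42), A = c(55, 100))
  hm <- encode_heatmaps(tri, 128, 128, sigma = 20)
  expect_equal(dim(hm), c(128, 128, 3))
  # peak exactly 1 at the integer keypoint location
  expect_equal(hm[41, 31, 1], 1.0)
  # distance exactly sigma along x: exp(-1/2)
  expect_equal(hm[41, 51, 1], exp(-0.5), tolerance = 1e-12)
  # pixel at Euclidean distance sigma*sqrt(2): value e^-1
  hm2 <- encode_heatmaps(vf_triplet(c(30, 40), c(80, 42), c(55, 100)),
                         128, 128, sigma = 20 / sqrt(2))
  expect_equal(hm2[41, 51, 1], exp(-1), tolerance = 1e-12)
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(encode_heatmaps(vf_triplet(c(-1, 4), c(5, 5), c(9, 9)), 20, 20),
               "outside")
  expect_error(encode_heatmaps(tri, 128, 128, sigma = 0), "sigma")
})

test_that("decoding inverts encoding for all sigmas", {
  set.seed(21)
  for (sigma in c(5, 10, 20)) {
    # integer keypoints: exact round trip
    for (i in 1:5) {
      m <- matrix(sample(5:58, 6), 3, 2)
      tri <- vf_triplet(m[1, ], m[2, ], m[3, ])
      dec <- decode_heatmaps(encode_heatmaps(tri, 64, 64, sigma))
      expect_equal(as.matrix(dec)[, 1:2], as.matrix(tri)[, 1:2])
    }
    # fractional keypoints: within 1 px, swept over sub-pixel offsets
    for (off in seq(0.05, 0.95, by = 0.15)) {
      tri <- vf_triplet(c(20 + off, 30 - off / 2), c(40 - off, 22 + off),
                        c(31 + off, 45 + off))
      dec <- decode_heatmaps(encode_heatmaps(tri, 64, 64, sigma))
      expect_lt(max(abs(as.matrix(dec)[, 1:2] - as.matrix(tri)[, 1:2])), 1)
    }
  }
})

test_that("decoding breaks ties in row-major order and flags flat channels", {
  st <- array(0, dim = c(8, 8, 3))
  st[3, 5, 1] <- 1; st[6, 2, 1] <- 1      # two equal maxima, channel 1
  st[4, 4, 2] <- 1
  st[2, 2, 3] <- 1
  tri <- decode_heatmaps(st)
  expect_equal(unname(tri$LV), c(4, 2))    # (x=4, y=2) precedes (x=1, y=5)
  flat <- array(0.5, dim = c(4, 4, 3))
  w <- capture_warnings(tri2 <- decode_heatmaps(flat))
  expect_length(w, 3)
  expect_match(w, "low-confidence", all = TRUE)
  expect_equal(unname(tri2$LV), c(0, 0))   # first position, row-major
})

test_that("weighted MSE follows its per-channel definition", {
  set.seed(5)
  p <- array(runif(2 * 3 * 3), dim = c(2, 3, 3))
  t0 <- array(runif(2 * 3 * 3), dim = c(2, 3, 3))
  expect_equal(wmse_loss(p, p), 0)
  # weight identity: w = 1 sums the per-channel MSEs
  byhand <- sum(sapply(1:3, function(k) mean((p[, , k] - t0[, , k])^2)))
  expect_equal(wmse_loss(p, t0, c(1, 1, 1)), byhand)
  # hand expansion of the weighted form on a 1 x 2 x 3 toy stack
  tp <- array(c(0.2, 0.8, 0.1, 0.4, 0.9, 0.3), dim = c(1, 2, 3))
  tt <- array(c(0.0, 1.0, 0.5, 0.4, 0.8, 0.2), dim = c(1, 2, 3))
  hand <- 1.2 * ((0.2 - 0)^2 + (0.8 - 1)^2) / 2 +
    1.2 * ((0.1 - 0.5)^2 + (0.4 - 0.4)^2) / 2 +
    1.0 * ((0.9 - 0.8)^2 + (0.3 - 0.2)^2) / 2
  expect_equal(wmse_loss(tp, tt), hand)
  # linear in each channel weight
  w <- c(1.2, 1.2, 1)
  for (k in 1:3) {
    w2 <- w; w2[k] <- 2 * w[k]
    ch <- if (k == 1) mean((p[, , 1] - t0[, , 1])^2) else
      if (k == 2) mean((p[, , 2] - t0[, , 2])^2) else
        mean((p[, , 3] - t0[, , 3])^2)
    expect_equal(wmse_loss(p, t0, w2) - wmse_loss(p, t0, w), w[k] * ch)
  }
  expect_error(wmse_loss(p, t0[, 1:2, ]), "shapes differ")
})

test_that("plain MSE and weighted l1 match hand computations", {
  a <- array(c(0.1, 0.7, 0.6, 0.2), dim = c(2, 2, 1))
  b <- array(c(0.3, 0.7, 0.9, 0.0), dim = c(2, 2, 1))
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, b), mean(c(0.2, 0, 0.3, 0.2)^2))
  expect_equal(weighted_l1_loss(a, a), 0)
  # equal weights reduce to the mean absolute error
  expect_equal(weighted_l1_loss(a, b, w_hi = 1, w_lo = 1),
               mean(abs(a - b)))
  # hand value: targets >= 0.5 weighted 2
  hand <- mean(c(1, 2, 2, 1) * abs(c(0.1 - 0.3, 0.7 - 0.7, 0.6 - 0.9,
                                     0.2 - 0.0)))
  expect_equal(weighted_l1_loss(a, b), hand)
})

test_that("heatmap stacks survive the array-container round trip exactly", {
  tri <- vf_triplet(c(10.5, 20.25), c(40, 22), c(31, 45))
  hm <- encode_heatmaps(tri, 64, 64, sigma = 10)
  f <- tempfile(fileext = ".hms")
  write_heatmap_stack(hm, f)
  back <- read_heatmap_stack(f)
  expect_identical(dim(back), dim(hm))
  expect_identical(as.numeric(back), as.numeric(hm))
  expect_equal(attr(back, "sigma"), 10)
  unlink(f)
})

test_that("soft Dice loss matches the overlap formula", {
  m1 <- matrix(c(1, 1, 1, 0), 2)
  expect_equal(dice_loss(m1, m1), 0, tolerance = 1e-6)
  expect_equal(dice_loss(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2)),
               1, tolerance = 1e-6)
  # TP = 2, FP = 1, FN = 1 -> 1 - 4/6
  expect_equal(dice_loss(matrix(c(1, 1, 1, 0), 2), matrix(c(1, 1, 0, 1), 2)),
               1 / 3, tolerance = 1e-6)
})
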