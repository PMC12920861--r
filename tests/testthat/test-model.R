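# Desk-scale network tests run at input size 64 and small widths; the
# architecture is identical to the full 224 configuration up to feature-map
# sizes.

test_that("network outputs honor shape and activation contracts", {
  net <- build_network(model_config("heatmap", 64, 0.35), seed = 2)
  x <- array(rnorm(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
  out <- vfpose:::.net_forward(net$ptr, x, FALSE)
  expect_equal(dim(out), c(64, 64, 3, 2))
  expect_true(all(out > 0 & out < 1))
  seg <- build_network(model_config("segmentation", 64, 0.35), seed = 2)
  expect_equal(dim(vfpose:::.net_forward(seg$ptr, x, FALSE)), c(64, 64, 1, 2))
  dir <- build_network(model_config("direct", 64, 0.35), seed = 2)
  o <- vfpose:::.net_forward(dir$ptr, x, FALSE)
  expect_equal(dim(o), c(1, 1, 6, 2))
  expect_true(all(o > 0 & o < 1))
  expect_error(model_config("heatmap", input_size = 100), "divisible")
})

test_that("parameter count matches an independent layer-by-layer tabulation", {
  # hand count at width 1: conv = cin*9*cout (+bias), pointwise = cin*cout,
  # depthwise = 9*c, batch norm = 2*c
  conv3 <- function(ci, co, bias = FALSE) ci * 9 * co + if (bias) co else 0
  pw <- function(ci, co) ci * co
  bn <- function(c) 2 * c
  block <- function(ci, co, t) {
    n <- 0
    ce <- ci * t
    if (t != 1) n <- n + pw(ci, ce) + bn(ce)
    n + 9 * ce + bn(ce) + pw(ce, co) + bn(co)
  }
  sched <- list(c(1, 16, 1), c(6, 24, 2), c(6, 32, 3), c(6, 64, 4),
                c(6, 96, 3), c(6, 160, 3), c(6, 320, 1))
  enc <- conv3(3, 32) + bn(32)
  cin <- 32
  for (g in sched) for (r in seq_len(g[3])) {
    enc <- enc + block(cin, g[2], g[1]); cin <- g[2]
  }
  expect_lt(abs(enc - 1811712) / 1811712, 0.2)  # published MobileNetV2 backbone
  dec <- 0
  skips <- c(96, 32, 24, 16)
  dch <- c(256, 128, 64, 32)
  prev <- 320
  for (i in 1:4) {
    dec <- dec + conv3(prev + skips[i], dch[i]) + bn(dch[i]) +
      conv3(dch[i], dch[i]) + bn(dch[i])
    prev <- dch[i]
  }
  head <- conv3(32, 16, TRUE) + conv3(16, 16, TRUE) + conv3(16, 3, TRUE)
  hand_total <- enc + dec + head
  net <- build_network(model_config("heatmap", 224, 1.0), seed = 1)
  expect_lt(abs(n_params(net) - hand_total) / hand_total, 0.2)
})

test_that("backpropagated gradients match finite differences on the head", {
  set.seed(7)
  S <- 32
  net <- build_network(model_config("heatmap", S, 0.25), seed = 3)
  x <- array(rnorm(S * S * 3 * 2), dim = c(S, S, 3, 2))
  y <- array(runif(S * S * 3 * 2), dim = c(S, S, 3, 2))
  w <- c(1.2, 1.2, 1)
  invisible(vfpose:::.net_step(net$ptr, x, y, "wmse", w, 0, FALSE))
  gr <- vfpose:::.net_get_grads(net$ptr)
  np <- length(gr)
  worst <- 0
  for (pi_ in (np - 5):np) {      # the three BN-free head convolutions
    for (rep in seq_len(min(3, length(gr[[pi_]])))) {
      ei <- order(abs(gr[[pi_]]), decreasing = TRUE)[rep]
      gan <- gr[[pi_]][ei]
      w0 <- vfpose:::.net_get_param_elem(net$ptr, pi_, ei)
      h <- 1e-3
      vfpose:::.net_set_param_elem(net$ptr, pi_, ei, w0 + h)
      lp <- vfpose:::.net_step(net$ptr, x, y, "wmse", w, 0, FALSE)
      vfpose:::.net_set_param_elem(net$ptr, pi_, ei, w0 - h)
      lm <- vfpose:::.net_step(net$ptr, x, y, "wmse", w, 0, FALSE)
      vfpose:::.net_set_param_elem(net$ptr, pi_, ei, w0)
      worst <- max(worst, abs((lp - lm) / (2 * h) - gan) / max(abs(gan), 1e-3))
    }
  }
  expect_lt(worst, 0.01)
})

test_that("unit channel weights reduce the weighted loss to scaled MSE", {
  set.seed(8)
  S <- 32
  net <- build_network(model_config("heatmap", S, 0.25), seed = 5)
  x <- array(rnorm(S * S * 3 * 4), dim = c(S, S, 3, 4))
  y <- array(runif(S * S * 3 * 4), dim = c(S, S, 3, 4))
  l1 <- vfpose:::.net_step(net$ptr, x, y, "wmse", c(1, 1, 1), 0, FALSE)
  g1 <- unlist(vfpose:::.net_get_grads(net$ptr))
  l2 <- vfpose:::.net_step(net$ptr, x, y, "mse", numeric(0), 0, FALSE)
  g2 <- unlist(vfpose:::.net_get_grads(net$ptr))
  # loss and first-step gradient are exactly the channel count times MSE,
  # up to float32 round-off
  expect_equal(l1, 3 * l2, tolerance = 1e-5)
  expect_lt(sqrt(sum((g1 - 3 * g2)^2)) / sqrt(sum(g1^2)), 0.01)
})

test_that("training reduces the loss and is reproducible under a seed", {
  ds <- tiny_dataset()
  recs <- ds$records
  tr <- recs[1:22]; va <- recs[23:30]
  cfg <- model_config("heatmap", 64, 0.35)
  ctl <- train_config(max_epochs = 6, patience = 5, learning_rate = 3e-3,
                      seed = 4, augment = FALSE)
  fit1 <- vf_train(tr, va, cfg, ctl)
  expect_lt(fit1$history$train_loss[nrow(fit1$history)],
            fit1$history$train_loss[1])
  fit2 <- vf_train(tr, va, cfg, ctl)
  expect_equal(fit1$history, fit2$history)
  expect_s3_class(fit1, "vf_net")
  expect_output(print(fit1), "heatmap")
  # predictions decode to in-frame keypoints
  p <- predict(fit1, recs[31:34])
  expect_length(p$triplets, 4)
  for (tri in p$triplets) {
    m <- as.matrix(tri)
    expect_true(all(m[, "x"] >= 0 & m[, "x"] <= 63 &
                      m[, "y"] >= 0 & m[, "y"] <= 63))
  }
})

test_that("early stopping halts after patience epochs without improvement", {
  ds <- tiny_dataset()
  tr <- ds$records[1:10]; va <- ds$records[11:14]
  # validation loss improves until epoch 3 and is then forced constant;
  # with patience 2 training must stop at epoch 5 with best epoch 3
  vals <- c(5, 4, 3, 3, 3, 3, 3, 3, 3, 3)
  epoch_i <- 0
  testthat::local_mocked_bindings(
    .net_eval_loss = function(...) {
      epoch_i <<- epoch_i + 1
      vals[min(epoch_i, length(vals))]
    },
    .package = "vfpose")
  ctl <- train_config(max_epochs = 10, patience = 2, learning_rate = 0,
                      seed = 1, augment = FALSE)
  fit <- vf_train(tr, va, model_config("heatmap", 64, 0.25), ctl)
  expect_equal(nrow(fit$history), 5)
  expect_equal(fit$best_epoch, 3)
  expect_error(vf_train(list(), va, model_config("heatmap", 64, 0.25), ctl),
               "empty")
})

test_that("direct-variant predictions land in the frame after de-normalization", {
  ds <- tiny_dataset()
  fit <- vf_train(ds$records[1:16], ds$records[17:20],
                  model_config("direct", 64, 0.25),
                  train_config(max_epochs = 2, patience = 1, loss = "coord_mse",
                               seed = 2, augment = FALSE))
  p <- predict(fit, ds$records[21:24])
  for (tri in p$triplets) {
    m <- as.matrix(tri)
    expect_true(all(m[, 1:2] >= 0 & m[, 1:2] <= 63))
  }
})

test_that("segmentation predictions threshold to binary masks", {
  ds <- tiny_dataset()
  fit <- vf_train(ds$records[1:16], ds$records[17:20],
                  model_config("segmentation", 64, 0.25),
                  train_config(max_epochs = 3, patience = 2, loss = "dice",
                               learning_rate = 3e-3, seed = 2,
                               augment = FALSE))
  p <- predict(fit, ds$records[21:24])
  for (mk in p$masks) expect_true(all(mk %in% c(0L, 1L)))
  expect_true(is.numeric(p$n_undecodable))
})

test_that("fitted networks survive a save/load round trip", {
  ds <- tiny_dataset()
  fit <- vf_train(ds$records[1:10], ds$records[11:14],
                  model_config("heatmap", 64, 0.25),
                  train_config(max_epochs = 2, patience = 1, seed = 6,
                               augment = FALSE))
  p1 <- predict(fit, ds$records[15:16])
  path <- tempfile(fileext = ".rds")
  save_vf_net(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_vf_net(path)
  p2 <- predict(back, ds$records[15:16])
  expect_equal(p1$raw, p2$raw)
  unlink(c(path, paste0(path, ".json")))
})
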