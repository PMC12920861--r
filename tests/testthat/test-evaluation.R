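test_that("per-keypoint error follows the coordinate RMSE convention", {
  a <- vf_triplet(c(10, 20), c(30, 40), c(50, 60))
  expect_equal(unname(keypoint_error(a, a)), c(0, 0, 0))
  b <- vf_triplet(c(13, 24), c(30, 40), c(57, 60))
  e <- keypoint_error(b, a)
  expect_equal(unname(e["LV"]), sqrt((3^2 + 4^2) / 2))
  expect_equal(unname(e["RV"]), 0)
  expect_equal(unname(e["A"]), 7 / sqrt(2))
})

test_that("AGA errors reduce to MAE and RMSE of the angle differences", {
  expect_equal(unname(aga_errors(c(10, 20), c(10, 20))), c(0, 0))
  expect_equal(unname(aga_errors(c(13, 17), c(10, 20))), c(3, 3))
  expect_equal(unname(aga_errors(c(10, 26), c(10, 20))), c(3, sqrt(18)))
  expect_error(aga_errors(numeric(0), numeric(0)), "no decodable")
})

test_that("DSC counts overlap like the confusion-matrix formula", {
  m <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dsc(m, m), 1)
  expect_equal(dsc(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2)), 0)
  expect_equal(dsc(matrix(c(1, 1, 1, 0), 2), matrix(c(1, 1, 0, 1), 2)), 2 / 3)
  expect_message(z <- dsc(matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
  expect_equal(z, 1)
})

test_that("cross-fold aggregation reproduces the published means", {
  tabs <- study_reference_tables()
  agg <- aggregate_folds(tabs[tabs$table == 1, ])
  lv <- agg$mean[agg$method == "heatmap" & agg$keypoint == "LV"]
  expect_equal(round(lv, 2), 5.09)
  ov <- agg$mean[agg$method == "heatmap" & agg$keypoint == "overall"]
  expect_equal(round(ov, 2), 6.02)
  agg2 <- aggregate_folds(tabs[tabs$table == 2, ])
  expect_equal(round(agg2$mean[agg2$method == "heatmap" &
                                 agg2$metric == "aga_mae_deg"], 2), 5.87)
  # constant columns aggregate to themselves
  const <- data.frame(fold = 0:4, method = "m", metric = "x",
                      keypoint = NA, mean = 7, sd = 1)
  expect_equal(aggregate_folds(const)$mean, 7)
})

test_that("repeated-measures ANOVA matches its oracle and aov", {
  tabs <- study_reference_tables()
  mae <- vfpose:::fold_method_matrix(tabs, "aga_mae_deg")
  an <- rm_anova(mae)
  expect_equal(round(an$F, 2), 9.64)
  expect_equal(an$df, c(2, 8))
  # no method effect when all columns are identical
  same <- matrix(rep(rnorm(5), 3), 5, 3)
  expect_equal(rm_anova(same)$F, 0)
  set.seed(14)
  for (i in 1:50) {
    mat <- matrix(rnorm(15, 10, 2), 5, 3)
    o <- rm_anova_oracle(mat)
    r <- rm_anova(mat)
    expect_lt(abs(r$F - o$F) / o$F, 1e-10)
    expect_lt(abs(r$eta_sq - o$eta_sq), 1e-12)
    # F invariant to shifting one whole fold row
    mat2 <- mat; mat2[3, ] <- mat2[3, ] + 5
    expect_equal(rm_anova(mat2)$F, r$F, tolerance = 1e-8)
  }
  # independent route: base R aov with a fold error stratum
  mat <- matrix(rnorm(15, 10, 2), 5, 3)
  d <- data.frame(y = as.vector(mat),
                  fold = factor(rep(1:5, 3)),
                  method = factor(rep(1:3, each = 5)))
  av <- summary(stats::aov(y ~ method + Error(fold), data = d))
  Faov <- av[["Error: Within"]][[1]]["method", "F value"]
  expect_equal(rm_anova(mat)$F, unname(Faov), tolerance = 1e-10)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3, 4, 5), 2)), "missing")
})

test_that("Holm correction is a monotone step-down bounded by 1", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(2)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))
    h <- holm_bonferroni(p)
    expect_true(all(h >= p - 1e-15))
    expect_true(all(h <= 1))
    o <- order(p)
    expect_true(all(diff(h[o]) >= -1e-15))
  }
})

test_that("Hedges' g reproduces the published effect sizes", {
  tabs <- study_reference_tables()
  rmse <- vfpose:::fold_method_matrix(tabs, "rmse_px")
  expect_equal(round(abs(hedges_g(rmse[, "heatmap"], rmse[, "direct"])), 2),
               2.76)
  x <- rnorm(5)
  expect_equal(hedges_g(x, x), 0)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "zero pooled")
})

test_that("pairwise comparisons reproduce the published Holm p-values", {
  tabs <- study_reference_tables()
  rmse <- vfpose:::fold_method_matrix(tabs, "rmse_px")
  pw <- pairwise_comparisons(rmse)
  expect_equal(round(pw$p_holm[pw$a == "heatmap" & pw$b == "direct"], 4),
               0.0227)
  expect_equal(round(pw$p_holm[pw$a == "heatmap" & pw$b == "segmentation"], 4),
               0.0853)
  cmp <- compare_methods(rmse)
  expect_s3_class(cmp, "vf_comparison")
  expect_output(print(cmp), "ANOVA")
})

test_that("subgroup metrics partition the frames exhaustively", {
  set.seed(6)
  true <- lapply(1:10, function(i) random_triplet(64, 64))
  pred <- lapply(true, function(tr)
    vfpose:::transform_triplet(tr, diag(2), c(1, -1)))
  flag <- rep(c(TRUE, FALSE), 5)
  sub <- subgroup_metrics(true, pred, flag)
  n_fl <- sub$n[sub$subgroup == "flagged" & sub$metric == "rmse_px"][1]
  n_un <- sub$n[sub$subgroup == "unflagged" & sub$metric == "rmse_px"][1]
  expect_equal(n_fl + n_un, 10)
  # a single-subgroup input marks the other subgroup absent
  sub2 <- subgroup_metrics(true, pred, rep(TRUE, 10))
  expect_true("absent" %in% sub2$metric[sub2$subgroup == "unflagged"])
  # missing predictions are excluded with a count
  pred2 <- lapply(seq_along(true), function(i) if (i == 1) NULL else pred[[i]])
  sub3 <- subgroup_metrics(true, pred2, flag)
  expect_equal(sub3$n_undecodable[sub3$subgroup == "flagged"][1], 1)
})

test_that("reference verification flags perturbed cells and bad schemas", {
  v <- verify_reference_aggregates()
  expect_true(attr(v, "all_pass"))
  tabs <- study_reference_tables()
  tabs$mean[tabs$method == "heatmap" & tabs$fold == 0 &
              tabs$metric == "rmse_px" & tabs$keypoint == "LV"] <- 9.99
  v2 <- verify_reference_aggregates(tabs)
  expect_false(attr(v2, "all_pass"))
  expect_false(v2$pass[v2$quantity == "rmse_px_lv_heatmap"])
  expect_error(verify_reference_aggregates(tabs[, setdiff(names(tabs), "sd")]),
               "columns")
})
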