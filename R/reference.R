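#' Per-fold reference results of the original clinical study
#'
#' The package ships, as a plain-text fixture, the per-fold test-set
#' results published for the three compared methods on the clinical
#' dataset (per-keypoint RMSE in pixels, and AGA MAE/RMSE in degrees,
#' each as mean and SD over the fold's test images). These cells let the
#' whole statistics layer be exercised and verified without any training.
#'
#' @return A data frame with columns table, fold, method, metric,
#'   keypoint, mean, sd.
#' @export
study_reference_tables <- function() {
  path <- system.file("extdata", "study_fold_results.csv", package = "vfpose")
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(keypoint = "character"))
}

# fold x method matrix of fold-level values for one metric; per-keypoint
# pixel errors are first averaged over the three keypoints within a fold.
fold_method_matrix <- function(tab, metric) {
  d <- tab[tab$metric == metric, ]
  folds <- sort(unique(d$fold))
  methods <- c("heatmap", "direct", "segmentation")
  mat <- sapply(methods, function(m) {
    vapply(folds, function(f) {
      cells <- d$mean[d$fold == f & d$method == m]
      mean(cells)
    }, numeric(1))
  })
  rownames(mat) <- paste0("fold", folds)
  mat
}

#' Recompute every published cross-fold aggregate and statistic
#'
#' From the per-fold reference cells ([study_reference_tables()]),
#' recomputes all cross-fold summary statistics reported for the study:
#' per-keypoint and overall cross-fold mean RMSE, the average degradation
#' of direct regression, cross-fold AGA MAE/RMSE means, the
#' repeated-measures ANOVAs (on fold-level keypoint-averaged RMSE and on
#' AGA MAE/RMSE), Holm-corrected paired comparisons and Hedges' g effect
#' sizes -- and compares each against the published value at its printed
#' precision.
#'
#' Effect sizes are compared as magnitudes because the published
#' comparison directions are not reported in a consistent order.
#'
#' @param tables Reference cells, by default [study_reference_tables()].
#' @return A data frame with columns quantity, computed, reported, tol,
#'   pass; attribute `all_pass`.
#' @export
verify_reference_aggregates <- function(tables = study_reference_tables()) {
  need <- c("table", "fold", "method", "metric", "keypoint", "mean", "sd")
  if (!all(need %in% names(tables)))
    stop("reference table lacks required columns: ",
         paste(setdiff(need, names(tables)), collapse = ", "))
  expected <- utils::read.csv(system.file("extdata",
                                          "study_reported_aggregates.csv",
                                          package = "vfpose"),
                              stringsAsFactors = FALSE)
  vals <- reference_aggregate_values(tables)
  out <- data.frame(quantity = expected$quantity,
                    computed = NA_real_, reported = expected$value,
                    tol = expected$tol, pass = NA)
  for (i in seq_len(nrow(out))) {
    q <- out$quantity[i]
    if (!q %in% names(vals)) next
    v <- vals[[q]]
    if (grepl("^g_", q)) v <- abs(v)
    out$computed[i] <- v
    out$pass[i] <- abs(v - out$reported[i]) <= out$tol[i] + 1e-12
  }
  attr(out, "all_pass") <- all(out$pass %in% TRUE)
  out
}

#' Recomputed aggregate values as a named list
#'
#' The same recomputation as [verify_reference_aggregates()] but returning
#' the raw computed values (signed effect sizes) without comparison.
#'
#' @param tables Reference cells, by default [study_reference_tables()].
#' @return A named list of numeric scalars.
#' @export
reference_aggregate_values <- function(tables = study_reference_tables()) {
  t1 <- tables[tables$table == 1, ]
  agg1 <- aggregate_folds(t1)
  pick <- function(m, k) agg1$mean[agg1$method == m & agg1$keypoint == k]
  rmse_mat <- fold_method_matrix(tables, "rmse_px")
  mae_mat <- fold_method_matrix(tables, "aga_mae_deg")
  armse_mat <- fold_method_matrix(tables, "aga_rmse_deg")
  an1 <- rm_anova(rmse_mat)
  an2 <- rm_anova(mae_mat)
  an3 <- rm_anova(armse_mat)
  pw1 <- pairwise_comparisons(rmse_mat)
  pw2 <- pairwise_comparisons(mae_mat)
  pw3 <- pairwise_comparisons(armse_mat)
  prow <- function(pw, a, b) pw[pw$a == a & pw$b == b, ]
  agg2 <- aggregate_folds(tables[tables$table == 2, ])
  pick2 <- function(m, metric) agg2$mean[agg2$method == m & agg2$metric == metric]
  list(
    rmse_px_lv_heatmap = pick("heatmap", "LV"),
    rmse_px_a_heatmap = pick("heatmap", "A"),
    rmse_px_rv_heatmap = pick("heatmap", "RV"),
    rmse_px_overall_heatmap = pick("heatmap", "overall"),
    rmse_px_delta_direct = pick("direct", "overall") - pick("heatmap", "overall"),
    anova_rmse_px_F = an1$F,
    anova_rmse_px_p = an1$p,
    g_rmse_px_heatmap_direct = prow(pw1, "heatmap", "direct")$hedges_g,
    g_rmse_px_heatmap_segmentation = prow(pw1, "heatmap", "segmentation")$hedges_g,
    g_rmse_px_direct_segmentation = prow(pw1, "direct", "segmentation")$hedges_g,
    holm_rmse_px_heatmap_direct = prow(pw1, "heatmap", "direct")$p_holm,
    holm_rmse_px_heatmap_segmentation =
      prow(pw1, "heatmap", "segmentation")$p_holm,
    holm_rmse_px_direct_segmentation =
      prow(pw1, "direct", "segmentation")$p_holm,
    aga_mae_heatmap = pick2("heatmap", "aga_mae_deg"),
    aga_mae_direct = pick2("direct", "aga_mae_deg"),
    aga_mae_segmentation = pick2("segmentation", "aga_mae_deg"),
    aga_rmse_heatmap = pick2("heatmap", "aga_rmse_deg"),
    aga_rmse_direct = pick2("direct", "aga_rmse_deg"),
    aga_rmse_segmentation = pick2("segmentation", "aga_rmse_deg"),
    anova_aga_mae_F = an2$F,
    anova_aga_mae_p = an2$p,
    anova_aga_mae_eta_sq = an2$eta_sq,
    g_aga_mae_heatmap_direct = prow(pw2, "heatmap", "direct")$hedges_g,
    g_aga_mae_heatmap_segmentation = prow(pw2, "heatmap", "segmentation")$hedges_g,
    holm_aga_mae_heatmap_direct = prow(pw2, "heatmap", "direct")$p_holm,
    holm_aga_mae_heatmap_segmentation =
      prow(pw2, "heatmap", "segmentation")$p_holm,
    anova_aga_rmse_F = an3$F,
    anova_aga_rmse_p = an3$p,
    anova_aga_rmse_eta_sq = an3$eta_sq,
    g_aga_rmse_direct_segmentation = prow(pw3, "direct", "segmentation")$hedges_g,
    g_aga_rmse_heatmap_segmentation = prow(pw3, "heatmap", "segmentation")$hedges_g,
    holm_aga_rmse_direct_segmentation =
      prow(pw3, "direct", "segmentation")$p_holm)
}

#' Plain-text report of the reference verification
#'
#' Renders the fold metrics layout plus the verification of every
#' recomputed aggregate, mirroring the study's table structure.
#'
#' @param verification Result of [verify_reference_aggregates()].
#' @return The verification data frame, invisibly; the report is printed.
#' @export
report_reference <- function(verification = verify_reference_aggregates()) {
  cat("Recomputed cross-fold aggregates vs published values\n")
  cat(sprintf("%-38s %10s %10s %6s\n", "quantity", "computed", "reported",
              "pass"))
  for (i in seq_len(nrow(verification)))
    cat(sprintf("%-38s %10.4f %10.4f %6s\n", verification$quantity[i],
                verification$computed[i], verification$reported[i],
                ifelse(isTRUE(verification$pass[i]), "yes", "NO")))
  cat(sprintf("all pass: %s\n", isTRUE(attr(verification, "all_pass"))))
  invisible(verification)
}
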