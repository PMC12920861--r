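#' Per-keypoint localization error
#'
#' For each keypoint the error is the root mean square of the two
#' coordinate differences, `sqrt((dx^2 + dy^2) / 2)` in pixels -- i.e. the
#' RMSE over the x and y coordinates of a single keypoint (the Euclidean
#' distance divided by sqrt(2)). Errors are reported in the network input
#' pixel space.
#'
#' @param pred,true [vf_triplet()] objects.
#' @return Named numeric vector `c(LV, RV, A)` in pixels.
#' @export
keypoint_error <- function(pred, true) {
  stopifnot(inherits(pred, "vf_triplet"), inherits(true, "vf_triplet"))
  d <- as.matrix(pred) - as.matrix(true)
  stats::setNames(sqrt(rowSums(d^2) / 2), rownames(d))
}

#' AGA error metrics
#'
#' Mean absolute error and root mean square error of the anterior glottic
#' angle over a set of frames, in degrees.
#'
#' @param preds,trues Numeric vectors of predicted and true AGA in
#'   degrees, or lists of [vf_triplet()] (angles are then computed).
#' @return Named numeric vector `c(mae, rmse)` in degrees.
#' @export
aga_errors <- function(preds, trues) {
  if (is.list(preds)) preds <- vapply(preds, compute_aga, numeric(1))
  if (is.list(trues)) trues <- vapply(trues, compute_aga, numeric(1))
  stopifnot(length(preds) == length(trues))
  if (length(preds) == 0) stop("no decodable prediction/truth pairs")
  d <- preds - trues
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 TP / (2 TP + FP + FN)`. Two empty masks score 1 by convention (a
#' message notes this degenerate case).
#'
#' @param pred_mask,true_mask 0/1 matrices of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred_mask, true_mask) {
  check_same_shape(pred_mask, true_mask)
  p <- pred_mask != 0; t <- true_mask != 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) {
    message("both masks empty: DSC = 1 by convention")
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Cross-fold aggregation of a fold metrics table
#'
#' Takes a long-format per-fold metrics table (columns `fold`, `method`,
#' `metric`, `keypoint`, `mean`, `sd`) and returns the unweighted mean of
#' the fold means per (method, metric, keypoint). For per-keypoint pixel
#' errors an `overall` row per method is added: the mean of the three
#' keypoint cross-fold means.
#'
#' @param table A data frame as produced by [run_experiment()] or
#'   [study_reference_tables()].
#' @return A data frame with columns method, metric, keypoint, mean.
#' @export
aggregate_folds <- function(table) {
  stopifnot(all(c("fold", "method", "metric", "mean") %in% names(table)))
  if (!"keypoint" %in% names(table)) table$keypoint <- ""
  table$keypoint[is.na(table$keypoint)] <- ""
  key <- interaction(table$method, table$metric, table$keypoint, drop = TRUE)
  agg <- do.call(rbind, lapply(split(table, key), function(d) {
    data.frame(method = d$method[1], metric = d$metric[1],
               keypoint = d$keypoint[1], mean = mean(d$mean))
  }))
  rownames(agg) <- NULL
  kp <- agg[!is.na(agg$keypoint) & agg$keypoint %in% c("LV", "RV", "A"), ]
  if (nrow(kp)) {
    ov <- do.call(rbind, lapply(split(kp, interaction(kp$method, kp$metric,
                                                      drop = TRUE)),
                                function(d) {
      if (nrow(d) != 3) return(NULL)
      data.frame(method = d$method[1], metric = d$metric[1],
                 keypoint = "overall", mean = mean(d$mean))
    }))
    agg <- rbind(agg, ov)
  }
  rownames(agg) <- NULL
  agg
}

#' One-way repeated-measures ANOVA across methods
#'
#' Folds act as subjects and methods as the repeated condition. The sum of
#' squares is decomposed into method, subject (fold) and residual terms;
#' `F = MS_method / MS_residual` with `(m - 1, (m - 1)(n - 1))` degrees of
#' freedom, and the effect size is the classic eta squared
#' `SS_method / SS_total`.
#'
#' @param mat An `n_folds x n_methods` numeric matrix (no missing cells;
#'   column names are the method labels).
#' @return An object of class `vf_rm_anova` with `F`, `df`, `p`,
#'   `eta_sq` and the sum-of-squares decomposition.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); m <- ncol(mat)
  if (n < 2 || m < 2) stop("need at least 2 folds and 2 methods")
  if (anyNA(mat)) stop("missing cells are not allowed (no imputation)")
  g <- mean(mat)
  ss_method <- n * sum((colMeans(mat) - g)^2)
  ss_subject <- m * sum((rowMeans(mat) - g)^2)
  ss_total <- sum((mat - g)^2)
  ss_error <- ss_total - ss_method - ss_subject
  df1 <- m - 1; df2 <- (m - 1) * (n - 1)
  Fv <- (ss_method / df1) / (ss_error / df2)
  structure(list(F = Fv, df = c(df1, df2),
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                 eta_sq = ss_method / ss_total,
                 ss = c(method = ss_method, subject = ss_subject,
                        error = ss_error, total = ss_total),
                 means = colMeans(mat)),
            class = "vf_rm_anova")
}

#' @export
print.vf_rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.2f, p = %.4f, eta^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$eta_sq))
  invisible(x)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down Holm correction with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param raw_p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(raw_p) {
  if (length(raw_p) == 0) stop("no p-values supplied")
  stats::p.adjust(raw_p, method = "holm")
}

#' Hedges' g for paired fold-level samples
#'
#' Standardized mean difference with small-sample bias correction:
#' `g = (mean(a) - mean(b)) / s_pooled * J` with
#' `s_pooled = sqrt((var(a) + var(b)) / 2)` (equal sample sizes) and
#' `J = 1 - 3 / (4 df - 1)`, `df = 2 n - 2`.
#'
#' @param a,b Numeric vectors of equal length (e.g. one value per fold).
#' @return Hedges' g (signed; `a` larger than `b` gives a positive g).
#' @export
hedges_g <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (sp == 0) stop("zero pooled standard deviation")
  n <- length(a)
  J <- 1 - 3 / (4 * (2 * n - 2) - 1)
  (mean(a) - mean(b)) / sp * J
}

#' Pairwise method comparison with Holm correction and effect sizes
#'
#' For each pair of methods, a paired t-test on the fold-level values;
#' p-values are Holm-Bonferroni adjusted across the pairs and Hedges' g is
#' reported for each pair (first method minus second).
#'
#' @param mat An `n_folds x n_methods` matrix with method column names.
#' @return A data frame with columns pair, a, b, p_raw, p_holm, hedges_g.
#' @export
pairwise_comparisons <- function(mat) {
  mat <- as.matrix(mat)
  methods <- colnames(mat) %||% paste0("m", seq_len(ncol(mat)))
  pairs <- utils::combn(ncol(mat), 2)
  res <- data.frame(
    pair = apply(pairs, 2, function(ij)
      paste(methods[ij[1]], "vs", methods[ij[2]])),
    a = methods[pairs[1, ]], b = methods[pairs[2, ]],
    p_raw = apply(pairs, 2, function(ij)
      stats::t.test(mat[, ij[1]], mat[, ij[2]], paired = TRUE)$p.value),
    hedges_g = apply(pairs, 2, function(ij)
      hedges_g(mat[, ij[1]], mat[, ij[2]])))
  res$p_holm <- holm_bonferroni(res$p_raw)
  res[, c("pair", "a", "b", "p_raw", "p_holm", "hedges_g")]
}

#' Full method comparison report
#'
#' Combines the repeated-measures ANOVA with Holm-corrected pairwise
#' paired t-tests and Hedges' g effect sizes.
#'
#' @param mat An `n_folds x n_methods` matrix with method column names.
#' @return An object of class `vf_comparison`: the `vf_rm_anova` plus the
#'   pairwise table.
#' @export
compare_methods <- function(mat) {
  structure(list(anova = rm_anova(mat), pairwise = pairwise_comparisons(mat)),
            class = "vf_comparison")
}

#' @export
print.vf_comparison <- function(x, ...) {
  print(x$anova)
  pw <- x$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %-35s p_holm = %.4f  g = %+.2f\n", pw$pair[i], pw$p_holm[i],
                pw$hedges_g[i]))
  invisible(x)
}

#' Metrics split by a per-frame subgroup flag
#'
#' Computes per-keypoint pixel errors and AGA errors separately for the
#' frames where `flag` is `TRUE` and where it is `FALSE` (e.g. oncologic
#' vs non-oncologic patients). Frames with missing (undecodable)
#' predictions are excluded with a count.
#'
#' @param true_triplets List of ground-truth [vf_triplet()] (already in
#'   the prediction pixel space).
#' @param pred_triplets List of predicted [vf_triplet()] or `NULL`.
#' @param flag Logical vector, one value per frame.
#' @return A data frame with one row per (subgroup, metric, keypoint).
#' @export
subgroup_metrics <- function(true_triplets, pred_triplets, flag) {
  stopifnot(length(true_triplets) == length(pred_triplets),
            length(flag) == length(true_triplets))
  out <- list()
  for (grp in c(TRUE, FALSE)) {
    idx <- which(flag == grp)
    lab <- if (grp) "flagged" else "unflagged"
    if (!length(idx)) {
      out[[lab]] <- data.frame(subgroup = lab, metric = "absent",
                               keypoint = NA, mean = NA, sd = NA, n = 0,
                               n_undecodable = 0)
      next
    }
    ok <- idx[!vapply(pred_triplets[idx], is.null, logical(1))]
    nund <- length(idx) - length(ok)
    if (!length(ok)) {
      out[[lab]] <- data.frame(subgroup = lab, metric = "undecodable",
                               keypoint = NA, mean = NA, sd = NA, n = 0,
                               n_undecodable = nund)
      next
    }
    err <- t(vapply(ok, function(i)
      keypoint_error(pred_triplets[[i]], true_triplets[[i]]), numeric(3)))
    aga <- aga_errors(pred_triplets[ok], true_triplets[ok])
    rows <- rbind(
      data.frame(subgroup = lab, metric = "rmse_px",
                 keypoint = colnames(err), mean = colMeans(err),
                 sd = apply(err, 2, stats::sd), n = length(ok),
                 n_undecodable = nund),
      data.frame(subgroup = lab, metric = c("aga_mae_deg", "aga_rmse_deg"),
                 keypoint = NA, mean = as.numeric(aga), sd = NA,
                 n = length(ok), n_undecodable = nund))
    out[[lab]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
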