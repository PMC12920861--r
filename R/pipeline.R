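default_loss_for <- function(variant) {
  switch(variant, heatmap = "wmse", direct = "coord_mse", segmentation = "dice")
}

# Evaluate one method's predictions on a test split: per-keypoint pixel
# errors, AGA errors, DSC (segmentation), undecodable count.
evaluate_predictions <- function(preds, test_records, S) {
  true_scaled <- lapply(test_records, function(r) {
    d <- dim(r$image)
    transform_triplet(r$triplet, diag(c(S / d[2], S / d[1])))
  })
  ok <- which(!vapply(preds$triplets, is.null, logical(1)))
  nund <- length(preds$triplets) - length(ok)
  if (!length(ok)) stop("no decodable predictions in this fold")
  err <- t(vapply(ok, function(i)
    keypoint_error(preds$triplets[[i]], true_scaled[[i]]), numeric(3)))
  # a predicted triplet can be degenerate (coincident keypoints): its AGA is
  # infeasible and the pair is excluded from the angle metrics with a count
  aga_p <- vapply(preds$triplets[ok], function(tr)
    tryCatch(compute_aga(tr), error = function(e) NA_real_), numeric(1))
  aga_t <- vapply(true_scaled[ok], compute_aga, numeric(1))
  valid <- !is.na(aga_p)
  aga <- if (any(valid)) aga_errors(aga_p[valid], aga_t[valid])
         else c(mae = NA_real_, rmse = NA_real_)
  rows <- rbind(
    data.frame(metric = "rmse_px", keypoint = colnames(err),
               mean = colMeans(err), sd = apply(err, 2, stats::sd)),
    data.frame(metric = c("aga_mae_deg", "aga_rmse_deg"), keypoint = NA,
               mean = as.numeric(aga), sd = NA))
  if (preds$variant == "segmentation") {
    ds <- vapply(seq_along(test_records), function(i) {
      gt <- triangle_mask(true_scaled[[i]], S, S)
      dsc(preds$masks[[i]], gt)
    }, numeric(1))
    rows <- rbind(rows, data.frame(metric = "dsc", keypoint = NA,
                                   mean = mean(ds), sd = stats::sd(ds)))
  }
  rows$n <- length(ok)
  rows$n_undecodable <- nund
  rownames(rows) <- NULL
  rows
}

#' Run the full cross-validated method comparison
#'
#' For each requested method, trains and evaluates the network with
#' patient-grouped k-fold cross-validation (no patient overlap between
#' the train+validation and test sides), collects the per-fold metrics
#' table, cross-fold aggregates, and -- when at least two methods are
#' compared -- the repeated-measures ANOVA with Holm-corrected pairwise
#' comparisons on fold-level values (keypoint-averaged RMSE, AGA MAE and
#' AGA RMSE). Runs are resumable per (method, fold) when `out_dir` is
#' given: completed fold metric files are loaded instead of retrained. A
#' failing fold is recorded and the run continues.
#'
#' @param records List of [vf_frame()] records.
#' @param methods Character subset of heatmap, direct, segmentation.
#' @param k Number of folds.
#' @param config A [model_config()] used as template (its `variant` is
#'   overridden per method).
#' @param control A [train_config()] template (its `loss` is overridden
#'   by each method's default loss unless `keep_loss = TRUE`).
#' @param keep_loss Use `control$loss` for every method (for loss
#'   ablations of the heatmap model).
#' @param seed Seed for fold construction and training.
#' @param out_dir Optional output directory for CSVs and resume files.
#' @param verbose Print progress.
#' @return A list of class `vf_experiment` with `metrics` (per-fold
#'   table), `aggregates`, `comparisons` (per metric), `folds`,
#'   `failures`.
#' @export
run_experiment <- function(records, methods = c("heatmap", "direct",
                                                "segmentation"),
                           k = 5, config = model_config(),
                           control = train_config(), keep_loss = FALSE,
                           seed = 1, out_dir = NULL, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  folds <- make_patient_folds(records, k = k, seed = seed)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  fid <- vapply(records, function(r) r$frame_id, character(1))
  metrics <- list()
  failures <- list()
  for (m in methods) {
    cfg <- config
    cfg$variant <- m
    ctl <- control
    if (!keep_loss) ctl$loss <- default_loss_for(m)
    for (f in folds) {
      tag <- sprintf("fold%d_%s", f$fold_index, m)
      cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv"))
      if (!is.null(cache) && file.exists(cache)) {
        rows <- utils::read.csv(cache, stringsAsFactors = FALSE)
        metrics[[tag]] <- rows
        next
      }
      res <- tryCatch({
        tr <- records[fid %in% f$train_ids]
        va <- records[fid %in% f$val_ids]
        te <- records[fid %in% f$test_ids]
        ctl$seed <- as.integer(seed + 131L * f$fold_index)
        fit <- vf_train(tr, va, cfg, ctl, verbose = FALSE)
        preds <- predict(fit, te)
        rows <- evaluate_predictions(preds, te, cfg$input_size)
        rows <- cbind(fold = f$fold_index, method = m, rows)
        if (!is.null(cache)) utils::write.csv(rows, cache, row.names = FALSE)
        if (verbose) message(tag, " done (best epoch ", fit$best_epoch, ")")
        rows
      }, error = function(e) {
        warning("fold ", f$fold_index, " of method ", m, " failed: ",
                conditionMessage(e))
        failures[[tag]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(res)) metrics[[tag]] <- res
    }
  }
  if (length(metrics) == 0)
    stop("every fold failed; first error: ", failures[[1]])
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  aggregates <- aggregate_folds(metrics)
  comparisons <- NULL
  if (length(methods) >= 2 && length(failures) == 0) {
    comparisons <- list()
    for (metric in intersect(c("rmse_px", "aga_mae_deg", "aga_rmse_deg"),
                             metrics$metric)) {
      d <- metrics[metrics$metric == metric, ]
      mat <- sapply(methods, function(mm)
        vapply(sort(unique(d$fold)), function(ff)
          mean(d$mean[d$fold == ff & d$method == mm]), numeric(1)))
      comparisons[[metric]] <- tryCatch(compare_methods(mat),
                                        error = function(e) {
        warning("comparison on ", metric, " not possible: ",
                conditionMessage(e))
        NULL
      })
    }
  } else if (length(methods) < 2) {
    warning("only one method requested: no ANOVA comparison performed")
  }
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(aggregates, file.path(out_dir, "aggregates.csv"),
                     row.names = FALSE)
    export_folds_csv(folds, records, file.path(out_dir, "folds.csv"))
  }
  structure(list(metrics = metrics, aggregates = aggregates,
                 comparisons = comparisons, folds = folds,
                 failures = failures),
            class = "vf_experiment")
}

#' @export
print.vf_experiment <- function(x, ...) {
  cat("Cross-validated vocal-fold pose experiment\n")
  agg <- x$aggregates
  for (m in unique(agg$method)) {
    d <- agg[agg$method == m, ]
    cat(sprintf("  %-13s", m))
    cat(paste(sprintf("%s %s=%.2f",
                      ifelse(is.na(d$keypoint) | d$keypoint == "", d$metric,
                             paste0(d$metric, "[", d$keypoint, "]")),
                      "", d$mean), collapse = "  "), "\n")
  }
  if (!is.null(x$comparisons))
    for (nm in names(x$comparisons)) {
      cat(nm, ": ")
      print(x$comparisons[[nm]]$anova)
    }
  if (length(x$failures))
    cat("FAILED folds:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
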