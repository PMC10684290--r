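#' Object count of a density map
#'
#' The count is the sum over all pixels; because [downsample_sum()] is
#' sum-preserving, the count is independent of the map's resolution.
#'
#' @param d a [density_map()].
#' @return Numeric (possibly fractional) count.
#' @export
count_from_density <- function(d) {
  stopifnot(inherits(d, "density_map"))
  sum(d$values)
}

#' Counting metrics: MAE, RMSE and R-squared
#'
#' For per-image true counts C and predictions C':
#' `MAE = mean(|C - C'|)`, `RMSE = sqrt(mean((C - C')^2))`, and
#' `R2 = 1 - sum((C - C')^2) / sum((C - mean(C))^2)`. R-squared is undefined
#' (reported `NA`) when the true counts are all identical.
#'
#' @param truths,predictions numeric vectors of equal positive length.
#' @return List of class `eval_metrics` with `mae`, `rmse`, `r2`,
#'   `n_images`.
#' @export
compute_metrics <- function(truths, predictions) {
  n <- length(truths)
  if (n == 0 || length(predictions) != n) {
    stop("truths and predictions must have equal nonzero length")
  }
  err <- truths - predictions
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  ss_tot <- sum((truths - mean(truths))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot
  structure(list(mae = mae, rmse = rmse, r2 = r2, n_images = n),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n = %d  MAE %.4f  RMSE %.4f  R2 %s\n",
              x$n_images, x$mae, x$rmse,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2))))
  invisible(x)
}

#' Evaluate a network on annotated records
#'
#' @param net a trained [build_network()] handle.
#' @param records list of `list(id, image, points)` records.
#' @param clip_negative passed to [predict_count()].
#' @return An `eval_metrics` object.
#' @export
evaluate_records <- function(net, records, clip_negative = FALSE) {
  truths <- vapply(records, function(r) as.numeric(n_points(r$points)), 0)
  preds <- vapply(records, function(r) {
    predict_count(net, r$image, clip_negative)$count
  }, 0)
  compute_metrics(truths, preds)
}

#' Relative improvement over the best competitor
#'
#' Benchmark-table arithmetic: for each metric independently, the baseline
#' is the best competitor (minimum MAE, minimum RMSE, maximum R-squared;
#' rows with missing metrics are skipped per metric), and the improvement is
#' `100 * (best_mae - our_mae) / best_mae` for MAE (RMSE analogous) and
#' `100 * (our_r2 - best_r2) / best_r2` for R-squared. Choosing the best
#' competitor per metric makes these the conservative "at least" bounds.
#'
#' @param ours one-row data frame (or list) with `mae`, `rmse`, `r2`.
#' @param competitors data frame with columns `mae`, `rmse`, `r2` (NA =
#'   missing).
#' @return Named list `r2_gain_pct`, `mae_reduction_pct`,
#'   `rmse_reduction_pct`.
#' @export
relative_improvement <- function(ours, competitors) {
  competitors <- as.data.frame(competitors)
  if (nrow(competitors) == 0 ||
      all(is.na(competitors$mae) & is.na(competitors$rmse) &
            is.na(competitors$r2))) {
    stop("no competitor with non-missing metrics")
  }
  best_mae <- min(competitors$mae, na.rm = TRUE)
  best_rmse <- min(competitors$rmse, na.rm = TRUE)
  best_r2 <- max(competitors$r2, na.rm = TRUE)
  list(r2_gain_pct = 100 * (ours$r2 - best_r2) / best_r2,
       mae_reduction_pct = 100 * (best_mae - ours$mae) / best_mae,
       rmse_reduction_pct = 100 * (best_rmse - ours$rmse) / best_rmse)
}

#' Published field-benchmark comparison table
#'
#' The comparison table of counting methods on the 300-image field grape
#' berry benchmark (columns `type`, `ratio`, `method`, `mae`, `rmse`, `r2`;
#' missing entries are `NA`), shipped with the package for the
#' relative-improvement arithmetic. `ratio` is the labeled fraction of the
#' training set for semi-supervised rows.
#'
#' @param file optional path to an alternative CSV in the same layout.
#' @return A data frame.
#' @export
field_benchmark <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "field_benchmark.csv", package = "berrycount")
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("type", "ratio", "method", "mae", "rmse", "r2")
  if (!all(needed %in% names(df))) {
    stop("benchmark table must have columns: ", paste(needed, collapse = ", "))
  }
  df
}
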