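#' Per-image counting-error record
#'
#' Relative error is defined against the true (expert) count:
#' `100 * |predicted - true| / true`.
#'
#' @param predicted Predicted (real-valued) cell count.
#' @param true_count True cell count; must be positive.
#' @param id Image label.
#' @return One-row data.frame with columns `image_id`, `predicted`,
#'   `true_count`, `absolute_error`, `relative_error_pct`.
#' @export
evaluate_image <- function(predicted, true_count, id = NA_character_) {
  if (!is.finite(true_count) || true_count <= 0)
    stop("true_count must be positive, got ", true_count)
  abs_err <- abs(predicted - true_count)
  data.frame(image_id = as.character(id), predicted = predicted,
             true_count = as.integer(true_count),
             absolute_error = abs_err,
             relative_error_pct = 100 * abs_err / true_count,
             stringsAsFactors = FALSE)
}

#' Evaluate a set of (predicted, true) count pairs
#'
#' @param predicted,true_counts Equal-length numeric vectors.
#' @param ids Optional image labels.
#' @return Data.frame of per-image records, one row per image.
#' @export
evaluate_counts <- function(predicted, true_counts, ids = NULL) {
  stopifnot(length(predicted) == length(true_counts))
  if (is.null(ids)) ids <- as.character(seq_along(predicted))
  do.call(rbind, Map(evaluate_image, predicted, true_counts, ids))
}

#' Aggregate counting-error metrics
#'
#' Summarises per-image records into the standard aggregate metrics: the
#' mean of per-image relative errors, total predicted and true counts, the
#' overall difference `100 * |total_true - total_predicted| / total_true`
#' (which benefits from per-image errors cancelling in the sum), the
#' maximum per-image relative error, and the fraction of images whose
#' relative error is strictly below `threshold_pct`.
#'
#' @param records Data.frame from [evaluate_counts()] (nonempty).
#' @param threshold_pct Threshold for `fraction_below`; default 5.
#' @return List with `n_images`, `mean_relative_error_pct`,
#'   `max_relative_error_pct`, `total_predicted`, `total_true`,
#'   `overall_difference_pct`, `fraction_below`.
#' @export
summarize_counts <- function(records, threshold_pct = 5) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no evaluation records to summarise")
  total_pred <- sum(records$predicted)
  total_true <- sum(records$true_count)
  list(n_images = nrow(records),
       mean_relative_error_pct = mean(records$relative_error_pct),
       max_relative_error_pct = max(records$relative_error_pct),
       total_predicted = total_pred,
       total_true = total_true,
       overall_difference_pct = 100 * abs(total_true - total_pred) / total_true,
       fraction_below = mean(records$relative_error_pct < threshold_pct))
}

#' Reference benchmark counts
#'
#' The 26 (predicted, true) count pairs of a published evaluation of the
#' redundant-count-map method on HEK 293A phase-contrast test images,
#' shipped with the package so the aggregate error statistics can be
#' recomputed exactly.
#'
#' @return Data.frame with columns `image`, `predicted`, `true_count`.
#' @export
benchmark_counts <- function() {
  path <- system.file("extdata", "benchmark_counts.csv",
                      package = "cellcountr", mustWork = TRUE)
  utils::read.csv(path)
}
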