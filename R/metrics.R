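# Scoring-power and ranking-power evaluation metrics.

#' Regression metrics for predicted affinities
#'
#' Computes RMSE (`sqrt(mean((pred - obs)^2))`), the Pearson correlation
#' between predictions and observations, MAE (`mean(|pred - obs|)`) and SD,
#' the standard deviation of the residuals about the least-squares regression
#' line of predictions on observations (the CASF scoring-power dispersion
#' statistic, denominator `n - 1`).
#'
#' @param pred Predicted pKa values.
#' @param obs Experimental pKa values (same length, `n >= 2`).
#' @return List of class `eval_report` with `rmse`, `pearson_r`, `mae`, `sd`,
#'   `n`.
#' @export
evaluate_predictions <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("pred and obs lengths differ")
  n <- length(pred)
  if (n < 2L) stopf("need at least 2 samples")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stopf("zero variance in predictions or observations; Pearson R undefined")
  fit <- stats::lm(pred ~ obs)
  structure(list(rmse = sqrt(mean((pred - obs)^2)),
                 pearson_r = stats::cor(pred, obs),
                 mae = mean(abs(pred - obs)),
                 sd = sqrt(sum(stats::residuals(fit)^2) / (n - 1L)),
                 n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n = %d complexes\n  RMSE      %.4f\n  Pearson R %.4f\n  MAE       %.4f\n  SD        %.4f\n",
              x$n, x$rmse, x$pearson_r, x$mae, x$sd))
  invisible(x)
}

#' Ranking power over three-complex clusters
#'
#' Each cluster holds three complexes of the same target with distinct true
#' affinities. A cluster is a high-level success when the predicted order of
#' all three matches the true order, and a low-level success when the
#' complex with the highest true affinity gets the highest prediction,
#' regardless of how the other two are ordered. Ties in the predictions
#' count as failures. Rates are percentages over clusters.
#'
#' @param clusters A data.frame with columns `cluster`, `y_true`, `y_pred`
#'   (three rows per cluster), or a list of such three-row data.frames.
#' @return List of class `ranking_report` with `high_level_rate`,
#'   `low_level_rate` (percent) and `n_clusters`.
#' @export
ranking_power <- function(clusters) {
  if (is.data.frame(clusters)) {
    clusters <- split(clusters, clusters$cluster)
  }
  n <- length(clusters)
  if (n == 0L) stopf("no clusters supplied")
  high <- 0L; low <- 0L
  for (cl in clusters) {
    yt <- cl$y_true; yp <- cl$y_pred
    if (length(yt) != 3L) stopf("every cluster must have exactly 3 complexes")
    if (anyDuplicated(yt)) stopf("true affinities within a cluster must be distinct")
    ot <- order(yt, decreasing = TRUE)
    if (yp[ot[1]] > yp[ot[2]] && yp[ot[2]] > yp[ot[3]]) high <- high + 1L
    if (yp[ot[1]] > max(yp[ot[2]], yp[ot[3]])) low <- low + 1L
  }
  structure(list(high_level_rate = 100 * high / n,
                 low_level_rate = 100 * low / n, n_clusters = n),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("%d clusters\n  high-level success %.2f%%\n  low-level success  %.2f%%\n",
              x$n_clusters, x$high_level_rate, x$low_level_rate))
  invisible(x)
}
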