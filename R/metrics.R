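# Accuracy metrics and the model-selection rule.
#
# MSE, RMSE and MAE are the usual mean squared / root mean squared /
# mean absolute error. Two R-squared conventions are reported:
#   * r2       -- the ratio sum(yhat - ybar)^2 / sum(y - ybar)^2 of
#                 regression sum of squares to total sum of squares, with
#                 ybar the mean of the observed targets in the evaluated
#                 partition. This is the convention the hypericin study
#                 selects models by; unlike the conventional form it is
#                 nonnegative but can exceed 1 for biased predictors.
#   * r2_conv  -- the conventional 1 - SSE/SST.
# All metrics are computed on the original mg/g scale.

#' Regression accuracy metrics
#'
#' @param y Observed targets (mg/g).
#' @param yhat Predictions (mg/g), same length.
#' @return A one-row data.frame with `n`, `mse`, `rmse`, `mae`, `r2`
#'   (regression-SS over total-SS) and `r2_conv` (1 - SSE/SST).
#' @export
compute_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    stop("target variance is zero; R-squared is undefined", call. = FALSE)
  }
  mse <- mean((y - yhat)^2)
  data.frame(
    n = length(y),
    mse = mse,
    rmse = sqrt(mse),
    mae = mean(abs(y - yhat)),
    r2 = sum((yhat - mean(y))^2) / sst,
    r2_conv = 1 - sum((y - yhat)^2) / sst
  )
}

#' Evaluate a trained model on all three partitions
#'
#' Applies [compute_metrics()] to the train, validation and test rows of
#' the table. The test partition plays no role in fitting or selection
#' before this point.
#'
#' @param model A trained `hyp_model`.
#' @param table The full `sample_table` (with target).
#' @param split The `hyp_split` used for training.
#' @return A `metrics_report` data.frame: one row per partition with the
#'   model id.
#' @export
evaluate_model <- function(model, table, split) {
  enc <- encode_features(table)
  if (is.null(enc$y)) stop("table has no hypericin target", call. = FALSE)
  parts <- list(train = split$train, val = split$val, test = split$test)
  if (any(lengths(parts) == 0L)) stop("empty partition", call. = FALSE)
  pred <- stats::predict(model, enc$x)
  out <- do.call(rbind, lapply(names(parts), function(p) {
    idx <- parts[[p]]
    cbind(model = model$model_id, partition = p,
          compute_metrics(enc$y[idx], pred[idx]))
  }))
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Select the best model by test R-squared
#'
#' Ranks models by their test-partition `r2` (the regression-SS
#' convention, the study's selection rule); ties break by lower test RMSE,
#' then lexicographic model id.
#'
#' @param reports One or more `metrics_report` data.frames (or a list of
#'   them).
#' @return A list with `best` (model id) and `table` (the per-model test
#'   comparison, ranked).
#' @export
select_best <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  all_rows <- do.call(rbind, lapply(reports, as.data.frame))
  test <- all_rows[all_rows$partition == "test", , drop = FALSE]
  ord <- order(-test$r2, test$rmse, test$model)
  test <- test[ord, , drop = FALSE]
  test$rank <- seq_len(nrow(test))
  rownames(test) <- NULL
  list(best = test$model[1L], table = test)
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df)
  invisible(x)
}
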