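# One-at-a-time (OAT) sensitivity analysis.
#
# For each of the 13 predictors a synthetic evaluation set is built in
# which that variable sweeps the range mean +/- 1 SD (clipped to the
# observed bounds; ordinals sweep all their codes) while every other
# variable is fixed at its training mean (continuous) or rounded mean
# code (ordinal). The model's sensitivity to a variable is the population
# standard deviation of its predictions over that sweep; scores are
# normalised to [0, 1] by dividing by the largest raw SD.

#' Per-variable statistics of a training table
#'
#' Means, SDs and observed ranges used to anchor the perturbation grids.
#'
#' @param table A `sample_table` (typically the training rows).
#' @return An object of class `sample_stats`: a data.frame with `name`,
#'   `kind`, `mean`, `sd`, `min`, `max` for the 13 predictors.
#' @export
sample_stats <- function(table) {
  df <- as.data.frame(table)
  sc <- hypericum_schema()
  out <- do.call(rbind, lapply(predictor_names(), function(nm) {
    v <- df[[nm]]
    data.frame(name = nm, kind = sc$kind[match(nm, sc$name)],
               mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  structure(out, n_source = nrow(df),
            class = c("sample_stats", "data.frame"))
}

#' Build the one-at-a-time perturbation grid for one variable
#'
#' @param variable Name of the swept predictor.
#' @param stats A [sample_stats()] table.
#' @param k Grid size for continuous variables (>= 3; ordinals always use
#'   all their codes).
#' @param width SD multiplier of the sweep half-range (default 1).
#' @return A `sample_table` (no target) whose rows differ only in
#'   `variable`.
#' @export
build_perturbation_grid <- function(variable, stats, k = 21L, width = 1) {
  stopifnot(inherits(stats, "sample_stats"), k >= 3L)
  if (!variable %in% stats$name) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  i <- match(variable, stats$name)
  if (stats$kind[i] == "ordinal") {
    values <- seq(stats$min[i], stats$max[i])
  } else {
    lo <- max(stats$mean[i] - width * stats$sd[i], stats$min[i])
    hi <- min(stats$mean[i] + width * stats$sd[i], stats$max[i])
    values <- seq(lo, hi, length.out = k)
  }
  base <- ifelse(stats$kind == "ordinal", round(stats$mean), stats$mean)
  grid <- as.data.frame(matrix(rep(base, each = length(values)),
                               nrow = length(values)))
  names(grid) <- stats$name
  grid[[variable]] <- values
  as_sample_table(grid)
}

#' One-at-a-time sensitivity scores of a trained model
#'
#' @param model A trained `hyp_model`.
#' @param stats A [sample_stats()] table (training partition).
#' @param k Grid size for continuous sweeps.
#' @param width SD multiplier of the sweep range.
#' @return A `sensitivity_report` data.frame with per-variable `raw_sd`
#'   (mg/g, population SD of predictions over the sweep), `score`
#'   (raw_sd / max raw_sd, in [0, 1]) and `rank`.
#' @export
sensitivity_scores <- function(model, stats, k = 21L, width = 1) {
  raw <- vapply(stats$name, function(nm) {
    grid <- build_perturbation_grid(nm, stats, k = k, width = width)
    p <- stats::predict(model, grid)
    sqrt(mean((p - mean(p))^2))  # population SD
  }, numeric(1))
  if (max(raw) > 0) {
    score <- raw / max(raw)
  } else {
    warning("model output is constant on every grid; all scores set to 0",
            call. = FALSE)
    score <- raw
  }
  out <- data.frame(variable = stats$name, raw_sd = unname(raw),
                    score = unname(score), stringsAsFactors = FALSE)
  out <- out[order(-out$raw_sd, out$variable), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, model = model$model_id, k = as.integer(k), width = width,
            class = c("sensitivity_report", "data.frame"))
}

#' Response curve of a model along one variable
#'
#' The one-at-a-time sweep and the model's predictions along it, with a
#' simple monotonicity summary ("increasing", "decreasing", "flat" or
#' "mixed").
#'
#' @inheritParams sensitivity_scores
#' @param variable The swept predictor.
#' @return A data.frame with `value` and `prediction`, plus attributes
#'   `variable` and `trend`.
#' @export
response_curve <- function(model, variable, stats, k = 21L, width = 1) {
  grid <- build_perturbation_grid(variable, stats, k = k, width = width)
  p <- stats::predict(model, grid)
  d <- diff(p)
  eps <- 1e-10 * max(1, max(abs(p)))
  trend <- if (all(abs(d) <= eps)) "flat"
  else if (all(d >= -eps)) "increasing"
  else if (all(d <= eps)) "decreasing"
  else "mixed"
  structure(data.frame(value = grid[[variable]], prediction = p),
            variable = variable, trend = trend)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> model %s (k = %d, width = %g SD)\n",
              attr(x, "model"), attr(x, "k"), attr(x, "width")))
  df <- as.data.frame(x)
  df$raw_sd <- signif(df$raw_sd, 4)
  df$score <- signif(df$score, 4)
  print(df)
  invisible(x)
}
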