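#' Min-max feature scaler
#'
#' Fits per-column (lo, hi) ranges on the training design matrix and maps
#' each feature linearly onto [-1, 1]; the target is scaled the same way.
#' The [-1, 1] range suits the logistic-sigmoid hidden layer of the
#' perceptron and keeps all three models on a common footing. Constant
#' columns map to 0. Predictions are always inverse-scaled before any
#' metric is computed, so reported errors are on the original mg/g scale.
#'
#' @param x Numeric training matrix (n x p).
#' @param y Optional numeric training target.
#' @return An object of class `hyp_scaler`.
#' @export
fit_scaler <- function(x, y = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  tgt <- if (!is.null(y)) c(lo = min(y), hi = max(y)) else NULL
  structure(list(lo = lo, hi = hi, target = tgt, p = ncol(x),
                 names = colnames(x)),
            class = "hyp_scaler")
}

scale_column <- function(v, lo, hi) {
  if (hi > lo) (v - lo) / (hi - lo) * 2 - 1 else rep(0, length(v))
}

unscale_column <- function(v, lo, hi) {
  if (hi > lo) (v + 1) / 2 * (hi - lo) + lo else rep(lo, length(v))
}

#' Apply a fitted scaler to a feature matrix
#' @param scaler A `hyp_scaler` from [fit_scaler()].
#' @param x Numeric matrix with the same column count as the fit.
#' @return Scaled matrix (training columns land in [-1, 1]).
#' @export
apply_scaler <- function(scaler, x) {
  check_scaler(scaler)
  stopifnot(is.matrix(x))
  if (ncol(x) != scaler$p) {
    stop(sprintf("scaler was fitted on %d columns, got %d", scaler$p, ncol(x)),
         call. = FALSE)
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- scale_column(x[, j], scaler$lo[j], scaler$hi[j])
  }
  out
}

#' Invert a fitted scaler on a feature matrix
#' @inheritParams apply_scaler
#' @return Matrix on the original scale.
#' @export
invert_scaler <- function(scaler, x) {
  check_scaler(scaler)
  stopifnot(is.matrix(x), ncol(x) == scaler$p)
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- unscale_column(x[, j], scaler$lo[j], scaler$hi[j])
  }
  out
}

#' Scale / unscale the target variable
#' @param scaler A `hyp_scaler` fitted with a target.
#' @param y Numeric vector.
#' @return Numeric vector.
#' @export
scale_target <- function(scaler, y) {
  check_scaler(scaler)
  if (is.null(scaler$target)) stop("scaler has no fitted target range", call. = FALSE)
  scale_column(y, scaler$target[["lo"]], scaler$target[["hi"]])
}

#' @rdname scale_target
#' @export
unscale_target <- function(scaler, y) {
  check_scaler(scaler)
  if (is.null(scaler$target)) stop("scaler has no fitted target range", call. = FALSE)
  unscale_column(y, scaler$target[["lo"]], scaler$target[["hi"]])
}

check_scaler <- function(scaler) {
  if (!inherits(scaler, "hyp_scaler")) {
    stop("scaler has not been fitted (expected a 'hyp_scaler' object)",
         call. = FALSE)
  }
  invisible(scaler)
}

#' Partition sample indices into train / validation / test sets
#'
#' Uses the study's 60/20/20 convention by default: partition sizes are
#' the floor of `n * fraction` with the remainder assigned one-by-one in
#' the order train, validation, test (so n = 100 gives exactly 60/20/20).
#' Assignment is a seeded uniform permutation and is reproducible for
#' equal seeds.
#'
#' @param n Number of samples (>= 3).
#' @param fractions Numeric length-3 vector (train, validation, test);
#'   positive, summing to 1.
#' @param seed Integer RNG seed, recorded in the result.
#' @return An object of class `hyp_split` with integer index vectors
#'   `train`, `val`, `test` and the `seed`.
#' @export
split_dataset <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 samples to populate all partitions", call. = FALSE)
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    for (k in seq_len(rem)) sizes[k] <- sizes[k] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  structure(list(
    train = sort(perm[seq_len(sizes[1L])]),
    val   = sort(perm[sizes[1L] + seq_len(sizes[2L])]),
    test  = sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]),
    seed  = as.integer(seed)
  ), class = "hyp_split")
}

#' @export
print.hyp_split <- function(x, ...) {
  cat(sprintf("<hyp_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
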