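# Gaussian radial-basis-function network regressor.
#
# Hidden layer of m Gaussian units R_j(x) = exp(-||x - a_j||^2 / (2 s^2))
# with a single shared spread s, linear output y = sum_j w_j R_j(x) + b.
# Centers are chosen by greedy forward selection from the training points:
# at each step the candidate whose inclusion most reduces the training SSE
# (with output weights refit by ordinary least squares) is added, until
# `max_neurons` is reached or the validation MSE stops improving. The
# preset used for hypericin is 48 neurons with spread 50.

#' Gaussian radial-basis activation
#'
#' exp(-||x - center||^2 / (2 sigma^2)), the standard negative-exponent
#' Gaussian with Euclidean distance; equals 1 exactly at the center.
#'
#' @param x Numeric vector, or matrix of row vectors.
#' @param center Numeric vector.
#' @param sigma Positive spread.
#' @return Activation(s) in (0, 1].
#' @export
rbf_activation <- function(x, center, sigma) {
  if (sigma <= 0) stop("spread sigma must be positive", call. = FALSE)
  if (is.matrix(x)) {
    d2 <- rowSums((x - matrix(center, nrow(x), length(center), byrow = TRUE))^2)
  } else {
    d2 <- sum((x - center)^2)
  }
  exp(-d2 / (2 * sigma^2))
}

# n x m design of Gaussian activations for rows of x against centers.
rbf_design <- function(x, centers, sigma) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# OLS with ridge fallback for (near-)rank-deficient activation designs.
ls_weights <- function(phi, y) {
  a <- cbind(phi, 1)
  fit <- tryCatch(qr.coef(qr(a), y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) {
    warning("rank-deficient RBF design; using ridge-stabilised solve",
            call. = FALSE)
    ridge <- diag(1e-8, ncol(a))
    fit <- solve(crossprod(a) + ridge, crossprod(a, y))
  }
  drop(fit)
}

#' Fit a Gaussian RBF network by greedy center selection
#'
#' @param x,y Scaled training design matrix and target.
#' @param x_val,y_val Optional validation partition; when supplied, the
#'   returned network is the neuron count with the best validation MSE,
#'   and selection stops early after `patience` additions without
#'   improvement.
#' @param max_neurons Maximum number of hidden units (<= n_train).
#' @param sigma Shared Gaussian spread (on the scaled feature space).
#' @param centers `"greedy"` (default; forward selection of training
#'   points by SSE reduction) or `"kmeans"` (k-means centroids, all
#'   `max_neurons` at once).
#' @param patience Validation patience for greedy selection.
#' @param seed Seed for the k-means strategy.
#' @return A list of class `rbf_params`: `centers` (m x d), `sigma`,
#'   `w` (m), `b`, `m`, and the per-size SSE trace.
#' @export
fit_rbf_network <- function(x, y, x_val = NULL, y_val = NULL,
                            max_neurons = 48L, sigma = 50,
                            centers = c("greedy", "kmeans"),
                            patience = 8L, seed = 1L) {
  centers <- match.arg(centers)
  stopifnot(is.matrix(x), nrow(x) >= 1L, length(y) == nrow(x))
  if (sigma <= 0) stop("spread sigma must be positive", call. = FALSE)
  max_neurons <- min(as.integer(max_neurons), nrow(x))

  if (centers == "kmeans") {
    km <- with_seed(seed, stats::kmeans(x, centers = max_neurons,
                                        nstart = 5L, iter.max = 50L))
    ctr <- km$centers
    phi <- rbf_design(x, ctr, sigma)
    wb <- ls_weights(phi, y)
    m <- max_neurons
    sel <- seq_len(m)
    trace <- data.frame(m = m, train_sse = sum((phi %*% wb[sel] + wb[m + 1] - y)^2))
    return(structure(list(centers = ctr, sigma = sigma, w = wb[sel],
                          b = wb[m + 1], m = m, trace = trace,
                          strategy = "kmeans"),
                     class = "rbf_params"))
  }

  phi_all <- rbf_design(x, x, sigma)   # candidate activations, col j = point j
  selected <- integer(0)
  best <- NULL
  best_val <- Inf
  since <- 0L
  trace <- vector("list", max_neurons)
  for (m in seq_len(max_neurons)) {
    remaining <- setdiff(seq_len(nrow(x)), selected)
    sse_cand <- vapply(remaining, function(j) {
      wb <- ls_weights(phi_all[, c(selected, j), drop = FALSE], y)
      sum((cbind(phi_all[, c(selected, j), drop = FALSE], 1) %*% wb - y)^2)
    }, numeric(1))
    pick <- remaining[which.min(sse_cand)]
    selected <- c(selected, pick)
    wb <- ls_weights(phi_all[, selected, drop = FALSE], y)
    net <- list(centers = x[selected, , drop = FALSE], sigma = sigma,
                w = wb[seq_len(m)], b = wb[m + 1], m = m)
    trace[[m]] <- data.frame(m = m, train_sse = min(sse_cand))
    if (!is.null(x_val)) {
      pv <- rbf_design(x_val, net$centers, sigma) %*% net$w + net$b
      vm <- mean((pv - y_val)^2)
      if (vm < best_val) { best_val <- vm; best <- net; since <- 0L }
      else since <- since + 1L
      if (since >= patience) break
    } else best <- net
  }
  out <- best
  out$trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  out$strategy <- "greedy"
  structure(out, class = "rbf_params")
}

#' Fit the hypericin RBF network on a sample table
#'
#' Scaling and partition handling as in [fit_mlp()]; the network itself is
#' fit with [fit_rbf_network()]. Defaults follow the hypericin preset:
#' up to 48 neurons, spread 50.
#'
#' @inheritParams fit_mlp
#' @param max_neurons Maximum hidden units.
#' @param sigma Shared Gaussian spread.
#' @param centers Center-selection strategy, see [fit_rbf_network()].
#' @return An object of class `hyp_rbf`.
#' @export
fit_rbf <- function(table, split, max_neurons = 48L, sigma = 50,
                    centers = "greedy", seed = 1L) {
  enc <- encode_features(table)
  if (is.null(enc$y)) stop("training table has no hypericin target", call. = FALSE)
  scaler <- fit_scaler(enc$x[split$train, , drop = FALSE], enc$y[split$train])
  xs <- apply_scaler(scaler, enc$x)
  ys <- scale_target(scaler, enc$y)
  net <- fit_rbf_network(xs[split$train, , drop = FALSE], ys[split$train],
                         xs[split$val, , drop = FALSE], ys[split$val],
                         max_neurons = max_neurons, sigma = sigma,
                         centers = centers, seed = seed)
  structure(list(params = net, scaler = scaler, seed = as.integer(seed),
                 model_id = "RBF"),
            class = c("hyp_rbf", "hyp_model"))
}

#' Evaluate an RBF network on scaled inputs
#' @param params An `rbf_params` network.
#' @param x Scaled feature matrix.
#' @return Numeric vector of scaled outputs.
#' @export
rbf_forward <- function(params, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  drop(rbf_design(x, params$centers, params$sigma) %*% params$w) + params$b
}

#' @rdname predict.hyp_mlp
#' @export
predict.hyp_rbf <- function(object, newdata, ...) {
  xs <- prepare_features(object, newdata)
  unname(unscale_target(object$scaler, rbf_forward(object$params, xs)))
}

#' @export
print.hyp_rbf <- function(x, ...) {
  cat(sprintf("<hyp_rbf> %d Gaussian neurons, spread %.3g (%s centers)\n",
              x$params$m, x$params$sigma, x$params$strategy))
  invisible(x)
}
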