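# One-hidden-layer perceptron regressor, written from scratch.
#
# Architecture: 13 inputs -> H logistic-sigmoid ("logsig") hidden units ->
# 1 linear ("purelin") output, the 13-26-1 structure used for hypericin
# prediction. Training minimises the sum of squared errors E on the scaled
# target, either by Levenberg-Marquardt on the residual Jacobian (default)
# or by full-batch gradient descent (w <- w - gamma * dE/dw). The 20-sample
# validation partition drives early stopping: the returned weights are the
# ones with the best validation MSE seen during training.

logsig <- function(z) 1 / (1 + exp(-z))

#' Control parameters for MLP training
#'
#' @param learning_rate Step size gamma of the gradient-descent trainer.
#' @param max_epochs Maximum number of epochs (accepted steps for LM).
#' @param patience Early-stopping patience, in epochs without a new best
#'   validation MSE. Ignored when no validation set is supplied.
#' @param lambda0 Initial Levenberg-Marquardt damping.
#' @param lambda_inc,lambda_dec Damping multipliers on rejected / accepted
#'   LM steps.
#' @param lambda_max Damping ceiling; training stops when lambda exceeds it.
#' @param tol Stop when the training SSE improvement falls below `tol`.
#' @return A list of class `mlp_control`.
#' @export
mlp_control <- function(learning_rate = 0.05, max_epochs = 200L,
                        patience = 25L, lambda0 = 1e-2, lambda_inc = 10,
                        lambda_dec = 0.1, lambda_max = 1e10, tol = 1e-12) {
  stopifnot(learning_rate > 0, lambda0 > 0, patience >= 1, max_epochs >= 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lambda0 = lambda0,
                 lambda_inc = lambda_inc, lambda_dec = lambda_dec,
                 lambda_max = lambda_max, tol = tol),
            class = "mlp_control")
}

#' Initialise MLP weights
#'
#' Weights and biases are drawn i.i.d. uniform on [-0.5, 0.5] under the
#' given seed, so initialisation is deterministic per seed.
#'
#' @param hidden_size Number of hidden neurons (>= 1).
#' @param seed Integer RNG seed.
#' @param n_inputs Number of input features (13 for the habitat schema).
#' @param activation Hidden activation: `"logsig"` (default) or
#'   `"identity"` (a linear network, used for algebraic checks).
#' @return A list of class `mlp_params` with `W1` (hidden x inputs), `b1`,
#'   `w2` (hidden), `b2`, and tags.
#' @export
init_mlp <- function(hidden_size, seed = 1L, n_inputs = 13L,
                     activation = c("logsig", "identity")) {
  if (hidden_size < 1L) stop("hidden_size must be >= 1", call. = FALSE)
  activation <- match.arg(activation)
  n_par <- hidden_size * n_inputs + hidden_size + hidden_size + 1L
  w <- with_seed(seed, stats::runif(n_par, -0.5, 0.5))
  unpack_mlp(w, hidden_size, n_inputs, activation)
}

pack_mlp <- function(p) c(as.vector(p$W1), p$b1, p$w2, p$b2)

unpack_mlp <- function(w, H, d, activation = "logsig") {
  structure(list(
    W1 = matrix(w[seq_len(H * d)], H, d),
    b1 = w[H * d + seq_len(H)],
    w2 = w[H * d + H + seq_len(H)],
    b2 = w[H * d + 2L * H + 1L],
    hidden_size = H, n_inputs = d, activation = activation
  ), class = "mlp_params")
}

#' Forward pass of the MLP
#'
#' Hidden pre-activations net_j = sum_i w_ji x_i + b_j; hidden outputs
#' logsig(net_j) = 1 / (1 + exp(-net_j)); output = linear combination
#' plus bias.
#'
#' @param params An `mlp_params` object.
#' @param x A numeric matrix (n x inputs) or a single input vector,
#'   already on the scale the network was trained on.
#' @param hidden Also return the hidden activations.
#' @return Numeric vector of n outputs (or a list when `hidden = TRUE`).
#' @export
mlp_forward <- function(params, x, hidden = FALSE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$n_inputs) {
    stop(sprintf("expected %d input columns, got %d",
                 params$n_inputs, ncol(x)), call. = FALSE)
  }
  net <- x %*% t(params$W1) + matrix(params$b1, nrow(x), params$hidden_size,
                                     byrow = TRUE)
  z <- if (params$activation == "logsig") logsig(net) else net
  yhat <- drop(z %*% params$w2) + params$b2
  if (hidden) list(yhat = yhat, z = z) else yhat
}

# Residuals r = yhat - y and the n x p Jacobian dr/dw, with parameters
# packed as (W1 column-major, b1, w2, b2). Shared by both trainers.
mlp_jacobian <- function(params, x, y) {
  H <- params$hidden_size; d <- params$n_inputs
  fw <- mlp_forward(params, x, hidden = TRUE)
  z <- fw$z
  r <- fw$yhat - y
  dz <- if (params$activation == "logsig") z * (1 - z) else matrix(1, nrow(x), H)
  s <- dz * matrix(params$w2, nrow(x), H, byrow = TRUE)  # d yhat / d net_j
  jw1 <- s[, rep(seq_len(H), times = d), drop = FALSE] *
    x[, rep(seq_len(d), each = H), drop = FALSE]
  list(r = r, J = cbind(jw1, s, z, 1))
}

#' Gradient of the sum-of-squared-errors loss
#'
#' Analytic dE/dw for E = sum (yhat_i - y_i)^2, packed like the
#' parameter vector. Verified in the test suite against central finite
#' differences.
#'
#' @inheritParams mlp_forward
#' @param y Numeric target vector.
#' @return Numeric gradient vector.
#' @export
mlp_gradient <- function(params, x, y) {
  jj <- mlp_jacobian(params, x, y)
  drop(2 * crossprod(jj$J, jj$r))
}

mlp_sse <- function(params, x, y) sum((mlp_forward(params, x) - y)^2)

# Track the best-validation-MSE parameter vector across epochs.
new_tracker <- function(params, x_val, y_val) {
  env <- new.env(parent = emptyenv())
  env$best <- params
  env$best_val <- if (is.null(x_val)) Inf else
    mean((mlp_forward(params, x_val) - y_val)^2)
  env$since <- 0L
  env
}

track <- function(env, params, x_val, y_val) {
  if (is.null(x_val)) { env$best <- params; return(FALSE) }
  v <- mean((mlp_forward(params, x_val) - y_val)^2)
  if (v < env$best_val) {
    env$best_val <- v
    env$best <- params
    env$since <- 0L
  } else env$since <- env$since + 1L
  v
}

#' Train an MLP by full-batch gradient descent
#'
#' Implements the plain back-propagation update
#' w^t = w^(t-1) - gamma * dE/dw with a crisp learning rate gamma, on the
#' full training batch. Returns the parameters with the best validation
#' MSE seen (or the final parameters when no validation set is given).
#'
#' @param params Initial `mlp_params`.
#' @param x,y Scaled training design matrix and target.
#' @param x_val,y_val Optional validation partition for early stopping.
#' @param control An [mlp_control()] list.
#' @return A list with `params`, `trace` (per-epoch data.frame of training
#'   SSE and validation MSE) and `epochs`.
#' @export
train_backprop <- function(params, x, y, x_val = NULL, y_val = NULL,
                           control = mlp_control()) {
  stopifnot(nrow(x) >= 1L, length(y) == nrow(x))
  tracker <- new_tracker(params, x_val, y_val)
  trace <- vector("list", control$max_epochs)
  n_ep <- 0L
  for (ep in seq_len(control$max_epochs)) {
    g <- mlp_gradient(params, x, y)
    w <- pack_mlp(params) - control$learning_rate * g
    params <- unpack_mlp(w, params$hidden_size, params$n_inputs,
                         params$activation)
    sse <- mlp_sse(params, x, y)
    if (!is.finite(sse)) {
      stop(sprintf("non-finite training loss at epoch %d (learning rate too large?)",
                   ep), call. = FALSE)
    }
    vm <- track(tracker, params, x_val, y_val)
    trace[[ep]] <- data.frame(epoch = ep, train_sse = sse,
                              val_mse = if (isFALSE(vm)) NA_real_ else vm)
    n_ep <- ep
    if (!is.null(x_val) && tracker$since >= control$patience) break
  }
  list(params = tracker$best,
       trace = if (n_ep > 0L) do.call(rbind, trace[seq_len(n_ep)]) else
         data.frame(epoch = integer(), train_sse = numeric(),
                    val_mse = numeric()),
       epochs = n_ep)
}

#' Train an MLP by Levenberg-Marquardt
#'
#' Damped Gauss-Newton on the residual vector: each step solves
#' (J'J + lambda I) dw = -J'r. Accepted steps (SSE decreases) shrink
#' lambda; rejected steps grow it and are retried. Training stops at
#' `max_epochs` accepted steps, when lambda exceeds `lambda_max`, when the
#' SSE improvement drops below `tol`, or on validation patience. As with
#' the gradient trainer, the best-validation parameters are returned.
#'
#' @inheritParams train_backprop
#' @return A list with `params`, `trace` and `epochs`.
#' @export
train_lm <- function(params, x, y, x_val = NULL, y_val = NULL,
                     control = mlp_control()) {
  stopifnot(nrow(x) >= 1L, length(y) == nrow(x))
  lambda <- control$lambda0
  tracker <- new_tracker(params, x_val, y_val)
  sse <- mlp_sse(params, x, y)
  trace <- vector("list", control$max_epochs)
  n_ep <- 0L
  for (ep in seq_len(control$max_epochs)) {
    jj <- mlp_jacobian(params, x, y)
    jtj <- crossprod(jj$J)
    jtr <- crossprod(jj$J, jj$r)
    accepted <- FALSE
    while (!accepted && lambda <= control$lambda_max) {
      step <- tryCatch(
        solve(jtj + diag(lambda, ncol(jtj)), -jtr),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        cand <- unpack_mlp(pack_mlp(params) + drop(step), params$hidden_size,
                           params$n_inputs, params$activation)
        cand_sse <- mlp_sse(cand, x, y)
        if (is.finite(cand_sse) && cand_sse < sse) {
          accepted <- TRUE
          params <- cand
          improvement <- sse - cand_sse
          sse <- cand_sse
          lambda <- max(lambda * control$lambda_dec, 1e-12)
        }
      }
      if (!accepted) lambda <- lambda * control$lambda_inc
    }
    if (!accepted) break  # damping overflow: no descent direction left
    vm <- track(tracker, params, x_val, y_val)
    trace[[ep]] <- data.frame(epoch = ep, train_sse = sse,
                              val_mse = if (isFALSE(vm)) NA_real_ else vm,
                              lambda = lambda)
    n_ep <- ep
    if (improvement < control$tol) break
    if (!is.null(x_val) && tracker$since >= control$patience) break
  }
  list(params = tracker$best,
       trace = if (n_ep > 0L) do.call(rbind, trace[seq_len(n_ep)]) else
         data.frame(epoch = integer(), train_sse = numeric(),
                    val_mse = numeric(), lambda = numeric()),
       epochs = n_ep)
}

#' Fit the hypericin MLP on a sample table
#'
#' Encodes the 13 predictors, fits a min-max scaler on the training
#' partition only, scales features and target to [-1, 1], and trains a
#' `hidden`-unit logsig/purelin network. The default configuration is the
#' 13-26-1 structure with Levenberg-Marquardt training and early stopping
#' on the validation partition.
#'
#' @param table A `sample_table` with a hypericin target.
#' @param split A `hyp_split` from [split_dataset()].
#' @param hidden Hidden-layer size (default 26).
#' @param trainer `"lm"` (Levenberg-Marquardt, default) or `"backprop"`.
#' @param seed Seed for weight initialisation.
#' @param control An [mlp_control()] list.
#' @return An object of class `hyp_mlp` carrying the trained parameters,
#'   the fitted scaler, the loss trace and the configuration.
#' @export
fit_mlp <- function(table, split, hidden = 26L,
                    trainer = c("lm", "backprop"), seed = 1L,
                    control = mlp_control()) {
  trainer <- match.arg(trainer)
  enc <- encode_features(table)
  if (is.null(enc$y)) stop("training table has no hypericin target", call. = FALSE)
  scaler <- fit_scaler(enc$x[split$train, , drop = FALSE], enc$y[split$train])
  xs <- apply_scaler(scaler, enc$x)
  ys <- scale_target(scaler, enc$y)
  params <- init_mlp(hidden, seed = seed, n_inputs = ncol(enc$x))
  fitfun <- if (trainer == "lm") train_lm else train_backprop
  fit <- fitfun(params, xs[split$train, , drop = FALSE], ys[split$train],
                xs[split$val, , drop = FALSE], ys[split$val], control)
  structure(list(params = fit$params, scaler = scaler, trace = fit$trace,
                 epochs = fit$epochs, hidden = as.integer(hidden),
                 trainer = trainer, seed = as.integer(seed),
                 control = control, model_id = "MLP"),
            class = c("hyp_mlp", "hyp_model"))
}

#' Predict hypericin content with a trained model
#'
#' Applies the model's stored scaler to the encoded predictors, runs the
#' model, and inverse-scales the output back to mg/g. Works identically
#' for `hyp_mlp`, `hyp_rbf` and `hyp_svr` objects.
#'
#' @param object A trained model.
#' @param newdata A `sample_table`, data.frame, or pre-encoded numeric
#'   matrix of 13 predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted hypericin content (mg/g),
#'   order-preserving in the rows of `newdata`.
#' @export
predict.hyp_mlp <- function(object, newdata, ...) {
  xs <- prepare_features(object, newdata)
  unname(unscale_target(object$scaler, mlp_forward(object$params, xs)))
}

prepare_features <- function(object, newdata) {
  x <- if (is.matrix(newdata)) newdata else encode_features(newdata)$x
  apply_scaler(object$scaler, x)
}

#' @export
print.hyp_mlp <- function(x, ...) {
  cat(sprintf("<hyp_mlp> %d-%d-1 logsig/purelin, trainer %s, %d epochs\n",
              x$params$n_inputs, x$hidden, x$trainer, x$epochs))
  invisible(x)
}
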