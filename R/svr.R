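# Epsilon-insensitive support-vector regression with a Gaussian kernel,
# solved from scratch via the convex dual.
#
# Primal: min 1/2 ||w||^2 + C sum(xi_i + xi_i*) subject to residuals within
# the epsilon tube up to slacks. Dual, in the split multipliers
# z = (alpha+, alpha-) with 0 <= z <= C and sum(alpha+) = sum(alpha-):
#   min 1/2 z'Qz + p'z,  Q = [[K,-K],[-K,K]],  p = (eps - y, eps + y).
# The solver is SMO with maximal-violating-pair working-set selection
# (the libsvm scheme): each iteration updates the two multipliers that
# most violate the KKT conditions, with an exact analytic line search
# clipped to the box. The predictor is f(x) = sum_i beta_i K(x_i, x) + b
# with beta = alpha+ - alpha-; points strictly inside the tube end with
# beta = 0 and drop out of the support set.

#' Gaussian (RBF) kernel
#'
#' K(x_i, x_j) = exp(-gamma ||x_i - x_j||^2). Symmetric; equals 1 iff the
#' two points coincide.
#'
#' @param x_i,x_j Numeric vectors of equal length.
#' @param gamma Kernel parameter (> 0; 0 gives the constant kernel and is
#'   only meaningful in algebraic checks).
#' @return Scalar in (0, 1].
#' @export
gaussian_kernel <- function(x_i, x_j, gamma) {
  exp(-gamma * sum((x_i - x_j)^2))
}

# Dense Gaussian kernel matrix between row sets.
kernel_matrix <- function(x1, x2, gamma) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  exp(-gamma * pmax(d2, 0))
}

#' Dual objective of epsilon-SVR
#'
#' 1/2 beta' K beta - y' beta + epsilon * sum(|beta|), the dual objective
#' in the signed multipliers beta = alpha+ - alpha- (equal at any point
#' where alpha+ and alpha- are not simultaneously positive).
#'
#' @param beta Signed dual coefficients.
#' @param k Kernel matrix of the training points.
#' @param y Training targets (scaled space).
#' @param epsilon Tube half-width.
#' @return Scalar objective value (minimised by the solver).
#' @export
svr_dual_objective <- function(beta, k, y, epsilon) {
  drop(0.5 * beta %*% k %*% beta - sum(y * beta) + epsilon * sum(abs(beta)))
}

#' Solve the epsilon-SVR dual by SMO
#'
#' @param x Numeric training matrix (scaled features).
#' @param y Numeric training target (scaled).
#' @param cost Box constraint C (> 0).
#' @param epsilon Tube half-width (>= 0).
#' @param gamma Gaussian-kernel parameter (> 0).
#' @param tol KKT violation tolerance (stopping rule m - M < tol).
#' @param max_iter Maximum number of pairwise updates.
#' @return A list with signed coefficients `beta`, bias `b`, the final KKT
#'   `gap`, `iterations`, `objective` (dual), and the kernel matrix used.
#' @export
svr_solve_dual <- function(x, y, cost, epsilon, gamma,
                           tol = 1e-8, max_iter = 200000L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, length(y) == nrow(x),
            cost > 0, epsilon >= 0, gamma >= 0)
  n <- nrow(x)
  k <- kernel_matrix(x, x, gamma)
  s <- c(rep(1, n), rep(-1, n))
  kt <- rbind(cbind(k, k), cbind(k, k))       # K-tilde: K on index mod n
  q <- kt * tcrossprod(s)                     # Q = S K-tilde S
  p <- c(epsilon - y, epsilon + y)
  z <- numeric(2L * n)
  g <- p                                      # gradient Qz + p at z = 0
  it <- 0L
  gap <- Inf
  repeat {
    viol <- -s * g
    up <- (s > 0 & z < cost) | (s < 0 & z > 0)
    lo <- (s > 0 & z > 0) | (s < 0 & z < cost)
    i <- which(up)[which.max(viol[up])]
    gap <- viol[i] - min(viol[lo])
    if (gap < tol || it >= max_iter) break
    # second-order pair choice: maximise the guaranteed decrease b^2 / a
    cand <- which(lo & viol < viol[i])
    bvec <- viol[i] - viol[cand]
    avec <- pmax(kt[i, i] + diag(kt)[cand] - 2 * kt[i, cand], 1e-12)
    j <- cand[which.max(bvec^2 / avec)]
    a <- kt[i, i] + kt[j, j] - 2 * kt[i, j]
    t_star <- if (a > 1e-300) (viol[i] - viol[j]) / a else Inf
    t_hi <- min(if (s[i] > 0) cost - z[i] else z[i],
                if (s[j] > 0) z[j] else cost - z[j])
    t_step <- min(t_star, t_hi)
    z[i] <- z[i] + s[i] * t_step
    z[j] <- z[j] - s[j] * t_step
    g <- g + q[, i] * (s[i] * t_step) - q[, j] * (s[j] * t_step)
    it <- it + 1L
  }
  if (it >= max_iter && gap >= tol) {
    stop(sprintf(
      "SMO did not converge: KKT gap %.3e after %d iterations (tol %.1e)",
      gap, it, tol), call. = FALSE)
  }
  beta <- z[seq_len(n)] - z[n + seq_len(n)]
  # Bias from margin-interior (free) multipliers; fall back to the midpoint
  # of the KKT interval when every multiplier is at a bound.
  free <- (z > tol & z < cost - tol)
  b <- if (any(free)) mean((-s * g)[free]) else {
    viol <- -s * g
    up <- (s > 0 & z < cost) | (s < 0 & z > 0)
    lo <- (s > 0 & z > 0) | (s < 0 & z < cost)
    (max(viol[up]) + min(viol[lo])) / 2
  }
  list(beta = beta, b = b, gap = gap, iterations = it,
       objective = svr_dual_objective(beta, k, y, epsilon), k = k)
}

#' Fit the hypericin epsilon-SVR on a sample table
#'
#' Scaling as in [fit_mlp()]; epsilon and C act on the [-1, 1]-scaled
#' target (the preset epsilon = 0.0002 is a tube on that scale). The SVR
#' has no early-stopping role for the validation partition; it is fit on
#' the training rows only and the validation rows simply remain available
#' for evaluation.
#'
#' @inheritParams fit_mlp
#' @param cost Box constraint C (preset 995.2).
#' @param epsilon Tube half-width on the scaled target (preset 0.0002).
#' @param gamma Gaussian-kernel parameter; default 1/13 (reciprocal of the
#'   feature count).
#' @param tol,max_iter SMO stopping parameters.
#' @return An object of class `hyp_svr` with the support vectors, signed
#'   coefficients, bias, kernel settings and scaler.
#' @export
fit_svr <- function(table, split, cost = 995.2, epsilon = 2e-4,
                    gamma = 1 / 13, tol = 1e-8, max_iter = 200000L,
                    seed = 1L) {
  enc <- encode_features(table)
  if (is.null(enc$y)) stop("training table has no hypericin target", call. = FALSE)
  scaler <- fit_scaler(enc$x[split$train, , drop = FALSE], enc$y[split$train])
  xs <- apply_scaler(scaler, enc$x[split$train, , drop = FALSE])
  ys <- scale_target(scaler, enc$y[split$train])
  sol <- svr_solve_dual(xs, ys, cost = cost, epsilon = epsilon,
                        gamma = gamma, tol = tol, max_iter = max_iter)
  sv <- which(abs(sol$beta) > 1e-12)
  structure(list(
    params = list(beta = sol$beta[sv], sv = xs[sv, , drop = FALSE],
                  b = sol$b, gamma = gamma, cost = cost, epsilon = epsilon,
                  n_sv = length(sv), gap = sol$gap,
                  iterations = sol$iterations, objective = sol$objective),
    scaler = scaler, seed = as.integer(seed), model_id = "SVR"
  ), class = c("hyp_svr", "hyp_model"))
}

#' Evaluate an SVR model on scaled inputs
#' @param params The `params` list of a `hyp_svr`.
#' @param x Scaled feature matrix.
#' @return Numeric vector of scaled outputs.
#' @export
svr_forward <- function(params, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (params$n_sv == 0L) return(rep(params$b, nrow(x)))
  drop(kernel_matrix(x, params$sv, params$gamma) %*% params$beta) + params$b
}

#' @rdname predict.hyp_mlp
#' @export
predict.hyp_svr <- function(object, newdata, ...) {
  xs <- prepare_features(object, newdata)
  unname(unscale_target(object$scaler, svr_forward(object$params, xs)))
}

#' @export
print.hyp_svr <- function(x, ...) {
  cat(sprintf(
    "<hyp_svr> %d support vectors, C %.4g, epsilon %.4g, gamma %.4g\n",
    x$params$n_sv, x$params$cost, x$params$epsilon, x$params$gamma))
  invisible(x)
}
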