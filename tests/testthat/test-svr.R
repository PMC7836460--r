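test_that("Gaussian kernel matches its closed form and is symmetric", {
  a <- c(1, 2); b <- c(1, 2)
  expect_equal(gaussian_kernel(a, b, 0.7), 1.0)
  expect_equal(gaussian_kernel(c(0, 0), c(1, 0), 1), exp(-1), tolerance = 1e-12)
  for (seed in 1:5) {
    u <- hypericinML:::with_seed(seed, stats::rnorm(13))
    v <- hypericinML:::with_seed(seed + 10, stats::rnorm(13))
    expect_equal(gaussian_kernel(u, v, 0.3), gaussian_kernel(v, u, 0.3))
  }
})

test_that("constant targets inside the tube give zero multipliers and bias c", {
  x <- rand_x(15, seed = 1)
  y <- rep(0.4, 15)
  sol <- svr_solve_dual(x, y, cost = 10, epsilon = 0.1, gamma = 0.5)
  expect_equal(sol$beta, rep(0, 15))
  expect_equal(sol$b, 0.4, tolerance = 0.1)  # KKT pins b within the tube
  expect_lt(max(abs(y - (sol$b))), 0.1 + 1e-9)
})

test_that("large C and zero epsilon nearly interpolate near-linear data", {
  x <- matrix(seq(-1, 1, length.out = 8), 8, 1)
  y <- 0.8 * x[, 1] + 0.05
  sol <- svr_solve_dual(x, y, cost = 1e6, epsilon = 0, gamma = 2,
                        tol = 1e-10)
  k <- hypericinML:::kernel_matrix(x, x, 2)
  f <- drop(k %*% sol$beta) + sol$b
  expect_lt(max(abs(f - y)), 1e-6)
})

test_that("KKT conditions hold at the SMO solution on random instances", {
  for (seed in 1:5) {
    n <- 20
    x <- rand_x(n, d = 4, seed = seed)
    y <- hypericinML:::with_seed(seed + 30,
      0.5 * x[, 1] - 0.4 * x[, 2]^2 + stats::rnorm(n, 0, 0.1))
    C <- 5; eps <- 0.1; gam <- 0.5
    sol <- svr_solve_dual(x, y, C, eps, gam, tol = 1e-10)
    expect_true(all(abs(sol$beta) <= C + 1e-8))         # box
    expect_lt(abs(sum(sol$beta)), 1e-8)                 # equality constraint
    k <- hypericinML:::kernel_matrix(x, x, gam)
    resid <- y - (drop(k %*% sol$beta) + sol$b)
    inside <- abs(resid) < eps - 1e-6
    expect_true(all(abs(sol$beta[inside]) < 1e-6))      # strict interior -> 0
    at_bound <- abs(abs(sol$beta) - C) < 1e-8
    expect_true(all(abs(resid[at_bound]) >= eps - 1e-6))  # bound -> outside tube
  }
})

test_that("SMO attains the optimum certified by an interior-point QP oracle", {
  library(kernlab)
  for (seed in 1:4) {
    n <- c(12, 20, 25, 30)[seed]
    x <- rand_x(n, d = 3, seed = seed + 5)
    y <- hypericinML:::with_seed(seed + 60,
      0.5 * x[, 1] - 0.3 * x[, 2]^2 + stats::rnorm(n, 0, 0.1))
    C <- 10; eps <- 0.05; gam <- 0.5
    sol <- svr_solve_dual(x, y, C, eps, gam, tol = 1e-10)
    k <- hypericinML:::kernel_matrix(x, x, gam)
    qp <- kernlab::ipop(
      c = c(eps - y, eps + y),
      H = rbind(cbind(k, -k), cbind(-k, k)),
      A = matrix(c(rep(1, n), rep(-1, n)), 1), b = 0,
      l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
      sigf = 9, maxiter = 300)
    z <- kernlab::primal(qp)
    obj_oracle <- svr_dual_objective(z[1:n] - z[n + 1:n], k, y, eps)
    expect_lt(abs(sol$objective - obj_oracle) / max(abs(obj_oracle), 1e-12),
              1e-6)
  }
})

test_that("growing the tube weakly shrinks the support-vector set", {
  n <- 40
  x <- rand_x(n, d = 3, seed = 13)
  y <- hypericinML:::with_seed(77,
    0.6 * x[, 1] + 0.2 * x[, 3] + stats::rnorm(n, 0, 0.05))
  n_sv <- vapply(c(0.01, 0.05, 0.1, 0.2), function(eps) {
    sol <- svr_solve_dual(x, y, cost = 10, epsilon = eps, gamma = 0.5)
    sum(abs(sol$beta) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(n_sv) <= 0))
})

test_that("prediction agrees with the brute-force kernel expansion and handles edge cases", {
  params <- list(beta = hypericinML:::with_seed(4, stats::rnorm(6)),
                 sv = rand_x(6, seed = 7), b = 0.2, gamma = 0.3,
                 cost = 1, epsilon = 0.1, n_sv = 6L)
  x <- rand_x(9, seed = 8)
  naive <- vapply(seq_len(nrow(x)), function(i) {
    s <- params$b
    for (j in seq_len(params$n_sv)) {
      s <- s + params$beta[j] * exp(-params$gamma *
                                      sum((x[i, ] - params$sv[j, ])^2))
    }
    s
  }, numeric(1))
  expect_equal(svr_forward(params, x), naive, tolerance = 1e-12)
  # zero support vectors -> constant bias
  empty <- params; empty$n_sv <- 0L; empty$beta <- numeric(0)
  expect_equal(svr_forward(empty, x), rep(0.2, 9))
  # duplicated inputs -> identical predictions
  expect_equal(svr_forward(params, x[c(1, 1), ])[1],
               svr_forward(params, x[c(1, 1), ])[2])
})

test_that("the published preset (epsilon 0.0002, C 995.2) trains and predicts on habitat data", {
  tab <- small_table(n = 100, seed = 14)
  sp <- split_dataset(100, seed = 14)
  m <- fit_svr(tab, sp)
  expect_s3_class(m, "hyp_svr")
  expect_equal(m$params$cost, 995.2)
  expect_equal(m$params$epsilon, 2e-4)
  p <- predict(m, as.data.frame(tab)[, predictor_names()])
  expect_length(p, 100L)
  expect_true(all(is.finite(p)))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  expect_equal(predict(load_model(path), as.data.frame(tab)[, predictor_names()]),
               p, tolerance = 1e-9)
})
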