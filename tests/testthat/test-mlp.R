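test_that("initialisation is shaped, seeded and validated", {
  p <- init_mlp(26, seed = 1)
  expect_equal(dim(p$W1), c(26L, 13L))
  expect_equal(length(p$w2), 26L)
  expect_identical(p, init_mlp(26, seed = 1))
  expect_false(identical(p$W1, init_mlp(26, seed = 2)$W1))
  expect_true(all(abs(hypericinML:::pack_mlp(p)) <= 0.5))
  expect_error(init_mlp(0), ">= 1")
})

test_that("forward pass follows the logsig/purelin equations", {
  # all-zero weights -> output 0 for any input
  p0 <- hypericinML:::unpack_mlp(rep(0, 5 * 13 + 5 + 5 + 1), 5L, 13L)
  expect_equal(mlp_forward(p0, rand_x(4)), rep(0, 4))
  # logsig(0) = 0.5 via a single pass-through unit
  w <- rep(0, 1 * 13 + 1 + 1 + 1)
  p1 <- hypericinML:::unpack_mlp(w, 1L, 13L)
  p1$w2 <- 1
  expect_equal(mlp_forward(p1, rep(0, 13)), 0.5)
  # hand evaluation: w1 = e1, w2 = 2 -> 2 * logsig(1)
  p2 <- p1
  p2$W1[1, 1] <- 1
  p2$w2 <- 2
  x <- c(1, rep(0, 12))
  expect_equal(mlp_forward(p2, x), 2 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(mlp_forward(p2, x), 1.4621171573, tolerance = 1e-9)
  expect_error(mlp_forward(p2, rep(0, 12)), "input columns")
})

test_that("analytic SSE gradients match central finite differences", {
  for (seed in 1:10) {
    p <- init_mlp(4, seed = seed, n_inputs = 6L)
    x <- rand_x(8, d = 6, seed = seed + 100)
    y <- hypericinML:::with_seed(seed + 200, stats::rnorm(8))
    g <- mlp_gradient(p, x, y)
    w0 <- hypericinML:::pack_mlp(p)
    h <- 1e-6
    fd <- vapply(seq_along(w0), function(k) {
      wp <- w0; wm <- w0
      wp[k] <- wp[k] + h; wm[k] <- wm[k] - h
      (hypericinML:::mlp_sse(hypericinML:::unpack_mlp(wp, 4L, 6L), x, y) -
       hypericinML:::mlp_sse(hypericinML:::unpack_mlp(wm, 4L, 6L), x, y)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("gradient-descent training implements the crisp-rate update and converges on a trivial problem", {
  p <- init_mlp(3, seed = 1, n_inputs = 2L)
  x <- matrix(c(0.3, -0.2), 1, 2)
  y <- 0.7
  # max_epochs = 0 returns the parameters unchanged
  fit0 <- train_backprop(p, x, y, control = mlp_control(max_epochs = 0))
  expect_identical(fit0$params, p)
  expect_equal(fit0$epochs, 0L)
  # one epoch equals one explicit w - gamma * dE/dw step
  ctl <- mlp_control(learning_rate = 0.1, max_epochs = 1)
  fit1 <- train_backprop(p, x, y, control = ctl)
  manual <- hypericinML:::pack_mlp(p) - 0.1 * mlp_gradient(p, x, y)
  expect_equal(hypericinML:::pack_mlp(fit1$params), manual, tolerance = 1e-12)
  # single-sample convergence
  fit <- train_backprop(p, x, y, control = mlp_control(learning_rate = 0.5,
                                                      max_epochs = 2000))
  expect_lt(hypericinML:::mlp_sse(fit$params, x, y), 1e-6)
})

test_that("LM steps approach scaled gradient descent in the large-damping limit", {
  p <- init_mlp(3, seed = 4, n_inputs = 5L)
  x <- rand_x(12, d = 5, seed = 9)
  y <- hypericinML:::with_seed(10, stats::rnorm(12, 0, 0.5))
  jj <- hypericinML:::mlp_jacobian(p, x, y)
  lambda <- 1e8
  step <- solve(crossprod(jj$J) + diag(lambda, ncol(jj$J)),
                -crossprod(jj$J, jj$r))
  grad_dir <- -mlp_gradient(p, x, y) / (2 * lambda)
  expect_lt(max(abs(drop(step) - grad_dir)) / max(abs(grad_dir)), 1e-4)
})

test_that("LM training loss is nonincreasing and reaches the least-squares optimum of a linear toy", {
  # identity-activation network fitted to exactly linear data must match OLS
  x <- rand_x(40, d = 3, seed = 2)
  beta <- c(0.5, -0.3, 0.2)
  y <- drop(x %*% beta) + 0.1
  p <- init_mlp(2, seed = 1, n_inputs = 3L, activation = "identity")
  fit <- train_lm(p, x, y, control = mlp_control(max_epochs = 200))
  expect_true(all(diff(fit$trace$train_sse) <= 1e-12))
  ols <- stats::lm.fit(cbind(x, 1), y)
  expect_lt(hypericinML:::mlp_sse(fit$params, x, y), sum(ols$residuals^2) + 1e-10)
})

test_that("LM recovers a teacher network and early stopping returns the best-validation weights", {
  teacher <- init_mlp(4, seed = 11)
  n <- 300
  x <- rand_x(n, seed = 21)
  y <- mlp_forward(teacher, x)
  tr <- 1:180; va <- 181:240; te <- 241:300
  student <- init_mlp(8, seed = 3)
  fit <- train_lm(student, x[tr, ], y[tr], x[va, ], y[va],
                  mlp_control(max_epochs = 300, patience = 50))
  pr <- mlp_forward(fit$params, x[te, ])
  r2 <- 1 - sum((pr - y[te])^2) / sum((y[te] - mean(y[te]))^2)
  expect_gte(r2, 0.99)
  # returned parameters are at least as good as every recorded epoch
  val_mse <- mean((mlp_forward(fit$params, x[va, ]) - y[va])^2)
  expect_lte(val_mse, min(fit$trace$val_mse) + 1e-15)
})

test_that("fitted models are seed-reproducible and predict order-equivariantly", {
  tab <- small_table(n = 60, seed = 5)
  sp <- split_dataset(60, seed = 5)
  ctl <- mlp_control(max_epochs = 40)
  m1 <- fit_mlp(tab, sp, hidden = 6, seed = 2, control = ctl)
  m2 <- fit_mlp(tab, sp, hidden = 6, seed = 2, control = ctl)
  expect_identical(m1$params, m2$params)
  newdata <- as_sample_table(as.data.frame(tab)[, predictor_names()])
  p <- predict(m1, newdata)
  expect_length(p, 60L)
  perm <- hypericinML:::with_seed(1, sample(60))
  p_perm <- predict(m1, newdata[perm, , drop = FALSE])
  expect_equal(p_perm, p[perm], tolerance = 1e-12)
})
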