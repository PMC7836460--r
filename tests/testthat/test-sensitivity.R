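# A linear model expressed as a 1-unit identity-activation network with an
# identity scaler: predictions are exactly coefs . x + intercept, so the
# one-at-a-time sensitivities have a closed form (|coef| * popsd(grid)).
linear_mlp <- function(coefs, intercept = 0) {
  p <- hypericinML:::unpack_mlp(rep(0, 13 + 1 + 1 + 1), 1L, 13L,
                                activation = "identity")
  p$W1[1, ] <- coefs
  p$w2 <- 1
  p$b2 <- intercept
  sc <- fit_scaler(rbind(rep(-1, 13), rep(1, 13)), c(-1, 1))
  structure(list(params = p, scaler = sc, model_id = "LIN"),
            class = c("hyp_mlp", "hyp_model"))
}

# Hand-made training statistics on the identity-scaled cube: every
# continuous variable has mean 0, SD 0.25 inside [-1, 1]; ordinals keep
# their real code ranges with mean code 2.
fake_stats <- function() {
  sc <- hypericum_schema()
  kind <- sc$kind[match(predictor_names(), sc$name)]
  df <- data.frame(name = predictor_names(), kind = kind,
                   mean = ifelse(kind == "ordinal", 2, 0),
                   sd = ifelse(kind == "ordinal", 0.8, 0.25),
                   min = ifelse(kind == "ordinal", 1, -1),
                   max = ifelse(kind == "ordinal",
                                c(aspect = 4, phenology = 3)[predictor_names()],
                                1),
                   stringsAsFactors = FALSE)
  structure(df, n_source = 60L, class = c("sample_stats", "data.frame"))
}

test_that("perturbation grids sweep one variable and freeze the rest", {
  st <- fake_stats()
  g <- build_perturbation_grid("altitude", st, k = 3)
  df <- as.data.frame(g)
  expect_equal(df$altitude, c(-0.25, 0, 0.25))
  for (nm in setdiff(predictor_names(), "altitude")) {
    expect_equal(length(unique(df[[nm]])), 1L, label = paste("frozen", nm))
  }
  # ordinal sweep: exactly the valid codes
  expect_equal(as.data.frame(build_perturbation_grid("aspect", st))$aspect,
               1:4)
  expect_equal(as.data.frame(build_perturbation_grid("phenology", st))$phenology,
               1:3)
  expect_error(build_perturbation_grid("moisture", st), "unknown variable")
})

test_that("grids clip to the observed bounds of real training data", {
  tab <- small_table(n = 80, seed = 21)
  st <- sample_stats(tab)
  for (nm in c("altitude", "organic_carbon", "ph")) {
    i <- match(nm, st$name)
    g <- as.data.frame(build_perturbation_grid(nm, st, k = 11))
    expect_true(all(g[[nm]] >= st$min[i] & g[[nm]] <= st$max[i]))
  }
})

test_that("sensitivities of a linear model follow the closed-form coefficient ratios", {
  st <- fake_stats()
  coefs <- rep(0, 13)
  coefs[match("total_nitrogen", predictor_names())] <- 2
  coefs[match("ph", predictor_names())] <- 1
  m <- linear_mlp(coefs)
  s <- sensitivity_scores(m, st, k = 21)
  expect_equal(s$variable[1:2], c("total_nitrogen", "ph"))
  expect_equal(s$score[1], 1)
  expect_equal(s$raw_sd[1] / s$raw_sd[2], 2, tolerance = 1e-9)
  # closed form: |coef| * population SD of the 21-point grid
  grid_vals <- seq(-0.25, 0.25, length.out = 21)
  expect_equal(s$raw_sd[1], 2 * sqrt(mean((grid_vals - mean(grid_vals))^2)),
               tolerance = 1e-12)
  # every zero-coefficient variable scores exactly 0
  expect_true(all(s$raw_sd[-(1:2)] == 0))
  # single-driver model: score 1 for it, 0 elsewhere
  solo <- rep(0, 13); solo[1] <- 0.5
  s1 <- sensitivity_scores(linear_mlp(solo), st)
  expect_equal(s1$score, c(1, rep(0, 12)))
})

test_that("normalised scores are invariant to affine rescaling of the output", {
  st <- fake_stats()
  coefs <- seq(0.1, 1.3, length.out = 13)
  s1 <- sensitivity_scores(linear_mlp(coefs), st)
  s2 <- sensitivity_scores(linear_mlp(5 * coefs, intercept = -3), st)
  expect_equal(s2$score, s1$score, tolerance = 1e-12)
  expect_equal(s2$variable, s1$variable)
})

test_that("a constant model warns and reports all-zero scores", {
  st <- fake_stats()
  expect_warning(s <- sensitivity_scores(linear_mlp(rep(0, 13), 1.5), st),
                 "constant")
  expect_true(all(s$score == 0))
})

test_that("response curves compose with predict and flag monotone trends", {
  st <- fake_stats()
  up <- rep(0, 13); up[match("altitude", predictor_names())] <- 1
  m <- linear_mlp(up)
  cv <- response_curve(m, "altitude", st, k = 15)
  expect_equal(attr(cv, "trend"), "increasing")
  g <- build_perturbation_grid("altitude", st, k = 15)
  expect_equal(cv$prediction, predict(m, g), tolerance = 1e-12)
  down <- -up
  expect_equal(attr(response_curve(linear_mlp(down), "altitude", st), "trend"),
               "decreasing")
  flat <- linear_mlp(rep(0, 13), 2)
  expect_equal(attr(response_curve(flat, "altitude", st), "trend"), "flat")
})
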