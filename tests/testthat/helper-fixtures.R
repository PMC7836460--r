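# Shared fixtures, all built in code at test time.

# Small synthetic habitat table (with target) under a fixed seed.
small_table <- function(n = 50, seed = 7, noise_sd = 0.05) {
  cfg <- generator_config(noise_sd = noise_sd)
  generate_dataset(cfg, n = n, seed = seed)
}

# A minimal valid 3-row data.frame of raw samples, hand-written values.
tiny_df <- function(with_target = TRUE) {
  df <- data.frame(
    altitude = c(1500, 2300, 3500), slope = c(10, 20, 30),
    aspect = c(1, 3, 4), phenology = c(1, 2, 3),
    organic_carbon = c(0.5, 1.0, 2.0), total_nitrogen = c(0.2, 0.3, 0.5),
    phosphorus = c(1, 3, 5), potassium = c(120, 200, 280),
    sand = c(36, 42, 49), silt = c(25, 38, 48), clay = c(8, 20, 33),
    ec = c(0.03, 0.09, 0.18), ph = c(6.5, 7.2, 7.8)
  )
  if (with_target) df$hypericin <- c(1.2, 1.6, 2.0)
  df
}

# Random scaled design matrix for model-level unit tests.
rand_x <- function(n, d = 13, seed = 1) {
  hypericinML:::with_seed(seed, matrix(stats::runif(n * d, -1, 1), n, d))
}

expect_setequal_vars <- function(got, expected) {
  expect_true(setequal(got, expected),
              label = paste("variables:", paste(sort(got), collapse = ", ")))
}
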