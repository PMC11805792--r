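test_that("default grid reproduces the documented parameter space", {
  g <- parameter_grid()
  expect_equal(g$noise_levels, c(3.0, 1.53, 1.0, 0.65))
  expect_equal(g$correlations, c(0.75, 0.5, 0.25, 0.0001))
  expect_length(g$beta1_values, 8)
  expect_length(g$beta2_values, 8)
  expect_length(g$beta3_values, 9)
  expect_false(0 %in% g$beta1_values)
  expect_false(0 %in% g$beta2_values)
  expect_true(0 %in% g$beta3_values)
  expect_equal(c(g$mu_x, g$mu_z, g$sd_x, g$sd_z), c(1, 2, 1, 1))
})

test_that("strict calibration substitutes exact noise levels", {
  g <- parameter_grid(strict_calibration = TRUE)
  expect_equal(g$noise_levels, sqrt(1 / c(0.1, 0.3, 0.5, 0.7) - 1))
  expect_equal(round(g$noise_levels, 2), c(3.00, 1.53, 1.00, 0.65))
})

test_that("grid validation rejects degenerate inputs", {
  expect_error(parameter_grid(beta1_values = c(-1, 0, 1)), "must not contain 0")
  expect_error(parameter_grid(noise_levels = numeric(0)), "non-empty")
  expect_error(parameter_grid(correlations = c(0.5, 1)), "inside")
  expect_error(parameter_grid(beta3_values = c(0.5, 0.5)), "duplicated")
})

test_that("enumerate_conditions forms the full ordered product", {
  conds <- enumerate_conditions(parameter_grid())
  expect_equal(nrow(conds), 9216) # 4 * 4 * 8 * 8 * 9
  expect_equal(sum(conds$beta3 == 0), 1024) # 4 * 4 * 8 * 8
  expect_equal(anyDuplicated(conds$cell_id), 0)
  # documented lexicographic order: lambda desc, r desc, betas asc
  expect_equal(conds$lambda, sort(conds$lambda, decreasing = TRUE))
  expect_equal(conds$lambda[1], 3.0)
  expect_equal(conds$r[1], 0.75)
  expect_equal(conds[1, c("beta1", "beta2", "beta3")],
               data.frame(beta1 = -1, beta2 = -1, beta3 = -1),
               ignore_attr = TRUE)
  # single-value grid collapses to one condition
  g1 <- parameter_grid(noise_levels = 1, correlations = 0.25,
                       beta1_values = 0.5, beta2_values = -0.5,
                       beta3_values = 0)
  expect_equal(nrow(enumerate_conditions(g1)), 1)
  # determinism of ids across calls
  expect_identical(conds$cell_id, enumerate_conditions(parameter_grid())$cell_id)
})

test_that("classify_shape implements the sign typology", {
  # canonical examples
  expect_equal(classify_shape(1, 1, 1), "synergistic")
  expect_equal(classify_shape(1, -1, 1), "buffering")
  expect_equal(classify_shape(1, 1, -1), "antagonistic")
  expect_equal(classify_shape(1, 1, 0), "none")
  expect_error(classify_shape(0, 1, 1), "non-zero")
  expect_error(classify_shape(1, 0, 1), "non-zero")
  # invariance to negating all three weights
  set.seed(11)
  b1 <- sample(c(-1, -0.5, 0.5, 1), 50, TRUE)
  b2 <- sample(c(-1, -0.5, 0.5, 1), 50, TRUE)
  b3 <- sample(c(-1, -0.25, 0, 0.25, 1), 50, TRUE)
  expect_equal(classify_shape(b1, b2, b3), classify_shape(-b1, -b2, -b3))
})

test_that("shape classes partition every noise level as 512/512/1024/256", {
  conds <- enumerate_conditions(parameter_grid())
  for (lam in unique(conds$lambda)) {
    tab <- table(conds$shape[conds$lambda == lam])
    expect_equal(unname(tab[c("synergistic", "antagonistic", "buffering", "none")]),
                 c(512, 512, 1024, 256), ignore_attr = TRUE)
  }
})

test_that("count_analyses reproduces the full-scale k bookkeeping", {
  g <- parameter_grid()
  n6 <- c(25, 50, 100, 250, 500, 1000)
  by_noise <- count_analyses(g, reps = 1000, sample_sizes = n6, "shape_noise")
  expect_equal(unique(by_noise$k[by_noise$shape == "synergistic"]), 3072000)
  expect_equal(unique(by_noise$k[by_noise$shape == "antagonistic"]), 3072000)
  expect_equal(unique(by_noise$k[by_noise$shape == "buffering"]), 6144000)
  expect_equal(unique(by_noise$k[by_noise$shape == "none"]), 1536000)
  by_n <- count_analyses(g, reps = 1000, sample_sizes = n6, "shape_n")
  expect_equal(unique(by_n$k[by_n$shape == "synergistic"]), 2048000)
  expect_equal(unique(by_n$k[by_n$shape == "none"]), 1024000)
  # one-cell degenerate case
  g1 <- parameter_grid(noise_levels = 1, correlations = 0.25,
                       beta1_values = 1, beta2_values = 1, beta3_values = 0)
  expect_equal(count_analyses(g1, 1, 25, "shape_noise")$k, 1)
})

test_that("count_analyses equals brute-force counting over the enumeration", {
  g <- parameter_grid(noise_levels = c(1, 0.65), correlations = c(0.5, 0.25),
                      beta1_values = c(-0.5, 1), beta2_values = c(-1, 0.25),
                      beta3_values = c(-1, 0, 0.5))
  conds <- enumerate_conditions(g)
  reps <- 7; ns <- c(10, 20, 30)
  got <- count_analyses(g, reps, ns, "shape_noise")
  for (i in seq_len(nrow(got))) {
    brute <- sum(conds$shape == got$shape[i] & conds$lambda == got$lambda[i]) *
      reps * length(ns)
    expect_equal(got$k[i], brute)
  }
  got_n <- count_analyses(g, reps, ns, "shape_n")
  for (i in seq_len(nrow(got_n))) {
    brute <- sum(conds$shape == got_n$shape[i]) * reps
    expect_equal(got_n$k[i], brute)
  }
})
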