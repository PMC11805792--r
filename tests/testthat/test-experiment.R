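tiny_config <- function(population_size = 2000, reps = 2,
                        sample_sizes = c(25, 100), ...) {
  experiment_config(grid = parameter_grid(noise_levels = 0.65,
                                          correlations = 0.0001,
                                          beta1_values = 1,
                                          beta2_values = 1,
                                          beta3_values = -1),
                    profile = "desk", population_size = population_size,
                    reps = reps, sample_sizes = sample_sizes, ...)
}

test_that("experiment_config validates and applies profiles", {
  cfg <- experiment_config(profile = "desk")
  expect_equal(cfg$population_size, 1e4)
  expect_equal(cfg$reps, 100L)
  expect_equal(cfg$sample_sizes, c(25L, 100L, 1000L))
  cfg_p <- experiment_config(profile = "full")
  expect_equal(cfg_p$population_size, 1e6)
  expect_equal(cfg_p$sample_sizes, c(25L, 50L, 100L, 250L, 500L, 1000L))
  expect_error(experiment_config(alpha = 1.5), "outside")
  expect_error(experiment_config(profile = "desk", sample_sizes = c(4, 100)),
               "exceed 4")
  expect_error(experiment_config(profile = "desk",
                                 sample_sizes = c(25, 2e4)),
               "population_size")
})

test_that("run_cell yields reps x sample_sizes records, deterministically", {
  cfg <- tiny_config()
  cond <- enumerate_conditions(cfg$grid)
  rec <- run_cell(cond, cfg)
  expect_equal(nrow(rec), 4) # 2 reps x 2 sample sizes
  expect_identical(rec, run_cell(cond, cfg))
  expect_equal(attr(rec, "skipped"), 0L)
  # byte-identical CSV on re-run
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(rec, f1, row.names = FALSE)
  write.csv(run_cell(cond, cfg), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("per-replicate seeds do not depend on execution order", {
  cfg <- tiny_config()
  conds <- enumerate_conditions(cfg$grid)
  rec_a <- run_cell(conds[1, ], cfg)
  # perturb global RNG state heavily, then rerun
  set.seed(999); rnorm(1e4)
  rec_b <- run_cell(conds[1, ], cfg)
  expect_identical(rec_a, rec_b)
})

test_that("mean misspecified b2 matches the closed-form expectation", {
  cfg <- experiment_config(grid = tiny_config()$grid, profile = "desk",
                           population_size = 5e4, reps = 300,
                           sample_sizes = 1000,
                           compute_generalization = FALSE)
  cond <- enumerate_conditions(cfg$grid) # (1, 1, -1, lambda .65, r 1e-4)
  rec <- run_cell(cond, cfg)
  b_e <- expected_misspecified(spec_from_condition(cond, cfg$grid))$b_e
  se_mean <- sd(rec$b2_s) / sqrt(nrow(rec))
  # 3 MC SEs around the expectation, plus the O(1/sqrt(N_pop)) offset of
  # the finite population itself
  expect_lt(abs(mean(rec$b2_s) - b_e[["b_e2"]]), 3 * se_mean + 3 / sqrt(5e4))
})

test_that("records carry the exact delta identities", {
  cfg <- tiny_config(loocv = TRUE)
  rec <- run_cell(enumerate_conditions(cfg$grid), cfg)
  expect_equal(rec$delta_r2_s, rec$r2s_interaction - rec$r2s_simple)
  expect_equal(rec$delta_overfit, rec$delta_r2_s - rec$delta_r2_p,
               tolerance = 1e-12)
  expect_true(all(rec$delta_r2_s >= -1e-12))
  expect_true(all(rec$r2cv_interaction <= rec$r2s_interaction + 1e-12))
  expect_true(all(rec$r2cv_simple <= rec$r2s_simple + 1e-12))
})

test_that("record_level and compute_generalization trim columns", {
  cfg_d <- tiny_config(record_level = "deltas", compute_generalization = FALSE)
  rec <- run_cell(enumerate_conditions(cfg_d$grid), cfg_d)
  expect_false(any(c("b1_s", "p_b2_s", "r2p_simple") %in% names(rec)))
  expect_true(all(c("delta_r2_s", "r2s_simple") %in% names(rec)))
})

test_that("aggregate_tables matches a brute-force quantile oracle", {
  set.seed(31)
  fake <- data.frame(
    shape = rep(c("synergistic", "buffering"), each = 50),
    lambda = 0.65, n = rep(c(25, 100), 50),
    delta_r2_s = c(rnorm(50, 0.02, 0.01), rnorm(50, 0.08, 0.03)),
    delta_overfit = rnorm(100, 0, 0.02),
    delta_r2_p = rnorm(100, 0.01, 0.05))
  got <- aggregate_tables(fake, "shape_noise")
  for (sh in c("buffering", "synergistic")) {
    sub <- fake[fake$shape == sh, ]
    row <- got[got$shape == sh, ]
    expect_equal(row$delta_r2_s_mdn, median(sub$delta_r2_s))
    expect_equal(row$delta_r2_s_q10,
                 quantile(sub$delta_r2_s, 0.1, names = FALSE))
    expect_equal(row$delta_r2_p_q90,
                 quantile(sub$delta_r2_p, 0.9, names = FALSE))
    expect_equal(row$delta_overfit_pctneg, 100 * mean(sub$delta_overfit < 0))
    expect_equal(row$k, nrow(sub))
  }
  # all-zero deltas: quantiles 0 and %<0 = 0 (zeros count as not-negative)
  zero <- within(fake, {delta_r2_s <- 0; delta_overfit <- 0; delta_r2_p <- 0})
  gz <- aggregate_tables(zero, "shape_n")
  expect_true(all(gz$delta_r2_p_mdn == 0) && all(gz$delta_r2_p_pctneg == 0))
})

test_that("aggregate_power counts significant replicates per coefficient", {
  cfg <- tiny_config(reps = 30, population_size = 5000,
                     sample_sizes = c(50, 200))
  # noiseless cell: all true coefficients always significant
  g0 <- parameter_grid(noise_levels = 0, correlations = 0.0001,
                       beta1_values = 1, beta2_values = 1, beta3_values = -1)
  cfg0 <- experiment_config(grid = g0, profile = "desk",
                            population_size = 5000, reps = 30,
                            sample_sizes = c(50, 200))
  rec <- run_cell(enumerate_conditions(g0), cfg0)
  pw <- aggregate_power(rec, alpha = 0.05)
  true_nonzero <- pw[pw$model == "interaction" &
                       pw$coefficient %in% c("b1", "b2", "b3"), ]
  expect_true(all(true_nonzero$pct_significant == 100))
  expect_equal(unique(pw$k), 30)
  # brute-force cross-check of one cell of the table
  brute <- 100 * mean(rec$p_b2_s[rec$n == 50] < 0.05)
  expect_equal(pw$pct_significant[pw$model == "simple" &
                                    pw$coefficient == "b2" & pw$n == 50],
               brute)
})

test_that("power of true coefficients rises with n; overfit falls", {
  g <- parameter_grid(noise_levels = 3, correlations = 0.0001,
                      beta1_values = 0.5, beta2_values = 0.5,
                      beta3_values = -0.5)
  cfg <- experiment_config(grid = g, profile = "desk",
                           population_size = 2e4, reps = 150,
                           sample_sizes = c(25, 100, 1000))
  rec <- run_cell(enumerate_conditions(g), cfg)
  pw <- aggregate_power(rec, 0.05)
  for (co in c("b1", "b2", "b3")) {
    p_by_n <- pw$pct_significant[pw$model == "interaction" &
                                   pw$coefficient == co]
    expect_true(all(diff(p_by_n) >= 0), info = co)
  }
  med_overfit <- tapply(rec$overfit_interaction, rec$n, median)
  expect_true(all(diff(med_overfit) < 0))
})

test_that("no-interaction cells favor the simple model more as n grows", {
  # the population must stay much larger than the biggest sample: when the
  # sampling fraction n/N is non-negligible, the interaction model's
  # spurious product term partially captures realized population noise and
  # the comparison is deflated (see the methods vignette)
  g <- parameter_grid(noise_levels = c(1, 0.65), correlations = c(0.25, 0.0001),
                      beta1_values = c(-1, 1), beta2_values = c(-0.5, 0.5),
                      beta3_values = 0)
  cfg <- experiment_config(grid = g, profile = "desk", population_size = 5e4,
                           reps = 60, sample_sizes = c(25, 500),
                           record_level = "deltas")
  rec <- run_conditions(enumerate_conditions(g), cfg)
  pct_neg <- tapply(rec$delta_r2_p < 0, rec$n, function(v) 100 * mean(v))
  expect_gt(pct_neg[["500"]], pct_neg[["25"]])
})

test_that("run_grid writes coherent artifacts and a manifest", {
  g <- parameter_grid(noise_levels = c(1, 0.65), correlations = 0.25,
                      beta1_values = c(-1, 1), beta2_values = c(-1, 1),
                      beta3_values = c(-0.5, 0, 0.5))
  cfg <- experiment_config(grid = g, profile = "desk", population_size = 2000,
                           reps = 10, sample_sizes = c(25, 100))
  out_dir <- file.path(tempdir(), "grid-out")
  res <- run_grid(cfg, out_dir = out_dir, write_records = TRUE)
  expect_equal(res$manifest$n_cells, 24)
  expect_equal(res$manifest$n_records, 24 * 10 * 2)
  # k bookkeeping equals the combinatorial counts
  ca <- count_analyses(g, reps = 10, sample_sizes = c(25, 100), "shape_noise")
  summ <- res$summary_shape_noise
  for (i in seq_len(nrow(summ))) {
    expect_equal(summ$k[i], ca$k[ca$shape == summ$shape[i] &
                                   ca$lambda == summ$lambda[i]])
  }
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "records.csv")))
  expect_true(file.exists(file.path(out_dir, "summary_shape_n.csv")))
  # determinism end to end: rerun reproduces the summary files byte for byte
  out2 <- file.path(tempdir(), "grid-out-2")
  run_grid(cfg, out_dir = out2, write_records = TRUE)
  for (f in c("records.csv", "summary_shape_noise.csv", "power.csv")) {
    expect_identical(readLines(file.path(out_dir, f)),
                     readLines(file.path(out2, f)))
  }
  unlink(c(out_dir, out2), recursive = TRUE)
})

test_that("f2_survey flags no-interaction cells as nil effects", {
  g <- parameter_grid(noise_levels = 0.65, correlations = c(0.5, 0.0001),
                      beta1_values = c(-1, 1), beta2_values = 1,
                      beta3_values = 0)
  sv <- f2_survey(g, population_size = 5000, seed = 4)
  expect_true(all(sv$per_cell$f2 < 1e-3))
  expect_equal(sv$pct_above_0.5, 0)
})
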