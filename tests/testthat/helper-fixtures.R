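# Shared fixtures: everything is generated in code, no stored data.

# the worked-example configuration (beta1 = beta2 = 1, mu = (1, 2),
# near-zero predictor correlation, lambda = 0.65)
example_spec <- function(beta3 = -1, size = 1e4, lambda = 0.65,
                         r = 0.0001) {
  population_spec(beta0 = 0, beta1 = 1, beta2 = 1, beta3 = beta3,
                  mu_x = 1, mu_z = 2, correlation = r,
                  noise_level = lambda, size = size, cell_id = "fixture")
}

# a quick sample without going through a population: iid draws from the
# generating model, used where the finite-population machinery is not
# under test
quick_sample <- function(n, beta = c(0, 1, 1, -1), lambda = 0.65,
                         r = 0.0001, seed = 1) {
  set.seed(seed)
  x <- 1 + rnorm(n)
  z <- 2 + r * (x - 1) + sqrt(1 - r^2) * rnorm(n)
  ystar <- beta[1] + beta[2] * x + beta[3] * z + beta[4] * x * z
  y <- ystar + rnorm(n, 0, lambda * sd(ystar))
  list(x = x, z = z, y = y, n = n, sample_uid = paste0("quick/", seed))
}

# independent OLS oracle: stats::lm with the model formula
lm_oracle <- function(smp, model, centering = FALSE) {
  x <- smp$x; z <- smp$z
  if (centering) { x <- x - mean(x); z <- z - mean(z) }
  d <- data.frame(y = smp$y, x = x, z = z)
  f <- if (model == "interaction") y ~ x + z + x:z else y ~ x + z
  fit <- lm(f, data = d)
  s <- summary(fit)
  list(coef = unname(coef(fit)), se = unname(s$coefficients[, 2]),
       p = unname(s$coefficients[, 4]), r2 = s$r.squared)
}

# brute-force LOOCV oracle: refit n times, predicting each held-out point
brute_loocv_r2 <- function(smp, model) {
  n <- length(smp$y)
  press <- 0
  for (i in seq_len(n)) {
    d <- data.frame(y = smp$y[-i], x = smp$x[-i], z = smp$z[-i])
    f <- if (model == "interaction") y ~ x + z + x:z else y ~ x + z
    fit <- lm(f, data = d)
    pred <- unname(predict(fit, newdata = data.frame(x = smp$x[i],
                                                     z = smp$z[i])))
    press <- press + (smp$y[i] - pred)^2
  }
  1 - press / sum((smp$y - mean(smp$y))^2)
}

# one tiny condition row in the enumerate_conditions layout
fixture_condition <- function(beta1 = 1, beta2 = 1, beta3 = -1,
                              lambda = 0.65, r = 0.0001,
                              cell_id = "cfix") {
  data.frame(cell_id = cell_id, lambda = lambda, r = r, beta0 = 0,
             beta1 = beta1, beta2 = beta2, beta3 = beta3,
             shape = classify_shape(beta1, beta2, beta3),
             stringsAsFactors = FALSE)
}
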