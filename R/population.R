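#' Noise level from a target population R-squared
#'
#' The error SD is \eqn{\lambda\,\sigma(Y^*)}, so the population R-squared of
#' the correctly specified model is \eqn{1/(1+\lambda^2)}; inverting gives
#' the calibration \eqn{\lambda = \sqrt{1/R^2 - 1}}. The four default grid
#' levels (3.0, 1.53, 1.0, 0.65) target R-squared .1, .3, .5 and .7.
#'
#' @param target_r2 Target population R-squared in (0, 1]; vectorized.
#' @return Noise level(s) \eqn{\lambda \ge 0}.
#' @examples
#' noise_from_r2(c(0.1, 0.3, 0.5, 0.7))
#' @export
noise_from_r2 <- function(target_r2) {
  if (!is.numeric(target_r2) || anyNA(target_r2) ||
      any(target_r2 <= 0) || any(target_r2 > 1))
    stop_domain("target_r2 must lie in (0, 1]")
  sqrt(1 / target_r2 - 1)
}

#' Population R-squared implied by a noise level
#'
#' Algebraic inverse of [noise_from_r2()]: \eqn{R^2 = 1/(1+\lambda^2)}.
#'
#' @param noise_level Noise level \eqn{\lambda \ge 0}; vectorized.
#' @return Population R-squared of the true model.
#' @export
r2_from_noise <- function(noise_level) {
  if (!is.numeric(noise_level) || anyNA(noise_level) || any(noise_level < 0))
    stop_domain("noise_level must be non-negative")
  1 / (1 + noise_level^2)
}

#' Specify the generating parameters of one finite population
#'
#' @param beta0,beta1,beta2,beta3 Regression weights of the generating model
#'   \eqn{Y^* = \beta_0 + \beta_1 X + \beta_2 Z + \beta_3 XZ}.
#' @param mu_x,mu_z Predictor means (defaults 1 and 2).
#' @param sd_x,sd_z Predictor SDs (defaults 1).
#' @param correlation Correlation r(X,Z), strictly inside (-1, 1).
#' @param noise_level Noise level \eqn{\lambda \ge 0} multiplying the
#'   realized \eqn{\sigma(Y^*)}.
#' @param size Population size (at least 2; the full study uses 1e6).
#' @param cell_id Optional identifier carried through to samples/records.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(beta0 = 0, beta1 = 1, beta2 = 1, beta3 = 0,
                            mu_x = 1, mu_z = 2, sd_x = 1, sd_z = 1,
                            correlation = 0.0001, noise_level = 1,
                            size = 1e6, cell_id = NA_character_) {
  for (nm in c("beta0", "beta1", "beta2", "beta3", "mu_x", "mu_z"))
    check_number(get(nm), nm)
  check_number(sd_x, "sd_x", lower = 0, open_lower = TRUE)
  check_number(sd_z, "sd_z", lower = 0, open_lower = TRUE)
  check_number(correlation, "correlation", lower = -1, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(noise_level, "noise_level", lower = 0)
  check_number(size, "size", lower = 2)
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         mu_x = mu_x, mu_z = mu_z, sd_x = sd_x, sd_z = sd_z,
         correlation = correlation, noise_level = noise_level,
         size = as.integer(size), cell_id = cell_id),
    class = "population_spec")
}

#' Build a population spec from one row of [enumerate_conditions()]
#'
#' @param condition A single-row data.frame (or list) with `lambda`, `r`,
#'   `beta0`..`beta3` and optionally `cell_id`.
#' @param grid The [parameter_grid()] supplying predictor means/SDs.
#' @param size Population size.
#' @return A `population_spec`.
#' @export
spec_from_condition <- function(condition, grid = parameter_grid(),
                                size = 1e6) {
  population_spec(beta0 = condition$beta0 %||% grid$beta0,
                  beta1 = condition$beta1, beta2 = condition$beta2,
                  beta3 = condition$beta3,
                  mu_x = grid$mu_x, mu_z = grid$mu_z,
                  sd_x = grid$sd_x, sd_z = grid$sd_z,
                  correlation = condition$r,
                  noise_level = condition$lambda,
                  size = size,
                  cell_id = condition$cell_id %||% NA_character_)
}

#' Generate a finite population under the interaction model
#'
#' X and Z are bivariate normal with the requested means, SDs and
#' correlation (Z is built conditionally on X: \eqn{Z = \mu_z + r\,
#' \sigma_z/\sigma_x (X - \mu_x) + \sigma_z\sqrt{1-r^2}\,W} with independent
#' standard-normal W). The noiseless outcome is \eqn{Y^* = \beta_0 +
#' \beta_1 X + \beta_2 Z + \beta_3 XZ} and noise is drawn with SD
#' \eqn{\lambda\,\sigma(Y^*)}, where \eqn{\sigma(Y^*)} is the realized SD
#' of \eqn{Y^*} in this population, so the signal-to-noise calibration is
#' exact for the finite population at hand.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; generation is fully deterministic given the
#'   seed (no implicit global randomness).
#' @return An object of class `population`: list with `x`, `z`, `y`,
#'   `y_star`, `realized_sd_ystar`, `realized_moments` and the `spec`.
#' @export
generate_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  check_number(seed, "seed")
  n <- spec$size
  r <- spec$correlation
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  x <- spec$mu_x + spec$sd_x * rnorm(n)
  z <- spec$mu_z + spec$sd_z * (r * (x - spec$mu_x) / spec$sd_x +
                                  sqrt(1 - r^2) * rnorm(n))
  y_star <- spec$beta0 + spec$beta1 * x + spec$beta2 * z + spec$beta3 * x * z
  sd_ystar <- sd(y_star)
  eps_sd <- spec$noise_level * sd_ystar
  y <- y_star + if (eps_sd > 0) rnorm(n, 0, eps_sd) else 0
  structure(
    list(x = x, z = z, y = y, y_star = y_star,
         realized_sd_ystar = sd_ystar,
         realized_moments = list(
           mean_x = mean(x), mean_z = mean(z), sd_x = sd(x), sd_z = sd(z),
           cor_xz = cor(x, z), mean_y = mean(y), sd_y = sd(y)),
         spec = spec, seed = as.integer(seed)),
    class = "population")
}

#' @export
print.population <- function(x, ...) {
  s <- x$spec
  cat("<population> N =", s$size, "\n")
  cat(sprintf("  betas = (%g, %g, %g, %g), lambda = %g, r = %g\n",
              s$beta0, s$beta1, s$beta2, s$beta3, s$noise_level,
              s$correlation))
  m <- x$realized_moments
  cat(sprintf("  realized: mean(x) = %.3f, mean(z) = %.3f, cor(x,z) = %.4f, sd(y*) = %.3f\n",
              m$mean_x, m$mean_z, m$cor_xz, x$realized_sd_ystar))
  invisible(x)
}

#' Draw a simple random sample (without replacement) from a population
#'
#' @param population A [generate_population()] result.
#' @param n Sample size, 2 < n <= population size. The interaction model
#'   needs n > 4 to be estimable downstream.
#' @param seed Integer seed for the draw; deterministic given the seed.
#' @param replicate_index Optional replicate label carried into records.
#' @return An object of class `interaction_sample`: list with `x`, `z`,
#'   `y`, `n`, `indices`, `parent_cell_id`, `replicate_index` and a
#'   `sample_uid` used to guard against mixing fits from different samples.
#' @export
draw_sample <- function(population, n, seed, replicate_index = NA_integer_) {
  stopifnot(inherits(population, "population"))
  npop <- population$spec$size
  check_number(n, "n", lower = 3, upper = npop)
  check_number(seed, "seed")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  idx <- sample.int(npop, n, replace = FALSE)
  structure(
    list(x = population$x[idx], z = population$z[idx],
         y = population$y[idx], n = as.integer(n), indices = idx,
         parent_cell_id = population$spec$cell_id,
         replicate_index = as.integer(replicate_index),
         sample_uid = paste(population$spec$cell_id, n,
                            replicate_index, seed, sep = "/")),
    class = "interaction_sample")
}
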