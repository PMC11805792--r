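#' Closed-form expected coefficients of the misspecified simple-effects model
#'
#' When the data-generating mechanism contains an interaction
#' (\eqn{\beta_3 \neq 0}) but the fitted model omits the product term, the
#' population-level (and statistically expected) coefficients of the
#' misspecified model are, for unit-SD predictors:
#' \deqn{b_{e0} = \beta_0 - \beta_3\mu_z\mu_x + \beta_3 r_{xz}}
#' \deqn{b_{e1} = \beta_1 + \beta_3\mu_z}
#' \deqn{b_{e2} = \beta_2 + \beta_3\mu_x}
#' with biases \eqn{B_n = b_{en} - \beta_n}. The r term is the covariance of
#' X and Z, which equals the correlation under unit SDs; the implementation
#' therefore refuses non-unit predictor SDs rather than silently
#' generalizing the printed formulas.
#'
#' Expected coefficients can be exactly 0 (an existing simple effect becomes
#' undetectable) or flip sign relative to the true weight; both situations
#' are flagged. Flags use exact arithmetic comparison, which is appropriate
#' on the quarter-step beta grid.
#'
#' @param spec A [population_spec()] with `sd_x = sd_z = 1`.
#' @return An object of class `expected_estimates`: list with `b_e`
#'   (named `b_e0`, `b_e1`, `b_e2`), `bias` (named `B0`, `B1`, `B2`),
#'   `cancellation_flags` and `sign_flip_flags` (logical, for `b_e1` and
#'   `b_e2`).
#' @examples
#' s <- population_spec(beta1 = 1, beta2 = 1, beta3 = -1,
#'                      correlation = 0.0001, noise_level = 0.65)
#' expected_misspecified(s)$b_e  # (1.9999, -1, 0): b2 cancelled, b1 flipped
#' @export
expected_misspecified <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$sd_x != 1 || spec$sd_z != 1)
    stop_domain("expected_misspecified supports unit predictor SDs only ",
                "(the closed-form results assume sd_x = sd_z = 1)")
  b3 <- spec$beta3
  b_e0 <- spec$beta0 - b3 * spec$mu_z * spec$mu_x + b3 * spec$correlation
  b_e1 <- spec$beta1 + b3 * spec$mu_z
  b_e2 <- spec$beta2 + b3 * spec$mu_x
  b_e <- c(b_e0 = b_e0, b_e1 = b_e1, b_e2 = b_e2)
  bias <- c(B0 = b_e0 - spec$beta0, B1 = b_e1 - spec$beta1,
            B2 = b_e2 - spec$beta2)
  structure(
    list(b_e = b_e, bias = bias,
         cancellation_flags = c(b_e1 = b_e1 == 0, b_e2 = b_e2 == 0),
         sign_flip_flags = c(b_e1 = sign(b_e1) == -sign(spec$beta1) & b_e1 != 0,
                             b_e2 = sign(b_e2) == -sign(spec$beta2) & b_e2 != 0),
         spec = spec),
    class = "expected_estimates")
}

#' @export
print.expected_estimates <- function(x, ...) {
  cat("<expected_estimates> misspecified simple-effects model\n")
  print(round(rbind(expected = x$b_e, bias = setNames(x$bias, names(x$b_e))), 4))
  if (any(x$cancellation_flags))
    cat("  cancelled to 0:",
        paste(names(which(x$cancellation_flags)), collapse = ", "), "\n")
  if (any(x$sign_flip_flags))
    cat("  sign flipped:",
        paste(names(which(x$sign_flip_flags)), collapse = ", "), "\n")
  invisible(x)
}

#' Interaction weights at which a misspecified simple effect vanishes
#'
#' The expected misspecified coefficients are linear in \eqn{\beta_3}, so
#' each simple effect has (at most) one tipping point:
#' \eqn{b_{e1} = 0} at \eqn{\beta_3 = -\beta_1/\mu_z} and
#' \eqn{b_{e2} = 0} at \eqn{\beta_3 = -\beta_2/\mu_x}. With the default
#' means (1, 2) and \eqn{\beta_1 = \beta_2 = 1} these are -0.5 and -1.
#' A zero mean makes the corresponding coefficient independent of
#' \eqn{\beta_3}; the tipping point is then reported as `NA` (absent).
#'
#' @param spec A [population_spec()].
#' @return List with `beta3_b1_zero` and `beta3_b2_zero` (each `NA` when
#'   absent).
#' @export
tipping_points <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  list(beta3_b1_zero = if (spec$mu_z != 0) -spec$beta1 / spec$mu_z else NA_real_,
       beta3_b2_zero = if (spec$mu_x != 0) -spec$beta2 / spec$mu_x else NA_real_)
}

#' Residual structure of the misspecified model on a population
#'
#' Splits the generating process into a part explainable by X and Z alone
#' and the leftover part \eqn{Y(XZ) = \beta_3 XZ + \epsilon}. Regressing
#' \eqn{Y(XZ)} on (1, X, Z) gives fitted values \eqn{a + bX + cZ}; unless
#' \eqn{a + bX + cZ - \beta_3 XZ = 0}, the residuals of the misspecified
#' model are neither independent of the predictors' product nor
#' homoscedastic. Two scalar diagnostics operationalize this:
#' `dependence_index`, the absolute correlation between the residual series
#' and XZ, and `heteroscedasticity_index`, the ratio of residual variances
#' in the top vs. bottom quartile of XZ. Under no interaction and
#' independent noise the indices are approximately 0 and 1; as the noise
#' level grows the well-behaved \eqn{\epsilon} dominates and both indices
#' approach those null values.
#'
#' @param population A [generate_population()] result.
#' @param spec The generating spec (defaults to the one stored in the
#'   population).
#' @return An object of class `residual_decomposition`: list with `a`, `b`,
#'   `c`, `residual_series`, `heteroscedasticity_index`,
#'   `dependence_index`.
#' @export
residual_structure <- function(population, spec = population$spec) {
  stopifnot(inherits(population, "population"))
  x <- population$x; z <- population$z
  eps <- population$y - population$y_star
  y_xz <- spec$beta3 * x * z + eps
  core <- ols_qr(cbind(1, x, z), y_xz, context = "residual_structure")
  res <- core$residuals
  xz <- x * z
  qs <- quantile(xz, c(0.25, 0.75))
  het <- var(res[xz >= qs[[2]]]) / var(res[xz <= qs[[1]]])
  dep <- if (sd(res) == 0) 0 else abs(cor(res, xz))
  structure(
    list(a = core$coefficients[1], b = core$coefficients[2],
         c = core$coefficients[3], residual_series = res,
         heteroscedasticity_index = het, dependence_index = dep),
    class = "residual_decomposition")
}
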