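#' Define the simulation parameter grid
#'
#' The default grid is the full factorial design of the study: four noise
#' levels \eqn{\lambda} targeting population R-squared values of .1, .3, .5
#' and .7; four predictor correlations; simple-effect weights \eqn{\beta_1}
#' and \eqn{\beta_2} from -1 to 1 in steps of 0.25 excluding 0; and the
#' interaction weight \eqn{\beta_3} on the same grid including 0 (no
#' interaction). Predictor means are 1 (X) and 2 (Z) with unit SDs.
#'
#' @param noise_levels Numeric vector of noise levels \eqn{\lambda}
#'   (unitless multipliers of \eqn{\sigma(Y^*)}). The default stores the
#'   printed two-decimal values; see `strict_calibration`.
#' @param correlations Numeric vector of predictor correlations r(X,Z),
#'   each in (-1, 1).
#' @param beta1_values,beta2_values Numeric vectors of simple-effect
#'   weights; 0 is not allowed.
#' @param beta3_values Numeric vector of interaction weights; may include 0.
#' @param beta0 Intercept, fixed at 0 in the default study.
#' @param mu_x,mu_z Predictor means.
#' @param sd_x,sd_z Predictor SDs (fixed at 1; the closed-form bias results
#'   assume unit SDs).
#' @param strict_calibration If `TRUE`, replace the default printed noise
#'   levels by the exact calibration \eqn{\sqrt{1/R^2 - 1}} for target
#'   R-squared .1, .3, .5, .7 (only the .3 level differs: 1.5275... instead
#'   of the printed 1.53). Ignored when `noise_levels` is supplied.
#' @return An object of class `parameter_grid`.
#' @seealso [enumerate_conditions()], [count_analyses()]
#' @examples
#' g <- parameter_grid()
#' nrow(enumerate_conditions(g)) # 9216
#' @export
parameter_grid <- function(noise_levels = c(3.0, 1.53, 1.0, 0.65),
                           correlations = c(0.75, 0.5, 0.25, 0.0001),
                           beta1_values = setdiff(seq(-1, 1, by = 0.25), 0),
                           beta2_values = setdiff(seq(-1, 1, by = 0.25), 0),
                           beta3_values = seq(-1, 1, by = 0.25),
                           beta0 = 0,
                           mu_x = 1, mu_z = 2,
                           sd_x = 1, sd_z = 1,
                           strict_calibration = FALSE) {
  check_flag(strict_calibration, "strict_calibration")
  if (strict_calibration && missing(noise_levels))
    noise_levels <- noise_from_r2(c(0.1, 0.3, 0.5, 0.7))
  dims <- list(noise_levels = noise_levels, correlations = correlations,
               beta1_values = beta1_values, beta2_values = beta2_values,
               beta3_values = beta3_values)
  for (nm in names(dims)) {
    v <- dims[[nm]]
    if (!is.numeric(v) || length(v) == 0L || anyNA(v))
      stop_config("grid dimension '", nm, "' must be a non-empty numeric vector")
    if (anyDuplicated(v))
      stop_config("grid dimension '", nm, "' contains duplicated values")
  }
  if (any(beta1_values == 0) || any(beta2_values == 0))
    stop_config("beta1_values and beta2_values must not contain 0 ",
                "(simple effects are always present in the design)")
  if (any(noise_levels < 0))
    stop_config("noise_levels must be non-negative")
  if (any(abs(correlations) >= 1))
    stop_config("correlations must lie strictly inside (-1, 1)")
  check_number(beta0, "beta0")
  check_number(mu_x, "mu_x"); check_number(mu_z, "mu_z")
  check_number(sd_x, "sd_x", lower = 0, open_lower = TRUE)
  check_number(sd_z, "sd_z", lower = 0, open_lower = TRUE)
  structure(
    list(noise_levels = as.numeric(noise_levels),
         correlations = as.numeric(correlations),
         beta1_values = as.numeric(beta1_values),
         beta2_values = as.numeric(beta2_values),
         beta3_values = as.numeric(beta3_values),
         beta0 = beta0, mu_x = mu_x, mu_z = mu_z, sd_x = sd_x, sd_z = sd_z),
    class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat("<parameter_grid>\n")
  cat("  noise levels (lambda):", paste(x$noise_levels, collapse = ", "), "\n")
  cat("  correlations r(X,Z):  ", paste(x$correlations, collapse = ", "), "\n")
  cat("  beta1:", paste(x$beta1_values, collapse = ", "), "\n")
  cat("  beta2:", paste(x$beta2_values, collapse = ", "), "\n")
  cat("  beta3:", paste(x$beta3_values, collapse = ", "), "\n")
  cat("  mu_x =", x$mu_x, " mu_z =", x$mu_z,
      " sd_x =", x$sd_x, " sd_z =", x$sd_z, " beta0 =", x$beta0, "\n")
  cat("  conditions:", length(x$noise_levels) * length(x$correlations) *
        length(x$beta1_values) * length(x$beta2_values) *
        length(x$beta3_values), "\n")
  invisible(x)
}

#' Classify the shape of an interaction from the signs of the weights
#'
#' Shapes follow the whole-model typology, which needs no designated
#' moderator and uses signs only:
#' \itemize{
#'   \item `none` — \eqn{\beta_3 = 0};
#'   \item `synergistic` — \eqn{\beta_1}, \eqn{\beta_2}, \eqn{\beta_3} all
#'     share one sign;
#'   \item `buffering` — the simple effects \eqn{\beta_1} and \eqn{\beta_2}
#'     have opposing signs (and \eqn{\beta_3 \neq 0});
#'   \item `antagonistic` — the simple effects share a sign opposed by
#'     \eqn{\beta_3}.
#' }
#'
#' @param beta1,beta2,beta3 Regression weights; vectors are recycled to a
#'   common length. `beta1` and `beta2` must be non-zero.
#' @return Character vector with values in
#'   `c("none", "synergistic", "buffering", "antagonistic")`.
#' @examples
#' classify_shape(1, 1, 1)   # synergistic
#' classify_shape(1, -1, 1)  # buffering
#' classify_shape(1, 1, -1)  # antagonistic
#' @export
classify_shape <- function(beta1, beta2, beta3) {
  n <- max(length(beta1), length(beta2), length(beta3))
  beta1 <- rep_len(beta1, n); beta2 <- rep_len(beta2, n)
  beta3 <- rep_len(beta3, n)
  if (any(beta1 == 0) || any(beta2 == 0))
    stop_domain("classify_shape: beta1 and beta2 must be non-zero ",
                "(the shape typology is undefined without both simple effects)")
  s1 <- sign(beta1); s2 <- sign(beta2); s3 <- sign(beta3)
  out <- rep("buffering", n)
  out[s3 == 0] <- "none"
  out[s1 == s2 & s2 == s3] <- "synergistic"
  out[s1 == s2 & s3 != 0 & s1 != s3] <- "antagonistic"
  out
}

#' Enumerate all simulation conditions of a grid
#'
#' Forms the Cartesian product of the five grid dimensions in a fixed
#' lexicographic order (noise level descending, correlation descending,
#' beta1/beta2/beta3 ascending) and assigns a stable `cell_id` to each
#' condition.
#'
#' @param grid A [parameter_grid()].
#' @return A data.frame with one row per condition and columns `cell_id`,
#'   `lambda`, `r`, `beta0`, `beta1`, `beta2`, `beta3`, `shape`.
#' @export
enumerate_conditions <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  conds <- expand.grid(
    beta3 = sort(grid$beta3_values),
    beta2 = sort(grid$beta2_values),
    beta1 = sort(grid$beta1_values),
    r = sort(grid$correlations, decreasing = TRUE),
    lambda = sort(grid$noise_levels, decreasing = TRUE),
    KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; reorder columns so the
  # slowest-varying key (lambda) comes first, matching the documented order
  conds <- conds[, c("lambda", "r", "beta1", "beta2", "beta3")]
  conds$beta0 <- grid$beta0
  conds$shape <- classify_shape(conds$beta1, conds$beta2, conds$beta3)
  conds$cell_id <- sprintf("c%05d", seq_len(nrow(conds)))
  rownames(conds) <- NULL
  conds[, c("cell_id", "lambda", "r", "beta0", "beta1", "beta2", "beta3",
            "shape")]
}

#' Exact analysis counts per interaction-shape group
#'
#' Pure combinatorics, no simulation: the number of fitted analyses k in a
#' group equals (number of conditions in the group) x (replicates) x
#' (number of sample sizes). With the default grid, 1000 replicates and six
#' sample sizes this reproduces the k bookkeeping of the study's summary
#' tables (per noise level: synergistic 3,072,000; antagonistic 3,072,000;
#' buffering 6,144,000; none 1,536,000).
#'
#' @param grid A [parameter_grid()].
#' @param reps Number of replicate samples per condition and sample size.
#' @param sample_sizes Vector of sample sizes.
#' @param group_by `"shape_noise"` (one row per shape x noise level,
#'   pooling all sample sizes: k = conditions x reps x |sample_sizes|) or
#'   `"shape_n"` (one row per shape x sample size, pooling noise levels:
#'   k = conditions x reps).
#' @return A data.frame with the group keys, `n_conditions` and `k`.
#' @export
count_analyses <- function(grid, reps, sample_sizes,
                           group_by = c("shape_noise", "shape_n")) {
  group_by <- match.arg(group_by)
  check_number(reps, "reps", lower = 1)
  if (length(sample_sizes) < 1L || !is.numeric(sample_sizes))
    stop_config("sample_sizes must be a non-empty numeric vector")
  conds <- enumerate_conditions(grid)
  if (group_by == "shape_noise") {
    agg <- as.data.frame(table(shape = conds$shape, lambda = conds$lambda),
                         stringsAsFactors = FALSE)
    names(agg)[names(agg) == "Freq"] <- "n_conditions"
    agg$lambda <- as.numeric(agg$lambda)
    agg <- agg[agg$n_conditions > 0, , drop = FALSE]
    agg$k <- agg$n_conditions * reps * length(sample_sizes)
    agg <- agg[order(agg$shape, -agg$lambda), , drop = FALSE]
  } else {
    tab <- as.data.frame(table(shape = conds$shape), stringsAsFactors = FALSE)
    names(tab)[names(tab) == "Freq"] <- "n_conditions"
    agg <- merge(tab, data.frame(n = sort(as.numeric(sample_sizes))))
    agg$k <- agg$n_conditions * reps
    agg <- agg[order(agg$shape, agg$n), c("shape", "n", "n_conditions", "k")]
  }
  rownames(agg) <- NULL
  agg
}
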