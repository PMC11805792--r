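# OLS engine for the two competing models. The solver is QR (via
# .lm.fit / LINPACK) on the main path; the normal equations are never
# inverted explicitly here because r(X,Z) up to 0.75 plus a product term
# stresses conditioning.

coef_names <- function(model) {
  if (model == "interaction") c("b0", "b1", "b2", "b3") else c("b0", "b1", "b2")
}

# Build the design matrix for a model; centering subtracts the *sample*
# means of x and z before forming the product (and the linear columns).
build_design <- function(x, z, model, centering) {
  cx <- 0; cz <- 0
  if (centering) { cx <- mean(x); cz <- mean(z) }
  xc <- x - cx; zc <- z - cz
  M <- if (model == "interaction") cbind(1, xc, zc, xc * zc) else cbind(1, xc, zc)
  list(M = M, center_x = cx, center_z = cz)
}

# Core QR least squares with classical inference. Returns NULL-safe pieces
# used by both the user-facing fit and the fast experiment loop.
ols_qr <- function(M, y, context = NULL) {
  p <- ncol(M)
  n <- nrow(M)
  fit <- .lm.fit(M, y)
  if (fit$rank < p)
    stop_domain("rank-deficient design matrix (rank ", fit$rank, " < ", p,
                ")", if (!is.null(context)) paste0(" [", context, "]"))
  piv <- fit$pivot
  beta <- numeric(p); beta[piv] <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  R <- fit$qr[seq_len(p), , drop = FALSE]
  R[lower.tri(R)] <- 0
  xtx_inv_p <- chol2inv(R)
  xtx_diag <- numeric(p); xtx_diag[piv] <- diag(xtx_inv_p)
  df <- n - p
  sigma2 <- sse / df
  se <- sqrt(sigma2 * xtx_diag)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  sst <- sum((y - mean(y))^2)
  list(coefficients = beta, se = se, p_values = pval, df = df,
       sse = sse, sst = sst, r2 = 1 - sse / sst, residuals = res)
}

#' Fit a simple-effects or interaction model by ordinary least squares
#'
#' Fits `y ~ x + z` (simple-effects model, the misspecified one when a true
#' interaction exists) or `y ~ x + z + x:z` (interaction model) with an
#' intercept, by QR least squares. Standard errors are classical
#' (\eqn{\hat\sigma^2 (X^\top X)^{-1}} with \eqn{\hat\sigma^2 = SSE/(n-p)}),
#' p values are two-sided from the t distribution with n - p degrees of
#' freedom, and the sample R-squared is \eqn{1 - SSE/SST} with SST about
#' the sample mean of y.
#'
#' @param sample An [draw_sample()] result (or any list with numeric `x`,
#'   `z`, `y` of equal length).
#' @param model `"interaction"` or `"simple"`.
#' @param centering If `TRUE`, mean-center x and z before forming the
#'   product term. Centering changes the intercept and simple-effect
#'   coefficients (and their SEs) but neither the interaction estimate, its
#'   SE, nor the R-squared.
#' @return An object of class `fit_result` with elements `coefficients`,
#'   `standard_errors`, `p_values` (all named `b0`, `b1`, `b2`[, `b3`]),
#'   `r2_sample`, `n`, `df`, `model`, `centering`, `center_x`, `center_z`,
#'   `sample_uid`.
#' @export
fit_ols <- function(sample, model = c("interaction", "simple"),
                    centering = FALSE) {
  model <- match.arg(model)
  check_flag(centering, "centering")
  x <- sample$x; z <- sample$z; y <- sample$y
  n <- length(y)
  stopifnot(length(x) == n, length(z) == n)
  p <- if (model == "interaction") 4L else 3L
  if (n <= p)
    stop_domain("n = ", n, " is too small to fit the ", model,
                " model (needs n > ", p, ")")
  d <- build_design(x, z, model, centering)
  ctx <- sample$sample_uid %||% NULL
  core <- ols_qr(d$M, y, context = ctx)
  nm <- coef_names(model)
  structure(
    list(coefficients = setNames(core$coefficients, nm),
         standard_errors = setNames(core$se, nm),
         p_values = setNames(core$p_values, nm),
         r2_sample = core$r2, n = n, df = core$df,
         model = model, centering = centering,
         center_x = d$center_x, center_z = d$center_z,
         sample_uid = sample$sample_uid %||% NA_character_),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model, "model",
      if (x$centering) "(mean-centered)" else "(uncentered)",
      " n =", x$n, "\n")
  tab <- cbind(estimate = x$coefficients, se = x$standard_errors,
               p = x$p_values)
  print(round(tab, 4))
  cat("R2(s) =", format(x$r2_sample, digits = 4), "\n")
  invisible(x)
}

#' Compare centered and uncentered parameterizations of the interaction fit
#'
#' Mean centering is often recommended against the collinearity introduced
#' by the product term, but it is a pure reparameterization: the interaction
#' estimate, its standard error, and the model R-squared are identical;
#' only the intercept and simple-effect coefficients change meaning.
#'
#' @param sample A sample as for [fit_ols()].
#' @return A list with `b3_uncentered`, `b3_centered`, `se_b3_uncentered`,
#'   `se_b3_centered`, `r2_uncentered`, `r2_centered`, and the two full
#'   `fit_result` objects.
#' @export
compare_centered <- function(sample) {
  fu <- fit_ols(sample, "interaction", centering = FALSE)
  fc <- fit_ols(sample, "interaction", centering = TRUE)
  list(b3_uncentered = unname(fu$coefficients["b3"]),
       b3_centered = unname(fc$coefficients["b3"]),
       se_b3_uncentered = unname(fu$standard_errors["b3"]),
       se_b3_centered = unname(fc$standard_errors["b3"]),
       r2_uncentered = fu$r2_sample,
       r2_centered = fc$r2_sample,
       fit_uncentered = fu, fit_centered = fc)
}

#' Sample R-squared change from adding the interaction term
#'
#' \eqn{\Delta R^2(s) = R^2(s)_{interaction} - R^2(s)_{simple}}; non-negative
#' by nesting. Both fits must come from the same sample.
#'
#' @param fit_simple A `fit_result` for the simple-effects model.
#' @param fit_interaction A `fit_result` for the interaction model.
#' @return The scalar \eqn{\Delta R^2(s)}.
#' @export
r2_change <- function(fit_simple, fit_interaction) {
  stopifnot(inherits(fit_simple, "fit_result"),
            inherits(fit_interaction, "fit_result"))
  if (fit_simple$model != "simple" || fit_interaction$model != "interaction")
    stop_domain("r2_change expects (simple, interaction) fits in that order")
  if (!identical(fit_simple$sample_uid, fit_interaction$sample_uid))
    stop_domain("fits come from different samples (",
                fit_simple$sample_uid, " vs ", fit_interaction$sample_uid, ")")
  fit_interaction$r2_sample - fit_simple$r2_sample
}

# Map a (possibly centered) fitted coefficient vector onto the uncentered
# basis (1, x, z, xz), so population predictions can reuse one precomputed
# design. Exact algebra: with centers (cx, cz),
#   b0 + b1(x-cx) + b2(z-cz) + b3(x-cx)(z-cz)
#     = (b0 - b1 cx - b2 cz + b3 cx cz) + (b1 - b3 cz) x + (b2 - b3 cx) z
#       + b3 xz.
uncentered_coefficients <- function(fit) {
  b <- fit$coefficients
  cx <- fit$center_x; cz <- fit$center_z
  if (fit$model == "interaction") {
    c(b[["b0"]] - b[["b1"]] * cx - b[["b2"]] * cz + b[["b3"]] * cx * cz,
      b[["b1"]] - b[["b3"]] * cz,
      b[["b2"]] - b[["b3"]] * cx,
      b[["b3"]])
  } else {
    c(b[["b0"]] - b[["b1"]] * cx - b[["b2"]] * cz, b[["b1"]], b[["b2"]], 0)
  }
}
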