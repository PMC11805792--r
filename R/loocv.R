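#' Leave-one-out cross-validated R-squared (PRESS R-squared)
#'
#' A practical proxy for the population R-squared when the population is
#' unavailable. Uses the closed-form leave-one-out identity: the prediction
#' error for observation i from the model fitted without it equals the
#' ordinary residual inflated by \eqn{1/(1 - h_{ii})}, where \eqn{h_{ii}}
#' is the leverage. Then \eqn{PRESS = \sum_i (e_i/(1-h_{ii}))^2} and
#' \eqn{R^2_{cv} = 1 - PRESS/SST} with SST about the full-sample mean of y
#' (the standard PRESS R-squared convention, which makes
#' \eqn{R^2_{cv} \le R^2(s)} provable since \eqn{PRESS \ge SSE}).
#' Negative values indicate a model that predicts held-out points worse
#' than the sample mean — strong overfitting.
#'
#' @param sample A sample as for [fit_ols()].
#' @param model `"interaction"` or `"simple"`.
#' @param centering Mean-center before forming the product term (does not
#'   change the result beyond numerical noise, as for R-squared).
#' @return An object of class `loocv_result`: list with `r2_cv`, `press`,
#'   `leverages`.
#' @export
loocv_r2 <- function(sample, model = c("interaction", "simple"),
                     centering = FALSE) {
  model <- match.arg(model)
  check_flag(centering, "centering")
  x <- sample$x; z <- sample$z; y <- sample$y
  n <- length(y)
  p <- if (model == "interaction") 4L else 3L
  if (n <= p + 1L)
    stop_domain("loocv_r2 needs n > ", p + 1L, " for the ", model, " model")
  d <- build_design(x, z, model, centering)
  qrX <- qr(d$M)
  if (qrX$rank < p)
    stop_domain("rank-deficient design matrix in loocv_r2")
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  if (any(h >= 1 - 1e-10))
    stop_domain("leverage of 1 at observation ",
                paste(which(h >= 1 - 1e-10), collapse = ", "),
                ": leave-one-out prediction is undefined there")
  res <- y - d$M %*% qr.coef(qrX, y)
  press <- sum((res / (1 - h))^2)
  sst <- sum((y - mean(y))^2)
  structure(list(r2_cv = 1 - press / sst, press = press, leverages = h),
            class = "loocv_result")
}
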