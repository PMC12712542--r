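# Minimal OLS ------------------------------------------------------------
#
# The pipeline's regressions go through this small, self-contained
# fitter. It solves the least-squares problem by QR decomposition (never
# by inverting X'X), because the perfect-fit demonstration drives
# residuals to machine zero, where normal equations lose digits.
# Standard errors are classical: sigma^2 (X'X)^{-1} with
# sigma^2 = SSE / (n - p), obtained from the R factor.

#' Ordinary least squares with coefficient standard errors and R-squared
#'
#' @param response Numeric response vector.
#' @param predictors Named list of numeric predictor vectors (or a data
#'   frame); names become coefficient names.
#' @param include_intercept Include an intercept term (default `TRUE`).
#' @return An object of class `regression_fit`: a list with
#'   `coefficients` and `standard_errors` (named numeric vectors, first
#'   term `"(intercept)"` when included), `r_squared`, `n_obs`,
#'   `residuals`, and `sigma` (residual SD).
#' @examples
#' fit <- ols_fit(c(1, 2, 2, 3), list(x = 1:4))
#' fit$coefficients
#' @export
ols_fit <- function(response, predictors, include_intercept = TRUE) {
  y <- as.numeric(response)
  if (is.data.frame(predictors)) predictors <- as.list(predictors)
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  X <- do.call(cbind, lapply(predictors, as.numeric))
  if (nrow(X) != length(y)) {
    stop("response and predictors differ in length", call. = FALSE)
  }
  if (anyNA(y) || anyNA(X)) stop("NA values in regression input",
                                 call. = FALSE)
  terms <- colnames(X)
  if (include_intercept) {
    X <- cbind("(intercept)" = 1, X)
    terms <- c("(intercept)", terms)
  }
  n <- length(y); p <- ncol(X)
  if (n < p) {
    stop(sprintf("need at least as many observations (%d) as terms (%d)",
                 n, p), call. = FALSE)
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    stop("singular design: predictors are collinear", call. = FALSE)
  }
  coef <- qr.coef(qr_x, y)
  res <- as.numeric(y - X %*% coef)
  sse <- sum(res^2)
  sst <- if (include_intercept) sum((y - mean(y))^2) else sum(y^2)
  # saturated fits (n == p) have no residual df: SEs are undefined (NaN)
  sigma2 <- if (n > p) sse / (n - p) else NaN
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- if (is.nan(sigma2)) rep(NaN, p) else
    sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(coef) <- names(se) <- terms
  structure(
    list(coefficients = coef, standard_errors = se,
         r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
         n_obs = n, residuals = res, sigma = sqrt(sigma2)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> n = %d, R^2 = %.6g\n", x$n_obs,
              x$r_squared))
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors)
  print(tab, ...)
  invisible(x)
}
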