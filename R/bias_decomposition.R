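# Covariance decomposition of the aggregation-order bias ----------------
#
# Let x, y be the species-level trait values under one aggregation order
# (the reference, by default transform-then-aggregate) and x*, y* the
# values under the other order. With bias vectors
#
#   theta = x - x*,   omega = y - y*,
#
# the slope of the starred regression decomposes exactly into
# covariance components of the reference values and the biases:
#
#   b(x*, y*) = cov(x*, y*) / var(x*)
#             = [cov(x,y) - cov(x,omega) - cov(theta,y) + cov(theta,omega)]
#               / [var(x) + var(theta) - 2 cov(x,theta)]
#
# and analogously for the Pearson correlation. The identity is algebra,
# not approximation, and holds under any common covariance divisor.
# Note the signs: with theta defined as x - x*, the starred vector is
# x* = x - theta, so the cross terms enter with minus signs; writing
# them with plus signs corresponds to the opposite sign convention for
# the bias (theta = x* - x). The decomposition shows that the slope
# difference between orders depends only on the variance-covariance
# structure of (x, y, theta, omega) -- a constant (mean) bias shifts
# nothing.

#' Bias vectors between two aggregation orders
#'
#' @param x,y Reference species-level values (same length, aligned by
#'   species).
#' @param x_star,y_star Species-level values under the other order.
#' @return A list with elements `theta = x - x_star` and
#'   `omega = y - y_star`.
#' @export
bias_vectors <- function(x, x_star, y, y_star) {
  n <- length(x)
  if (length(x_star) != n || length(y) != n || length(y_star) != n) {
    stop("all four vectors must have the same length", call. = FALSE)
  }
  list(theta = x - x_star, omega = y - y_star)
}

# shared engine: components + direct and reconstructed statistics
.decompose <- function(x, y, theta, omega, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  n <- length(x)
  if (length(y) != n || length(theta) != n || length(omega) != n) {
    stop("x, y, theta, omega must have the same length", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 species", call. = FALSE)
  cv <- function(a, b) {
    s <- sum((a - mean(a)) * (b - mean(b)))
    s / if (divisor == "n-1") (n - 1) else n
  }
  x_star <- x - theta
  y_star <- y - omega
  comp <- list(
    cov_xy = cv(x, y), cov_x_omega = cv(x, omega),
    cov_theta_y = cv(theta, y), cov_theta_omega = cv(theta, omega),
    var_x = cv(x, x), var_theta = cv(theta, theta),
    cov_x_theta = cv(x, theta),
    var_y = cv(y, y), var_omega = cv(omega, omega),
    cov_y_omega = cv(y, omega))
  num <- comp$cov_xy - comp$cov_x_omega - comp$cov_theta_y +
    comp$cov_theta_omega
  den_x <- comp$var_x + comp$var_theta - 2 * comp$cov_x_theta
  den_y <- comp$var_y + comp$var_omega - 2 * comp$cov_y_omega
  if (den_x <= 0) stop("degenerate regressor: var(x*) is zero",
                       call. = FALSE)
  structure(
    c(comp, list(
      divisor = divisor,
      slope_unbiased = comp$cov_xy / comp$var_x,
      corr_unbiased = comp$cov_xy / sqrt(comp$var_x * comp$var_y),
      slope_direct = cv(x_star, y_star) / cv(x_star, x_star),
      slope_reconstructed = num / den_x,
      corr_direct = if (den_y > 0) {
        cv(x_star, y_star) / sqrt(cv(x_star, x_star) * cv(y_star, y_star))
      } else NA_real_,
      corr_reconstructed = if (den_y > 0) num / sqrt(den_x * den_y)
                           else NA_real_)),
    class = "bias_decomposition")
}

#' Exact slope decomposition between aggregation orders
#'
#' Computes the ten covariance/variance components, the slope of the
#' reference regression (`slope_unbiased`), the directly computed slope
#' on the starred values (`slope_direct`), and the same slope
#' reconstructed from the components (`slope_reconstructed`); the last
#' two agree to floating-point precision.
#'
#' @param x,y Reference species-level values (length >= 3).
#' @param theta,omega Bias vectors (`x - x_star`, `y - y_star`).
#' @param divisor Covariance divisor, `"n-1"` (default, matching OLS
#'   conventions) or `"n"`; the identity holds for either.
#' @return A `bias_decomposition` object (a named list).
#' @export
slope_decomposition <- function(x, y, theta, omega, divisor = c("n-1", "n")) {
  .decompose(x, y, theta, omega, divisor)
}

#' Exact correlation decomposition between aggregation orders
#'
#' Same engine as [slope_decomposition()]; returned object carries
#' `corr_direct` (Pearson correlation of the starred values) and
#' `corr_reconstructed` (the component ratio), which agree to
#' floating-point precision. Requires positive variance of both starred
#' vectors.
#'
#' @inheritParams slope_decomposition
#' @return A `bias_decomposition` object.
#' @export
correlation_decomposition <- function(x, y, theta, omega,
                                      divisor = c("n-1", "n")) {
  d <- .decompose(x, y, theta, omega, divisor)
  if (is.na(d$corr_direct)) {
    stop("degenerate response: var(y*) is zero", call. = FALSE)
  }
  d
}

#' @export
print.bias_decomposition <- function(x, ...) {
  cat("<bias_decomposition>\n")
  cat(sprintf("  slope:  unbiased %.6g | direct %.6g | reconstructed %.6g\n",
              x$slope_unbiased, x$slope_direct, x$slope_reconstructed))
  if (!is.na(x$corr_direct)) {
    cat(sprintf("  corr :  unbiased %.6g | direct %.6g | reconstructed %.6g\n",
                x$corr_unbiased, x$corr_direct, x$corr_reconstructed))
  }
  comp <- unlist(x[c("cov_xy", "cov_x_omega", "cov_theta_y",
                     "cov_theta_omega", "var_x", "var_theta",
                     "cov_x_theta", "var_y", "var_omega", "cov_y_omega")])
  print(round(comp, 6))
  invisible(x)
}

#' Compare the two aggregation orders on a trait table
#'
#' Builds species-level values for two traits under both orders
#' (transform-then-aggregate and aggregate-then-transform), aligns
#' species present for both traits (sorted by identifier), and returns
#' the full slope/correlation decomposition of the difference.
#'
#' @param table A [trait_table()].
#' @param trait_x,trait_y Predictor and response trait names.
#' @param t_x,t_y Transforms for each trait.
#' @param reference Which order provides the reference vectors x, y:
#'   `"transform_first"` (default; the starred values are then the
#'   aggregate-then-transform ones) or `"aggregate_first"` to flip the
#'   labelling.
#' @param divisor Covariance divisor, passed through.
#' @return A `bias_decomposition` with attributes `species` (the aligned
#'   identifiers) and `n_dropped` (species lacking one of the traits).
#' @export
compare_aggregation_orders <- function(table, trait_x, trait_y, t_x, t_y,
                                       reference = c("transform_first",
                                                     "aggregate_first"),
                                       divisor = c("n-1", "n")) {
  reference <- match.arg(reference)
  sx <- summarize_trait(table, trait_x, t_x)
  sy <- summarize_trait(table, trait_y, t_y)
  common <- sort(intersect(sx$species, sy$species))
  n_dropped <- length(union(sx$species, sy$species)) - length(common)
  if (length(common) < 3L) {
    stop(sprintf("only %d species carry both '%s' and '%s'; need >= 3",
                 length(common), trait_x, trait_y), call. = FALSE)
  }
  if (n_dropped > 0) {
    message(sprintf(
      "compare_aggregation_orders: %d species lack one of the traits",
      n_dropped))
  }
  sx <- sx[match(common, sx$species), ]
  sy <- sy[match(common, sy$species), ]
  if (reference == "transform_first") {
    x <- sx$mean_transformed;  x_star <- sx$transform_of_mean
    y <- sy$mean_transformed;  y_star <- sy$transform_of_mean
  } else {
    x <- sx$transform_of_mean; x_star <- sx$mean_transformed
    y <- sy$transform_of_mean; y_star <- sy$mean_transformed
  }
  b <- bias_vectors(x, x_star, y, y_star)
  d <- .decompose(x, y, b$theta, b$omega, divisor)
  attr(d, "species") <- common
  attr(d, "n_dropped") <- n_dropped
  attr(d, "reference") <- reference
  d
}

#' Flatten a bias decomposition to a one-row data frame
#'
#' @param x A `bias_decomposition`.
#' @param ... Unused.
#' @return One-row data frame of all numeric fields.
#' @export
as.data.frame.bias_decomposition <- function(x, ...) {
  num <- x[vapply(x, is.numeric, logical(1L))]
  as.data.frame(num, stringsAsFactors = FALSE)
}
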