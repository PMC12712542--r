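# Jensen gap and its quadratic correction -------------------------------
#
# For a species with individual values x_1..x_n and a non-linear
# transform f, the two aggregation orders disagree by the Jensen gap
#
#   gap = mean(f(x_j)) - f(mean(x_j)),
#
# negative for concave f (log, sqrt), positive for convex f. A
# second-order Taylor expansion of f about the raw mean gives the
# quadratic approximation
#
#   gap ~ f''(xbar) * s2 / 2,   s2 = sum((x_j - xbar)^2) / n,
#
# so for log the gap is approximately -s2 / (2 * xbar^2): it grows with
# the ratio of within-species variance to the squared species mean.
# The same expression corrects a species-level summary (mean, SD, n)
# into an estimate of the mean of transformed values when individual
# measurements are unavailable.

#' Exact Jensen gap of one species' measurements
#'
#' @param values Numeric vector of individual measurements (length >= 1),
#'   strictly inside the transform's domain.
#' @param t A `trait_transform`.
#' @return `mean(f(values)) - f(mean(values))`; `<= 0` for concave
#'   transforms, `0` when the transform is linear or the values have no
#'   spread.
#' @examples
#' jensen_gap_exact(c(1, exp(2)), get_transform("log"))
#' @export
jensen_gap_exact <- function(values, t) {
  stopifnot(inherits(t, "trait_transform"), is.numeric(values),
            length(values) >= 1L)
  .check_domain(t, values)
  m <- mean(values)
  .check_domain(t, m, what = "mean")
  mean(t$forward(values)) - t$forward(m)
}

#' Quadratic approximation of the Jensen gap
#'
#' Second-order Taylor estimate `f''(mean_raw) * var_raw_pop / 2`,
#' computable from a species-level summary alone. For the log transform
#' this is `-var_raw_pop / (2 * mean_raw^2)`.
#'
#' @param mean_raw Species mean of raw values, strictly inside the
#'   domain.
#' @param var_raw_pop Within-species population variance (divisor n);
#'   must be `>= 0`.
#' @param t A `trait_transform`.
#' @return The approximate gap; exactly 0 when `var_raw_pop = 0` or the
#'   transform is linear.
#' @export
jensen_gap_quadratic <- function(mean_raw, var_raw_pop, t) {
  stopifnot(inherits(t, "trait_transform"),
            is.numeric(mean_raw), is.numeric(var_raw_pop),
            length(mean_raw) == length(var_raw_pop))
  if (any(var_raw_pop < 0)) stop("var_raw_pop must be >= 0", call. = FALSE)
  .check_domain(t, mean_raw, what = "mean_raw")
  t$second_deriv(mean_raw) * var_raw_pop / 2
}

#' Jensen gaps for every species and trait of a table
#'
#' Convenience wrapper computing, per species x trait, the exact gap,
#' its quadratic approximation, and their absolute difference.
#'
#' @param table A [trait_table()].
#' @param t A `trait_transform` applied to every trait in the table.
#' @param traits Traits to include (default: all present).
#' @return Data frame with columns `species`, `trait`, `n`, `exact_gap`,
#'   `approx_gap`, `abs_error`.
#' @export
jensen_gap_table <- function(table, t, traits = NULL) {
  if (!inherits(table, "trait_table")) table <- trait_table(table)
  if (is.null(traits)) traits <- sort(unique(table$trait))
  out <- lapply(traits, function(tr) {
    s <- summarize_trait(table, tr, t)
    exact <- s$mean_transformed - s$transform_of_mean
    approx <- jensen_gap_quadratic(s$mean_raw, s$var_raw_pop, t)
    data.frame(species = s$species, trait = tr, n = s$n,
               exact_gap = exact, approx_gap = approx,
               abs_error = abs(exact - approx),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correct a transformed species mean from summary statistics
#'
#' When only species-level summaries (mean, SD, n) are available, the
#' transform of the mean can be corrected toward the mean of transformed
#' values: `f(mean_raw) + f''(mean_raw) * var_pop / 2`. The SD is
#' converted to a population variance under the stated convention first
#' (external summary tables usually report the sample SD).
#'
#' @param mean_raw Species mean of raw values (vectorised).
#' @param sd_raw Within-species standard deviation, `>= 0`.
#' @param n Number of measurements behind the summary, `>= 1`.
#' @param t A `trait_transform`.
#' @param sd_convention `"population"` (SD already uses divisor n,
#'   default) or `"sample"` (divisor n - 1; converted by (n-1)/n).
#' @return Estimated mean of transformed values.
#' @examples
#' # log of the mean of {1, e^2}, corrected toward the mean of logs
#' corrected_transformed_mean(mean(c(1, exp(2))), stats::sd(c(1, exp(2))),
#'                            n = 2, get_transform("log"),
#'                            sd_convention = "sample")
#' @export
corrected_transformed_mean <- function(mean_raw, sd_raw, n, t,
                                       sd_convention = c("population",
                                                         "sample")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(is.numeric(mean_raw), is.numeric(sd_raw), is.numeric(n))
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(sd_raw < 0)) stop("sd_raw must be >= 0", call. = FALSE)
  var_pop <- if (sd_convention == "sample") {
    ifelse(n > 1, sd_raw^2 * (n - 1) / n, 0)
  } else {
    sd_raw^2
  }
  .check_domain(t, mean_raw, what = "mean_raw")
  t$forward(mean_raw) + t$second_deriv(mean_raw) * var_pop / 2
}

#' Species-specific offset of the aggregate-then-transform relationship
#'
#' If an individual-level relationship f(y) = a + b g(x) holds, the
#' species values obtained by transforming the raw means obey only
#' f(ybar) ~ a + b g(xbar) + C, where
#'
#'   C = b * g''(xbar) * var_x / 2  -  f''(ybar) * var_y / 2
#'
#' is species-specific because it depends on the species' own means and
#' within-species variances. A non-constant C distorts the species-level
#' relationship; this function evaluates it from two summaries. The
#' stored `var_raw_pop` already carries the 1/n divisor, so no further
#' division by the sample size is applied.
#'
#' @param summary_x,summary_y Single rows of a `species_trait_summary`
#'   (or any list-alikes with `mean_raw` and `var_raw_pop`), aligned to
#'   the same species.
#' @param b Slope of the individual-level linearised relationship.
#' @param t_f Transform applied to the response trait y.
#' @param t_g Transform applied to the predictor trait x.
#' @return The offset C (scalar).
#' @export
species_offset_C <- function(summary_x, summary_y, b, t_f, t_g) {
  stopifnot(inherits(t_f, "trait_transform"),
            inherits(t_g, "trait_transform"))
  mx <- summary_x$mean_raw; vx <- summary_x$var_raw_pop
  my <- summary_y$mean_raw; vy <- summary_y$var_raw_pop
  stopifnot(is.numeric(mx), is.numeric(vx), is.numeric(my), is.numeric(vy))
  .check_domain(t_g, mx, what = "mean_raw(x)")
  .check_domain(t_f, my, what = "mean_raw(y)")
  b * t_g$second_deriv(mx) * vx / 2 - t_f$second_deriv(my) * vy / 2
}
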