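# Transformation registry -----------------------------------------------
#
# Every correction formula in the package needs three things from a
# transformation f: its forward map, its second derivative f'' (the
# curvature term of the quadratic Jensen correction), and its domain of
# validity. A trait_transform bundles these; a small registry holds the
# built-ins and any transforms registered at runtime.

.transform_registry <- new.env(parent = emptyenv())

#' Construct a transformation specification
#'
#' Bundles a monotone transformation with its second derivative and an
#' open interval of validity. Domain checks in this package are strict:
#' a value at or outside the boundary raises an error rather than
#' producing `NaN`/`-Inf`, because silent non-finite values corrupt the
#' downstream covariance machinery.
#'
#' @param name Short identifier, e.g. `"log"`.
#' @param forward Function of one numeric vector: the map f(x).
#' @param second_deriv Function of one numeric vector: f''(x).
#' @param domain_lo,domain_hi Open bounds of validity; values must lie
#'   strictly inside `(domain_lo, domain_hi)`.
#' @param is_linear Logical; linear transforms have `second_deriv`
#'   identically zero and produce no Jensen gap.
#' @return An object of class `trait_transform`.
#' @seealso [get_transform()] for the built-in registry,
#'   [register_transform()] to add custom transforms.
#' @export
trait_transform <- function(name, forward, second_deriv,
                            domain_lo = -Inf, domain_hi = Inf,
                            is_linear = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(forward), is.function(second_deriv),
            is.numeric(domain_lo), is.numeric(domain_hi),
            domain_lo < domain_hi, is.logical(is_linear))
  structure(
    list(name = name, forward = forward, second_deriv = second_deriv,
         domain_lo = domain_lo, domain_hi = domain_hi,
         is_linear = is_linear),
    class = "trait_transform"
  )
}

#' @export
print.trait_transform <- function(x, ...) {
  cat(sprintf("<trait_transform> %s  domain (%g, %g)%s\n",
              x$name, x$domain_lo, x$domain_hi,
              if (x$is_linear) "  [linear]" else ""))
  invisible(x)
}

.register_builtin <- function(t) assign(t$name, t, envir = .transform_registry)

# Built-ins. The arcsine transform is implemented as
# arcsin(sqrt(x)) -- the variance-stabilising form used on proportions --
# with open domain (0, 1); plain arcsin(x) is NOT what "arcsine" means
# here (see the methods vignette).
.init_transforms <- function() {
  .register_builtin(trait_transform(
    "log", forward = log, second_deriv = function(x) -1 / x^2,
    domain_lo = 0))
  .register_builtin(trait_transform(
    "sqrt", forward = sqrt, second_deriv = function(x) -0.25 * x^(-1.5),
    domain_lo = 0))
  .register_builtin(trait_transform(
    "asin_sqrt",
    forward = function(x) asin(sqrt(x)),
    second_deriv = function(x) -(1 - 2 * x) / (4 * (x * (1 - x))^1.5),
    domain_lo = 0, domain_hi = 1))
  .register_builtin(trait_transform(
    "identity", forward = identity, second_deriv = function(x) 0 * x,
    is_linear = TRUE))
}

#' Look up a transformation by name
#'
#' The built-in registry contains `"log"`, `"sqrt"`, `"asin_sqrt"`
#' (arcsine of the square root, on proportions), `"identity"`, and the
#' parametric `"power"` transform x^p (which requires `params`, the
#' exponent). Transforms added with [register_transform()] are also
#' found here.
#'
#' @param name Registry identifier.
#' @param params For `"power"`: the exponent p (a single number).
#' @return A `trait_transform`.
#' @examples
#' get_transform("log")
#' get_transform("power", params = 0.5)
#' @export
get_transform <- function(name, params = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "power") {
    if (is.null(params) || !is.numeric(params) || length(params) != 1L ||
        !is.finite(params)) {
      stop("transform 'power' requires `params` = the exponent p",
           call. = FALSE)
    }
    p <- params
    return(trait_transform(
      name = sprintf("power(%g)", p),
      forward = function(x) x^p,
      second_deriv = function(x) p * (p - 1) * x^(p - 2),
      domain_lo = 0,
      is_linear = (p == 1)))
  }
  if (!exists(name, envir = .transform_registry, inherits = FALSE)) {
    stop(sprintf("unknown transform '%s'; available: %s", name,
                 paste(sort(c(ls(.transform_registry), "power")),
                       collapse = ", ")),
         call. = FALSE)
  }
  get(name, envir = .transform_registry, inherits = FALSE)
}

#' Register a custom transformation
#'
#' Adds a user-supplied transform to the registry for the current
#' session. Both the forward map and its second derivative must be
#' supplied explicitly; no symbolic or automatic differentiation is
#' attempted.
#'
#' @inheritParams trait_transform
#' @return The registered `trait_transform`, invisibly.
#' @export
register_transform <- function(name, forward, second_deriv,
                               domain_lo = -Inf, domain_hi = Inf,
                               is_linear = FALSE) {
  t <- trait_transform(name, forward, second_deriv, domain_lo, domain_hi,
                       is_linear)
  assign(name, t, envir = .transform_registry)
  invisible(t)
}

# strict open-interval check; names the first offending entry
.check_domain <- function(t, values, what = "value") {
  bad <- which(!is.finite(values) | values <= t$domain_lo |
                 values >= t$domain_hi)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(
      "%s[%d] = %g is outside the open domain (%g, %g) of transform '%s'",
      what, i, values[i], t$domain_lo, t$domain_hi, t$name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply a transformation elementwise
#'
#' @param t A `trait_transform`.
#' @param values Numeric vector, all strictly inside the transform's
#'   domain; violations raise an error naming the offending index and
#'   value.
#' @return Numeric vector of the same length, f(values).
#' @examples
#' apply_transform(get_transform("sqrt"), c(4, 9))
#' @export
apply_transform <- function(t, values) {
  stopifnot(inherits(t, "trait_transform"), is.numeric(values))
  .check_domain(t, values)
  t$forward(values)
}

#' Second derivative of a transformation at a point
#'
#' The curvature f''(x) that scales the quadratic Jensen correction.
#'
#' @inheritParams apply_transform
#' @param x Numeric vector of evaluation points, strictly inside the
#'   domain.
#' @return f''(x), vectorised.
#' @examples
#' second_derivative_at(get_transform("log"), 2)  # -1/4
#' @export
second_derivative_at <- function(t, x) {
  stopifnot(inherits(t, "trait_transform"), is.numeric(x))
  .check_domain(t, x, what = "x")
  t$second_deriv(x)
}
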