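#' Triangular distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the triangular distribution with minimum \code{lower}, mode
#' \code{mode} and maximum \code{upper}. All uncertain exposure factors in
#' this package are described by triangular distributions, the standard
#' choice in screening-level probabilistic exposure assessment when only a
#' minimum, most-likely and maximum value are available.
#'
#' Random generation uses the inverse-CDF transform of a uniform stream, so
#' draws are reproducible across platforms for a fixed seed.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param lower,mode,upper distribution parameters, \code{lower <= mode <=
#'   upper}, \code{lower < upper}.
#' @return \code{dtri} the density, \code{ptri} the CDF, \code{qtri} the
#'   quantile function, \code{rtri} a vector of \code{n} draws.
#' @examples
#' mean(rtri(1e4, 1, 2, 3))   # approx (1 + 2 + 3)/3 = 2
#' ptri(2, 1, 2, 3)           # 0.5
#' @name triangular
NULL

check_tri <- function(lower, mode, upper, name = NULL) {
  what <- if (is.null(name)) "triangular spec" else
    sprintf("triangular spec for '%s'", name)
  if (any(!is.finite(c(lower, mode, upper))))
    stop(what, ": parameters must be finite", call. = FALSE)
  if (lower > upper || lower == upper)
    stop(what, ": requires lower < upper (got ",
         lower, ", ", upper, ")", call. = FALSE)
  if (mode < lower || mode > upper)
    stop(what, ": mode ", mode, " outside [", lower, ", ", upper, "]",
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname triangular
#' @export
dtri <- function(x, lower, mode, upper) {
  check_tri(lower, mode, upper)
  d <- numeric(length(x))
  up <- x >= lower & x <= mode
  dn <- x > mode & x <= upper
  if (mode > lower)
    d[up] <- 2 * (x[up] - lower) / ((upper - lower) * (mode - lower))
  else
    d[up] <- 2 / (upper - lower)
  if (upper > mode)
    d[dn] <- 2 * (upper - x[dn]) / ((upper - lower) * (upper - mode))
  d
}

#' @rdname triangular
#' @export
ptri <- function(q, lower, mode, upper) {
  check_tri(lower, mode, upper)
  p <- numeric(length(q))
  p[q >= upper] <- 1
  up <- q > lower & q <= mode
  dn <- q > mode & q < upper
  if (mode > lower)
    p[up] <- (q[up] - lower)^2 / ((upper - lower) * (mode - lower))
  if (upper > mode)
    p[dn] <- 1 - (upper - q[dn])^2 / ((upper - lower) * (upper - mode))
  p
}

#' @rdname triangular
#' @export
qtri <- function(p, lower, mode, upper) {
  check_tri(lower, mode, upper)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  fc <- (mode - lower) / (upper - lower)
  ifelse(p < fc,
         lower + sqrt(p * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - p) * (upper - lower) * (upper - mode)))
}

#' @rdname triangular
#' @export
rtri <- function(n, lower, mode, upper) {
  qtri(stats::runif(n), lower, mode, upper)
}

#' Triangular parameter specification
#'
#' A validated (lower, mode, upper) triple describing one uncertain input
#' parameter. A single scalar is interpreted as a degenerate point mass,
#' the convention used for constants such as Henry's constant or a cancer
#' slope factor.
#'
#' @param lower minimum value, or a length-3 vector \code{c(lower, mode,
#'   upper)}, or a single scalar for a point mass.
#' @param mode most-likely value.
#' @param upper maximum value.
#' @param name parameter name used in validation messages.
#' @return An object of class \code{"triangular_spec"} with fields
#'   \code{lower}, \code{mode}, \code{upper}, \code{name}.
#' @examples
#' triangular_spec(1, 2, 3, name = "IR")
#' triangular_spec(5)   # point mass
#' @export
triangular_spec <- function(lower, mode = NULL, upper = NULL, name = NULL) {
  if (is.null(mode) && is.null(upper)) {
    if (length(lower) == 3) {
      upper <- lower[[3]]; mode <- lower[[2]]; lower <- lower[[1]]
    } else if (length(lower) == 1) {
      # degenerate point mass
      spec <- structure(list(lower = lower, mode = lower, upper = lower,
                             name = name), class = "triangular_spec")
      return(spec)
    } else {
      stop("triangular_spec needs 1 value (point mass) or 3 values",
           call. = FALSE)
    }
  }
  check_tri(lower, mode, upper, name = name)
  structure(list(lower = lower, mode = mode, upper = upper, name = name),
            class = "triangular_spec")
}

#' @export
print.triangular_spec <- function(x, ...) {
  if (x$lower == x$upper)
    cat(sprintf("<point mass%s> %g\n",
                if (is.null(x$name)) "" else paste0(" ", x$name), x$lower))
  else
    cat(sprintf("<triangular%s> T(%g, %g, %g)\n",
                if (is.null(x$name)) "" else paste0(" ", x$name),
                x$lower, x$mode, x$upper))
  invisible(x)
}

is_degenerate <- function(spec) spec$lower == spec$upper

#' Sample a triangular specification
#'
#' Draws \code{n} i.i.d. values from the triangular density described by
#' \code{spec}, via the inverse-CDF transform. A degenerate (point-mass)
#' spec returns its constant repeated \code{n} times without consuming
#' random numbers.
#'
#' @param spec a [triangular_spec()].
#' @param n number of draws, \code{n >= 1}.
#' @return Numeric vector of length \code{n}, every value in
#'   \code{[spec$lower, spec$upper]}.
#' @examples
#' set.seed(1)
#' x <- sample_triangular(triangular_spec(5, 10, 15), 1000)
#' range(x)   # within [5, 15]
#' @export
sample_triangular <- function(spec, n) {
  stopifnot(inherits(spec, "triangular_spec"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is_degenerate(spec)) return(rep(spec$lower, n))
  qtri(stats::runif(n), spec$lower, spec$mode, spec$upper)
}
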