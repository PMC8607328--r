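#' Shifted and scaled t distribution
#'
#' Container for a Student-t distribution with location and scale, the
#' family of both the prior predictive and the posterior of a normal
#' population mean under a normal-gamma prior.
#'
#' @param df Degrees of freedom, a single positive number.
#' @param loc Location (the mode and, for `df > 1`, the mean).
#' @param scale Scale, a single positive number.  The standard deviation
#'   equals `scale * sqrt(df / (df - 2))` for `df > 2`.
#' @return An object of class `"scaled_t"` with fields `df`, `loc`,
#'   `scale`.
#' @seealso [hpd()] for highest-density intervals of this family.
#' @examples
#' scaled_t(df = 32, loc = -0.06, scale = 0.103)
#' @export
scaled_t <- function(df, loc = 0, scale = 1) {
  stopifnot(is.numeric(df), length(df) == 1L, is.finite(df), df > 0,
            is.numeric(loc), length(loc) == 1L, is.finite(loc),
            is.numeric(scale), length(scale) == 1L, is.finite(scale),
            scale > 0)
  structure(list(df = df, loc = loc, scale = scale), class = "scaled_t")
}

#' @export
print.scaled_t <- function(x, ...) {
  cat(sprintf("Scaled t distribution: df = %g, location = %g, scale = %g\n",
              x$df, x$loc, x$scale))
  invisible(x)
}

#' Beta distribution
#'
#' Container for a beta distribution, used for the prior and posterior of
#' a binomial probability (areal fraction).
#'
#' @param shape1,shape2 Positive shape parameters (successes + 1 and
#'   failures + 1 in the conjugate-updating interpretation).
#' @return An object of class `"beta_dist"` with fields `shape1`,
#'   `shape2`.
#' @examples
#' beta_dist(3, 7)
#' @export
beta_dist <- function(shape1, shape2) {
  stopifnot(is.numeric(shape1), length(shape1) == 1L, is.finite(shape1),
            shape1 > 0,
            is.numeric(shape2), length(shape2) == 1L, is.finite(shape2),
            shape2 > 0)
  structure(list(shape1 = shape1, shape2 = shape2), class = "beta_dist")
}

#' @export
print.beta_dist <- function(x, ...) {
  cat(sprintf("Beta distribution: shape1 = %g, shape2 = %g\n",
              x$shape1, x$shape2))
  invisible(x)
}

#' Normal-gamma prior for a normal mean and precision
#'
#' Conjugate joint prior for the mean `mu` and precision `lambda = 1/sigma^2`
#' of a normal population: `lambda ~ Gamma(a, b)` (shape/rate) and
#' `mu | lambda ~ Normal(mu0, 1 / (n0 * lambda))`.  The prior sample size
#' `n0` expresses the information about the mean as an equivalent number
#' of observations; `n0 = 0` is the non-informative (flat) limit used when
#' nothing is known about the mean.
#'
#' @param a,b Shape and rate of the gamma prior on the precision; both
#'   positive.  The prior mean of the precision is `a/b` and its
#'   coefficient of variation `1/sqrt(a)`.
#' @param mu0 Prior mean of the population mean.
#' @param n0 Prior sample size for the mean, a non-negative number
#'   (non-integer values are allowed).
#' @return An object of class `"normal_gamma_prior"`.
#' @examples
#' normal_gamma_prior(a = 16, b = 6.56, mu0 = -0.06, n0 = 38)
#' @export
normal_gamma_prior <- function(a, b, mu0 = 0, n0 = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b > 0,
            is.numeric(mu0), length(mu0) == 1L, is.finite(mu0),
            is.numeric(n0), length(n0) == 1L, is.finite(n0), n0 >= 0)
  structure(list(a = a, b = b, mu0 = mu0, n0 = n0),
            class = "normal_gamma_prior")
}

#' @export
print.normal_gamma_prior <- function(x, ...) {
  cat("Normal-gamma prior\n")
  cat(sprintf("  precision: lambda ~ Gamma(shape = %g, rate = %g)", x$a, x$b),
      sprintf(" (mean %.4g, cv %.4g)\n", x$a / x$b, 1 / sqrt(x$a)))
  if (x$n0 > 0) {
    cat(sprintf("  mean: mu | lambda ~ Normal(%g, 1/(%g * lambda))\n",
                x$mu0, x$n0))
  } else {
    cat("  mean: non-informative flat prior (n0 = 0)\n")
  }
  invisible(x)
}

#' Beta prior for a binomial probability
#'
#' @param shape1,shape2 Positive shape parameters.  Under the
#'   mode/prior-sample-size construction (see [beta_from_mode_n0()])
#'   `shape1 = n0 * pi0 + 1` and `shape2 = n0 * (1 - pi0) + 1`.
#' @return An object of class `"beta_prior"` (also `"beta_dist"`).
#' @examples
#' beta_prior(21, 35)
#' @export
beta_prior <- function(shape1, shape2) {
  x <- beta_dist(shape1, shape2)
  class(x) <- c("beta_prior", class(x))
  x
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta prior: shape1 = %g, shape2 = %g\n", x$shape1, x$shape2))
  n0 <- x$shape1 + x$shape2 - 2
  if (n0 > 0) {
    cat(sprintf("  mode %.4g, prior sample size %g\n",
                (x$shape1 - 1) / n0, n0))
  } else {
    cat("  uniform (non-informative)\n")
  }
  invisible(x)
}

#' Sufficient statistics of a normal sample
#'
#' @param n Sample size (non-negative integer).
#' @param xbar Sample mean (ignored when `n = 0`).
#' @param ss Centred sum of squares `sum((x - xbar)^2)`; must be 0 when
#'   `n <= 1`.
#' @return An object of class `"normal_summary"`.
#' @examples
#' x <- c(0.1, -0.4, 0.3)
#' normal_summary(length(x), mean(x), sum((x - mean(x))^2))
#' @export
normal_summary <- function(n, xbar = NA_real_, ss = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n),
            is.numeric(ss), length(ss) == 1L, ss >= 0)
  if (n <= 1 && ss > 0) {
    stop("'ss' must be 0 when n <= 1", call. = FALSE)
  }
  if (n >= 1 && !is.finite(xbar)) {
    stop("'xbar' must be finite when n >= 1", call. = FALSE)
  }
  structure(list(n = as.integer(n), xbar = xbar, ss = ss),
            class = "normal_summary")
}
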