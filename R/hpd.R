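## Highest-posterior-density interval numerics for the two posterior
## families used throughout: shifted/scaled t and beta.  All coverage
## computations go through the distribution functions (pbeta/qbeta, pt/qt),
## never generic quadrature, for accuracy near the support boundaries.

#' Highest-density interval
#'
#' Computes the shortest interval with a given probability content (the
#' highest posterior density, HPD, interval): every point inside the
#' interval has higher density than any point outside.
#'
#' For the symmetric, unimodal scaled-t family the HPD interval is the
#' equal-tail interval `loc +/- q * scale`.  For the beta family the
#' interval is found by a one-dimensional search over the lower bound,
#' with the upper bound implied by the coverage through the quantile
#' function.  Beta densities with a boundary mode (`shape1 <= 1` or
#' `shape2 <= 1`, not both below 1) are monotone, so the HPD interval
#' abuts the corresponding boundary and no search is needed.  U-shaped
#' densities (`shape1 < 1` and `shape2 < 1`) have no interval HPD set;
#' these signal an error unless `equal_tail = TRUE` requests the
#' equal-tail interval as a fallback.  The flat `Beta(1, 1)` density is
#' resolved deterministically to the interval anchored at 0.
#'
#' @param dist A [scaled_t()] or [beta_dist()] object.
#' @param coverage Requested probability content, in (0, 1).
#' @param ... Passed to methods.
#' @return An object of class `"hpd_interval"`: a list with `lower`,
#'   `upper`, `coverage` (attained probability content) and `length`.
#' @examples
#' hpd(scaled_t(df = 5), 0.95)
#' hpd(beta_dist(3, 7), 0.95)
#' @export
hpd <- function(dist, coverage, ...) UseMethod("hpd")

new_hpd_interval <- function(lower, upper, coverage) {
  structure(list(lower = lower, upper = upper, coverage = coverage,
                 length = upper - lower),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("%.1f%% HPD interval: (%.6g, %.6g), length %.6g\n",
              100 * x$coverage, x$lower, x$upper, x$length))
  invisible(x)
}

check_coverage <- function(coverage) {
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      !is.finite(coverage) || coverage <= 0 || coverage >= 1) {
    stop("'coverage' must be a single number in (0, 1)", call. = FALSE)
  }
}

#' @rdname hpd
#' @export
hpd.scaled_t <- function(dist, coverage, ...) {
  check_coverage(coverage)
  q <- stats::qt((1 + coverage) / 2, df = dist$df)
  new_hpd_interval(dist$loc - q * dist$scale, dist$loc + q * dist$scale,
                   coverage)
}

#' @param equal_tail If `TRUE`, fall back to the equal-tail interval for
#'   U-shaped beta densities instead of signalling an error.
#' @rdname hpd
#' @export
hpd.beta_dist <- function(dist, coverage, equal_tail = FALSE, ...) {
  check_coverage(coverage)
  s1 <- dist$shape1
  s2 <- dist$shape2
  if (s1 < 1 && s2 < 1) {
    if (!equal_tail) {
      stop("U-shaped beta density (shape1 < 1 and shape2 < 1) has no ",
           "interval HPD set; use equal_tail = TRUE for the equal-tail ",
           "interval", call. = FALSE)
    }
    lo <- stats::qbeta((1 - coverage) / 2, s1, s2)
    return(new_hpd_interval(lo, stats::qbeta((1 + coverage) / 2, s1, s2),
                            coverage))
  }
  len <- beta_hpd_lower(s1, s2, coverage)
  new_hpd_interval(len$lower, len$upper, coverage)
}

## Vectorised HPD solve for Beta(shape1, shape2) at a common coverage.
## Returns list(lower, upper).  Monotone shapes hit a support boundary;
## interior modes (shape1 > 1 and shape2 > 1) are solved by bisection on
## the density-equality condition g(v) = log f(v) - log f(u(v)), where
## u(v) = Q(F(v) + coverage).  g is increasing on [0, Q(1 - coverage)],
## with g -> -Inf at 0 and +Inf at the right end, so bisection is safe.
beta_hpd_lower <- function(shape1, shape2, coverage, iter = 64L) {
  m <- max(length(shape1), length(shape2))
  s1 <- rep_len(shape1, m)
  s2 <- rep_len(shape2, m)
  lower <- numeric(m)
  upper <- numeric(m)

  lo_mode <- s1 <= 1 & s2 >= 1                  # mode at 0 (incl. uniform)
  hi_mode <- s1 >= 1 & s2 <= 1 & !lo_mode       # mode at 1
  if (any(s1 < 1 & s2 < 1)) {
    stop("U-shaped beta density in vectorised HPD solve", call. = FALSE)
  }
  lower[lo_mode] <- 0
  upper[lo_mode] <- stats::qbeta(coverage, s1[lo_mode], s2[lo_mode])
  lower[hi_mode] <- stats::qbeta(1 - coverage, s1[hi_mode], s2[hi_mode])
  upper[hi_mode] <- 1

  int <- !(lo_mode | hi_mode)
  if (any(int)) {
    a <- s1[int]
    b <- s2[int]
    vlo <- numeric(sum(int))
    vhi <- stats::qbeta(1 - coverage, a, b)
    for (i in seq_len(iter)) {
      v <- (vlo + vhi) / 2
      u <- stats::qbeta(pmin(stats::pbeta(v, a, b) + coverage, 1), a, b)
      g <- stats::dbeta(v, a, b, log = TRUE) -
        stats::dbeta(u, a, b, log = TRUE)
      hi <- g > 0
      vhi[hi] <- v[hi]
      vlo[!hi] <- v[!hi]
    }
    v <- (vlo + vhi) / 2
    lower[int] <- v
    upper[int] <- stats::qbeta(pmin(stats::pbeta(v, a, b) + coverage, 1),
                               a, b)
  }
  list(lower = lower, upper = upper)
}

## Vectorised HPD lengths (shared coverage), the workhorse of the binomial
## criterion sums.
beta_hpd_length <- function(shape1, shape2, coverage, iter = 64L) {
  r <- beta_hpd_lower(shape1, shape2, coverage, iter)
  r$upper - r$lower
}

#' Maximal coverage of a fixed-length interval under a beta distribution
#'
#' Finds the placement of an interval of length `lmax` inside `[0, 1]`
#' that maximises its probability content under `dist`, and returns that
#' content.  This is the coverage counterpart of the HPD length: an HPD
#' interval of a given coverage has length at most `lmax` exactly when
#' the best length-`lmax` interval has coverage at least that value.
#'
#' @param dist A [beta_dist()] (or [beta_prior()]) object.
#' @param lmax Interval length, in (0, 1).
#' @return A list of class `"hpd_interval"` giving the optimally placed
#'   interval and its (maximal) coverage.
#' @examples
#' max_coverage_beta(beta_dist(5, 15), 0.2)
#' @export
max_coverage_beta <- function(dist, lmax) {
  if (!inherits(dist, "beta_dist")) {
    stop("'dist' must be a beta_dist object", call. = FALSE)
  }
  if (!is.numeric(lmax) || length(lmax) != 1L || !is.finite(lmax) ||
      lmax <= 0) {
    stop("'lmax' must be a single positive number", call. = FALSE)
  }
  if (lmax >= 1) {
    return(new_hpd_interval(0, 1, 1))
  }
  r <- beta_max_cov_lower(dist$shape1, dist$shape2, lmax)
  new_hpd_interval(r$lower, r$lower + lmax, r$coverage)
}

## Vectorised maximal coverage of a length-l interval for Beta(s1, s2).
## Interior modes: bisection on h(v) = log f(v + l) - log f(v), which is
## decreasing, positive at v = 0 and negative at v = 1 - l.  Monotone
## densities anchor at the modal boundary; for (rare) U-shaped densities
## the better of the two boundary placements is taken.
beta_max_cov_lower <- function(shape1, shape2, l, iter = 64L) {
  m <- max(length(shape1), length(shape2))
  s1 <- rep_len(shape1, m)
  s2 <- rep_len(shape2, m)
  lower <- numeric(m)
  cov <- numeric(m)

  lo_mode <- s1 <= 1 & s2 >= 1
  hi_mode <- s1 >= 1 & s2 <= 1 & !lo_mode
  ushape <- s1 < 1 & s2 < 1
  lower[lo_mode] <- 0
  cov[lo_mode] <- stats::pbeta(l, s1[lo_mode], s2[lo_mode])
  lower[hi_mode] <- 1 - l
  cov[hi_mode] <- 1 - stats::pbeta(1 - l, s1[hi_mode], s2[hi_mode])
  if (any(ushape)) {
    c0 <- stats::pbeta(l, s1[ushape], s2[ushape])
    c1 <- 1 - stats::pbeta(1 - l, s1[ushape], s2[ushape])
    lower[ushape] <- ifelse(c0 >= c1, 0, 1 - l)
    cov[ushape] <- pmax(c0, c1)
  }

  int <- !(lo_mode | hi_mode | ushape)
  if (any(int)) {
    a <- s1[int]
    b <- s2[int]
    vlo <- numeric(sum(int))
    vhi <- rep(1 - l, sum(int))
    for (i in seq_len(iter)) {
      v <- (vlo + vhi) / 2
      h <- stats::dbeta(v + l, a, b, log = TRUE) -
        stats::dbeta(v, a, b, log = TRUE)
      up <- h > 0
      vlo[up] <- v[up]
      vhi[!up] <- v[!up]
    }
    v <- (vlo + vhi) / 2
    lower[int] <- v
    cov[int] <- stats::pbeta(v + l, a, b) - stats::pbeta(v, a, b)
  }
  list(lower = lower, coverage = cov)
}
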