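## Bayesian and mixed Bayesian-likelihood sample sizes for a normal
## population mean under the normal-gamma prior.
##
## With a flat prior on the mean (n0 = 0) the posterior interval length
## depends on the data only through the centred sum of squares SS, whose
## preposterior distribution is available in closed form: given lambda,
## SS ~ chi^2_(n-1) / lambda, and compounding over lambda ~ Gamma(a, b)
## gives W = SS / (SS + 2b) ~ Beta((n-1)/2, a).  All three criteria are
## then evaluated deterministically (closed forms or one-dimensional
## quadrature).  With an informative prior on the mean (n0 > 0) the
## fully Bayesian interval also depends on (xbar - mu0)^2 and ALC/WOC are
## evaluated by fixed-seed Monte Carlo over the preposterior.

#' Posterior of a normal mean under the normal-gamma prior
#'
#' Standard conjugate update.  The marginal posterior of the mean is a
#' shifted and scaled t distribution with `2a + n` degrees of freedom,
#' location `(n0 * mu0 + n * xbar) / (n0 + n)` and scale
#' `sqrt(b' / (a' * (n0 + n)))`, where `a' = a + n/2` and
#' `b' = b + ss/2 + n0 * n * (xbar - mu0)^2 / (2 * (n0 + n))`.
#' With `n = 0` (and `n0 > 0`) this is the prior marginal of the mean.
#'
#' @param prior A [normal_gamma_prior()].
#' @param data A [normal_summary()].
#' @return A [scaled_t()] object.
#' @examples
#' pr <- normal_gamma_prior(a = 16, b = 6.56, mu0 = -0.06, n0 = 38)
#' posterior_mu(pr, normal_summary(0))     # prior marginal, scale ~0.1039
#' @export
posterior_mu <- function(prior, data) {
  stopifnot(inherits(prior, "normal_gamma_prior"),
            inherits(data, "normal_summary"))
  n0 <- prior$n0
  n <- data$n
  if (n0 + n <= 0) {
    stop("posterior undefined: flat prior on the mean (n0 = 0) and no ",
         "data", call. = FALSE)
  }
  if (n == 0) {
    return(scaled_t(2 * prior$a, prior$mu0,
                    sqrt(prior$b / (prior$a * n0))))
  }
  loc <- (n0 * prior$mu0 + n * data$xbar) / (n0 + n)
  a_post <- prior$a + n / 2
  b_post <- prior$b + data$ss / 2 +
    n0 * n * (data$xbar - prior$mu0)^2 / (2 * (n0 + n))
  scaled_t(2 * prior$a + n, loc, sqrt(b_post / (a_post * (n0 + n))))
}

#' Closed-form ACC sample size for a normal mean
#'
#' The average coverage criterion admits a closed form: the preposterior
#' average coverage of a length-`lmax` interval centred at the posterior
#' mean equals the probability that a t variate with `2a` degrees of
#' freedom falls within `(lmax/2) * sqrt(a * (n + n0) / b)`, so
#' `n = ceiling(4b / (a * lmax^2) * t_(2a, 1-alpha/2)^2 - n0)`, clamped
#' at 0.  Informative priors on the mean (`n0 > 0`) reduce the required
#' size point-for-point.
#'
#' @param prior A [normal_gamma_prior()].
#' @param lmax Maximum (average) interval length.
#' @param coverage Required average coverage, default 0.95.
#' @return Integer sample size (possibly 0 when the prior alone meets
#'   the requirement).
#' @examples
#' n_mean_acc_closed(normal_gamma_prior(a = 16, b = 11.2), lmax = 0.2)
#' @export
n_mean_acc_closed <- function(prior, lmax, coverage = 0.95) {
  stopifnot(inherits(prior, "normal_gamma_prior"))
  if (!is.numeric(lmax) || length(lmax) != 1L || lmax <= 0) {
    stop("'lmax' must be positive", call. = FALSE)
  }
  check_coverage(coverage)
  tq <- stats::qt((1 + coverage) / 2, df = 2 * prior$a)
  n <- ceiling(4 * prior$b / (prior$a * lmax^2) * tq^2 - prior$n0 - 1e-9)
  max(0L, as.integer(n))
}

## ---- deterministic criterion values, flat prior on the mean (n0 = 0) ----

## E[(1 - W)^(-1/2)] for W ~ Beta(k, a): B(k, a - 1/2) / B(k, a).
## Finite only for a > 1/2.
ew_invsqrt <- function(k, a) {
  if (a <= 0.5) {
    stop("gamma shape 'a' must exceed 1/2 for a finite average length",
         call. = FALSE)
  }
  if (k <= 0) return(1)           # n = 1: SS degenerate at 0
  exp(lgamma(a - 0.5) + lgamma(a + k) - lgamma(a) - lgamma(a + k - 0.5))
}

## Average posterior HPD length, fully Bayesian, n0 = 0.
alc_mean_bayes <- function(n, a, b, coverage) {
  k <- (n - 1) / 2
  2 * stats::qt((1 + coverage) / 2, 2 * a + n) *
    sqrt(b / ((a + n / 2) * n)) * ew_invsqrt(k, a)
}

## Average likelihood-only interval length (2 t_(n-1) s / sqrt(n)),
## mixed Bayesian-likelihood; requires n >= 2.
alc_mean_mbl <- function(n, a, b, coverage) {
  k <- (n - 1) / 2
  2 * stats::qt((1 + coverage) / 2, n - 1) * sqrt(2 * b / ((n - 1) * n)) *
    exp(lgamma(k + 0.5) - lgamma(k) + lgamma(a - 0.5) - lgamma(a))
}

## Average coverage of a fixed-length interval, fully Bayesian: exact
## marginal identity (the analytic path behind the ACC closed form).
acc_mean_bayes <- function(n, a, b, coverage, lmax, n0 = 0) {
  2 * stats::pt((lmax / 2) * sqrt(a * (n + n0) / b), 2 * a) - 1
}

## Average coverage, mixed approach: quadrature over W ~ Beta(k, a).
acc_mean_mbl <- function(n, a, b, coverage, lmax) {
  k <- (n - 1) / 2
  f <- function(w) {
    s <- sqrt(2 * b * w / (1 - w) / (n - 1))
    (2 * stats::pt((lmax / 2) * sqrt(n) / s, n - 1) - 1) *
      stats::dbeta(w, k, a)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10, stop.on.error = FALSE)$value
}

## Interval length at the worst_level quantile of the preposterior of SS
## (lengths are increasing in SS, so this is the worst_level quantile of
## the length distribution).
woc_mean_len <- function(n, a, b, coverage, worst_level, mbl = FALSE) {
  k <- (n - 1) / 2
  w <- if (k > 0) stats::qbeta(worst_level, k, a) else 0
  if (mbl) {
    ss <- 2 * b * w / (1 - w)
    2 * stats::qt((1 + coverage) / 2, n - 1) * sqrt(ss / (n - 1) / n)
  } else {
    2 * stats::qt((1 + coverage) / 2, 2 * a + n) *
      sqrt(b / (1 - w) / ((a + n / 2) * n))
  }
}

## ---- Monte Carlo criterion evaluation (informative prior on the mean) ----

## Common-random-number draws: uniforms fixed once per evaluation context,
## transformed per candidate n, so the criterion is smooth in n and the
## bisection is deterministic given the seed.
mc_base <- function(draws, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  list(u_lam = stats::runif(draws), u_ss = stats::runif(draws),
       z = stats::rnorm(draws))
}

mc_mean_lengths <- function(n, prior, coverage, base, mbl = FALSE) {
  a <- prior$a
  b <- prior$b
  n0 <- prior$n0
  lam <- stats::qgamma(base$u_lam, a, b)
  ss <- if (n > 1) stats::qgamma(base$u_ss, (n - 1) / 2, 1 / 2) / lam else 0
  if (mbl) {
    2 * stats::qt((1 + coverage) / 2, n - 1) * sqrt(ss / (n - 1) / n)
  } else {
    dev <- base$z * sqrt((1 / n0 + 1 / n) / lam)   # xbar - mu0
    b_post <- b + ss / 2 + n0 * n * dev^2 / (2 * (n0 + n))
    2 * stats::qt((1 + coverage) / 2, 2 * a + n) *
      sqrt(b_post / ((a + n / 2) * (n0 + n)))
  }
}

## ---- search ----

#' Bayesian / mixed sample size for a normal population mean
#'
#' Finds the smallest sample size meeting a precision requirement for
#' estimating a normal population mean, with uncertainty about the
#' population precision expressed by the gamma part of a
#' [normal_gamma_prior()].  Criteria: ALC (preposterior-average HPD
#' length at most `lmax`), ACC (preposterior-average coverage of
#' length-`lmax` intervals at least `coverage`) and WOC (the length
#' requirement must hold with preposterior probability `worst_level`).
#' The fully Bayesian approach uses the conjugate posterior; the mixed
#' Bayesian-likelihood approach evaluates the likelihood-only interval
#' `2 t_(n-1, 1-alpha/2) s / sqrt(n)` and needs `n >= 2`.
#'
#' With `n0 = 0` (flat prior on the mean) all criteria are evaluated
#' deterministically; with `n0 > 0` the fully Bayesian ALC and WOC use
#' fixed-seed Monte Carlo over the preposterior.  The search brackets the
#' answer by doubling from the frequentist size and bisects (the criteria
#' are monotone in n), then verifies that the criterion fails at `n - 1`.
#'
#' @param prior A [normal_gamma_prior()].
#' @param spec A [precision_spec()].  `approach = "freq"` returns the
#'   closed-form frequentist size computed from `sigma0^2 = b/a`.
#' @param draws Monte Carlo draws when stochastic evaluation is needed
#'   (default 1e5).
#' @param seed Seed for the Monte Carlo draws (default 1).
#' @return An object of class `"ssd_result"`: sample size `n`, the
#'   `achieved` criterion value at `n`, the criterion/approach, and
#'   `mc_error` (Monte Carlo standard error of the achieved value; 0 for
#'   deterministic paths).
#' @examples
#' pr <- normal_gamma_prior(a = 94, b = 68)
#' ssd_mean(pr, precision_spec(lmax = 0.2, criterion = "alc"))  # n = 281
#' @export
ssd_mean <- function(prior, spec, draws = 1e5, seed = 1L) {
  stopifnot(inherits(prior, "normal_gamma_prior"),
            inherits(spec, "precision_spec"))
  if (spec$approach == "freq") {
    n <- n_mean_freq(sqrt(prior$b / prior$a), spec$lmax, spec$coverage)
    return(new_ssd_result(n, NA_real_, "freq", "freq", spec, 0))
  }
  mbl <- spec$approach == "mbl"
  stochastic <- !mbl && prior$n0 > 0 && spec$criterion != "acc"
  base <- if (stochastic) mc_base(draws, seed)

  ## value(n): the criterion statistic; ok(n): requirement satisfied
  eval_n <- function(n) {
    a <- prior$a
    b <- prior$b
    if (stochastic) {
      len <- mc_mean_lengths(n, prior, spec$coverage, base, mbl = FALSE)
      switch(spec$criterion,
             alc = c(mean(len), stats::sd(len) / sqrt(length(len))),
             woc = c(unname(stats::quantile(len, spec$worst_level)),
                     stats::sd(len) / sqrt(length(len))))
    } else {
      v <- switch(spec$criterion,
        alc = if (mbl) alc_mean_mbl(n, a, b, spec$coverage)
              else alc_mean_bayes(n, a, b, spec$coverage),
        acc = if (mbl) acc_mean_mbl(n, a, b, spec$coverage, spec$lmax)
              else acc_mean_bayes(n, a, b, spec$coverage, spec$lmax,
                                  prior$n0),
        woc = woc_mean_len(n, a, b, spec$coverage, spec$worst_level, mbl))
      c(v, 0)
    }
  }
  ok <- function(v) {
    if (spec$criterion == "acc") v[1] >= spec$coverage
    else v[1] <= spec$lmax
  }

  n_min <- if (mbl) 2L else 1L
  n_start <- max(n_min,
                 n_mean_freq(sqrt(prior$b / prior$a), spec$lmax,
                             spec$coverage) %/% 2L)
  ## bracket by doubling
  hi <- n_start
  v_hi <- eval_n(hi)
  it <- 0L
  while (!ok(v_hi)) {
    hi <- hi * 2L
    if (hi > 1e7) stop("sample-size search exceeded 1e7", call. = FALSE)
    v_hi <- eval_n(hi)
  }
  lo <- n_min - 1L                       # criterion treated as failing
  ## bisect on the satisfying predicate (monotone in n)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (mid < n_min) {
      lo <- mid
      next
    }
    if (ok(eval_n(mid))) hi <- mid else lo <- mid
  }
  v <- eval_n(hi)
  if (hi > n_min && ok(eval_n(hi - 1L))) {
    ## guard against a bracket artefact; walk down to certify minimality
    while (hi > n_min && ok(eval_n(hi - 1L))) hi <- hi - 1L
    v <- eval_n(hi)
  }
  new_ssd_result(hi, v[1], spec$criterion, spec$approach, spec, v[2])
}

new_ssd_result <- function(n, achieved, criterion, approach, spec,
                           mc_error = 0, n_beyond_prior = NULL,
                           achieved_label = NULL) {
  if (is.null(achieved_label)) {
    achieved_label <- switch(criterion,
                             acc = "average coverage",
                             woc = "worst-level length",
                             "average length")
  }
  structure(list(n = as.integer(n), achieved = achieved,
                 achieved_label = achieved_label,
                 criterion = criterion, approach = approach,
                 lmax = spec$lmax, coverage = spec$coverage,
                 worst_level = spec$worst_level, mc_error = mc_error,
                 n_beyond_prior = n_beyond_prior),
            class = "ssd_result")
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(sprintf("Sample size: n = %d  [%s, %s]\n", x$n,
              toupper(x$criterion), x$approach))
  if (is.finite(x$achieved)) {
    cat(sprintf("  achieved %s at n: %.5g", x$achieved_label, x$achieved))
    if (x$mc_error > 0) cat(sprintf(" (MC se %.2g)", x$mc_error))
    cat("\n")
  }
  if (!is.null(x$n_beyond_prior)) {
    cat(sprintf("  beyond the prior's effective sample size: %d\n",
                x$n_beyond_prior))
  }
  invisible(x)
}
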