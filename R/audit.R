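## Empirical audit of a sample size by forward simulation: draw the
## parameter from the prior, simulate a data set of size n, compute the
## posterior (or likelihood-only) interval, and summarise the length and
## coverage distributions.  Replicates drawn from the prior are averaged
## with equal weights: that is the standard Monte Carlo estimator of the
## preposterior expectations (re-weighting prior draws by the prior
## density would count the prior twice).

new_audit <- function(n, draws, lengths, coverages, lmax, seed) {
  structure(list(
    n = as.integer(n), draws = as.integer(draws),
    mean_length = mean(lengths),
    se_length = stats::sd(lengths) / sqrt(draws),
    mean_coverage = mean(coverages),
    se_coverage = stats::sd(coverages) / sqrt(draws),
    length_quantiles = stats::quantile(lengths,
                                       c(0.05, 0.25, 0.5, 0.75, 0.95)),
    lmax = lmax, seed = seed), class = "ssd_audit")
}

#' @export
print.ssd_audit <- function(x, ...) {
  cat(sprintf("Simulation audit at n = %d (%d replicates, seed %d)\n",
              x$n, x$draws, x$seed))
  cat(sprintf("  mean HPD length: %.5g (se %.2g)  [lmax %g]\n",
              x$mean_length, x$se_length, x$lmax))
  cat(sprintf("  mean coverage of length-lmax intervals: %.5g (se %.2g)\n",
              x$mean_coverage, x$se_coverage))
  invisible(x)
}

check_audit_args <- function(draws, seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("'seed' is required for a reproducible audit", call. = FALSE)
  }
  stopifnot(is.numeric(draws), length(draws) == 1L, draws >= 1)
}

#' Simulation audit of a normal-mean sample size
#'
#' Repeats, `draws` times: draw the precision (and, when `n0 > 0`, the
#' mean) from the prior, simulate `n` normal observations, compute the
#' posterior (fully Bayesian) or likelihood-only (mixed) interval, and
#' record its length and the coverage of a length-`lmax` interval.  With
#' a flat prior on the mean the interval geometry does not depend on the
#' true mean, which is then fixed at 0.
#'
#' @param prior A [normal_gamma_prior()].
#' @param n Sample size to audit (>= 2 for the mixed approach).
#' @param spec A [precision_spec()].
#' @param draws Number of replicates (default 2000).
#' @param seed RNG seed (required).
#' @return An object of class `"ssd_audit"` with means, Monte Carlo
#'   standard errors and length quantiles.
#' @examples
#' pr <- normal_gamma_prior(a = 94, b = 68)
#' audit_mean(pr, n = 281, precision_spec(lmax = 0.2), draws = 500,
#'            seed = 7)
#' @export
audit_mean <- function(prior, n, spec, draws = 2000, seed = NULL) {
  stopifnot(inherits(prior, "normal_gamma_prior"),
            inherits(spec, "precision_spec"))
  check_audit_args(draws, seed)
  mbl <- spec$approach == "mbl"
  if (n < 2 && mbl) {
    stop("mixed approach needs n >= 2", call. = FALSE)
  }
  stopifnot(n >= 1)
  set.seed(seed)
  lengths <- numeric(draws)
  coverages <- numeric(draws)
  for (i in seq_len(draws)) {
    lam <- stats::rgamma(1, prior$a, prior$b)
    mu <- if (prior$n0 > 0) {
      stats::rnorm(1, prior$mu0, 1 / sqrt(prior$n0 * lam))
    } else 0
    x <- stats::rnorm(n, mu, 1 / sqrt(lam))
    xbar <- mean(x)
    ss <- sum((x - xbar)^2)
    if (mbl) {
      s <- sqrt(ss / (n - 1))
      half <- stats::qt((1 + spec$coverage) / 2, n - 1) * s / sqrt(n)
      lengths[i] <- 2 * half
      coverages[i] <- 2 * stats::pt((spec$lmax / 2) * sqrt(n) / s,
                                    n - 1) - 1
    } else {
      post <- posterior_mu(prior, normal_summary(n, xbar, ss))
      lengths[i] <- hpd(post, spec$coverage)$length
      coverages[i] <- 2 * stats::pt((spec$lmax / 2) / post$scale,
                                    post$df) - 1
    }
  }
  new_audit(n, draws, lengths, coverages, spec$lmax, seed)
}

#' Simulation audit of a binomial-proportion sample size
#'
#' Repeats, `draws` times: draw the proportion from the beta prior,
#' simulate `z ~ Binomial(n, pi)`, compute the posterior
#' (fully Bayesian) or uniform-prior (mixed) beta posterior, and record
#' its HPD length and the maximal coverage of a length-`lmax` interval.
#' The exact finite-sum criterion values from [ssd_prop()] should lie
#' within a few Monte Carlo standard errors of these averages.
#'
#' @inheritParams audit_mean
#' @param prior A [beta_prior()].
#' @return An object of class `"ssd_audit"`.
#' @examples
#' audit_prop(beta_prior(1, 1), n = 234, precision_spec(lmax = 0.1),
#'            draws = 500, seed = 7)
#' @export
audit_prop <- function(prior, n, spec, draws = 2000, seed = NULL) {
  stopifnot(inherits(prior, "beta_dist"),
            inherits(spec, "precision_spec"), n >= 0)
  check_audit_args(draws, seed)
  set.seed(seed)
  pi_draw <- stats::rbeta(draws, prior$shape1, prior$shape2)
  z <- stats::rbinom(draws, n, pi_draw)
  if (spec$approach == "mbl") {
    s1 <- z + 1
    s2 <- n - z + 1
  } else {
    s1 <- z + prior$shape1
    s2 <- n - z + prior$shape2
  }
  lengths <- beta_hpd_length(s1, s2, spec$coverage)
  coverages <- beta_max_cov_lower(s1, s2, spec$lmax)$coverage
  new_audit(n, draws, lengths, coverages, spec$lmax, seed)
}
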