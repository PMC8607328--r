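## Prior elicitation: turning legacy survey summaries or expert quantile
## intervals into hyperparameters of the gamma prior for a precision and
## the beta prior for a proportion.

#' Gamma hyperparameters for a precision from a variance and a CV
#'
#' Sets the mean of the gamma prior for the precision `lambda = 1/sigma^2`
#' to the reciprocal of a legacy variance estimate, and its coefficient of
#' variation to a chosen value expressing trust in that estimate.  Solving
#' the two moment equations gives `a = 1/cv^2` and `b = a * variance`.
#'
#' @param variance Legacy estimate of the population variance (> 0); for
#'   log-transformed data this is the variance on the log scale.
#' @param cv Coefficient of variation of the gamma prior (> 0); smaller
#'   values mean more trust in the legacy variance.
#' @return A list with shape `a` and rate `b`.
#' @examples
#' gamma_from_mean_cv(0.41, 0.25)  # a = 16, b = 6.56
#' @export
gamma_from_mean_cv <- function(variance, cv) {
  stopifnot(is.numeric(variance), length(variance) == 1L,
            is.finite(variance), is.numeric(cv), length(cv) == 1L,
            is.finite(cv))
  if (variance <= 0) stop("'variance' must be positive", call. = FALSE)
  if (cv <= 0) stop("'cv' must be positive", call. = FALSE)
  a <- 1 / cv^2
  list(a = a, b = a * variance)
}

#' Beta prior from a prior mode and prior sample size
#'
#' Builds the beta prior whose mode equals a legacy proportion estimate
#' `pi0`, with concentration governed by a prior sample size `n0`:
#' `shape1 = n0 * pi0 + 1`, `shape2 = n0 * (1 - pi0) + 1`.  With `n0 = 0`
#' this is the uniform `Beta(1, 1)`.
#'
#' @param pi0 Prior estimate of the proportion, in `[0, 1]`.
#' @param n0 Prior sample size, a non-negative number.
#' @return A [beta_prior()] object.
#' @examples
#' beta_from_mode_n0(0.259, 20)  # Beta(6.18, 15.82)
#' @export
beta_from_mode_n0 <- function(pi0, n0) {
  stopifnot(is.numeric(pi0), length(pi0) == 1L, is.finite(pi0),
            is.numeric(n0), length(n0) == 1L, is.finite(n0))
  if (pi0 < 0 || pi0 > 1) stop("'pi0' must be in [0, 1]", call. = FALSE)
  if (n0 < 0) stop("'n0' must be non-negative", call. = FALSE)
  beta_prior(n0 * pi0 + 1, n0 * (1 - pi0) + 1)
}

## 2-D quantile matching on the log of the two parameters (positivity is
## enforced by the parameterisation).  Damped Newton with a numerical
## Jacobian, started from a normal-approximation moment match; residuals
## are required to be below `tol` in quantile space.
match_quantiles <- function(qfun, q, p, init, tol = 1e-6) {
  resid <- function(lp) {
    th <- exp(lp)
    qfun(p, th[1], th[2]) - q
  }
  lp <- log(init)
  r <- resid(lp)
  for (it in seq_len(200L)) {
    if (max(abs(r)) < tol * 1e-3) break
    h <- 1e-6
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      lp2 <- lp
      lp2[j] <- lp2[j] + h
      J[, j] <- (resid(lp2) - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      lp_new <- lp - lam * step
      r_new <- resid(lp_new)
      if (all(is.finite(r_new)) && sum(r_new^2) < sum(r^2)) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (lam < 1e-10) break
    lp <- lp_new
    r <- r_new
  }
  if (max(abs(r)) > tol) {
    ## polish with a derivative-free pass before giving up
    o <- stats::optim(lp, function(z) sum(resid(z)^2),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    lp <- o$par
    r <- resid(lp)
    if (max(abs(r)) > tol) {
      stop("quantile matching did not converge: residuals ",
           paste(signif(r, 3), collapse = ", "), call. = FALSE)
    }
  }
  list(par = exp(lp), residual = r)
}

#' Beta hyperparameters from two quantiles
#'
#' Solves for the beta distribution whose `p_lo`- and `p_hi`-quantiles
#' equal a stated plausible interval `(q_lo, q_hi)` for a proportion,
#' e.g. an expert's central 95% interval.  A two-dimensional root find on
#' the log-shape parameters matches the quantiles to within `1e-6`.
#'
#' @param q_lo,q_hi Interval bounds, with `0 < q_lo < q_hi < 1`.
#' @param p_lo,p_hi Probability levels the bounds correspond to
#'   (defaults: 2.5% and 97.5%).
#' @return A list with the fitted [beta_prior()] (`prior`), the
#'   nearest-integer hyperparameters (`rounded`), and the quantile
#'   residuals (`residual`).
#' @examples
#' beta_from_quantiles(0.25, 0.5)$rounded  # c(21, 35)
#' @export
beta_from_quantiles <- function(q_lo, q_hi, p_lo = 0.025, p_hi = 0.975) {
  stopifnot(is.numeric(q_lo), is.numeric(q_hi),
            length(q_lo) == 1L, length(q_hi) == 1L)
  if (!(q_lo > 0 && q_hi < 1 && q_lo < q_hi)) {
    stop("need 0 < q_lo < q_hi < 1", call. = FALSE)
  }
  if (!(p_lo > 0 && p_hi < 1 && p_lo < p_hi)) {
    stop("need 0 < p_lo < p_hi < 1", call. = FALSE)
  }
  m <- (q_lo + q_hi) / 2
  s <- (q_hi - q_lo) / (stats::qnorm(p_hi) - stats::qnorm(p_lo))
  k <- max(m * (1 - m) / s^2 - 1, 0.5)
  fit <- match_quantiles(stats::qbeta, c(q_lo, q_hi), c(p_lo, p_hi),
                         init = c(m * k, (1 - m) * k))
  list(prior = beta_prior(fit$par[1], fit$par[2]),
       rounded = round(fit$par),
       residual = fit$residual)
}

#' Gamma hyperparameters for a precision from a variance interval
#'
#' Converts a plausible interval `(v_lo, v_hi)` for a population variance
#' into the corresponding interval `(1/v_hi, 1/v_lo)` for the precision,
#' and solves for the gamma distribution whose `p_lo`- and
#' `p_hi`-quantiles match it to within `1e-6`.
#'
#' @param v_lo,v_hi Variance interval bounds, `0 < v_lo < v_hi`.
#' @param p_lo,p_hi Probability levels (defaults: 2.5% and 97.5%).
#' @return A list with shape `a`, rate `b`, the nearest-integer pair
#'   (`rounded`), and the quantile residuals (`residual`).
#' @examples
#' gamma_from_variance_interval(0.60, 0.90)$rounded  # c(94, 68)
#' @export
gamma_from_variance_interval <- function(v_lo, v_hi, p_lo = 0.025,
                                         p_hi = 0.975) {
  stopifnot(is.numeric(v_lo), is.numeric(v_hi),
            length(v_lo) == 1L, length(v_hi) == 1L)
  if (!(v_lo > 0 && v_lo < v_hi)) {
    stop("need 0 < v_lo < v_hi", call. = FALSE)
  }
  q <- c(1 / v_hi, 1 / v_lo)            # precision quantiles, increasing
  m <- mean(q)
  s <- (q[2] - q[1]) / (stats::qnorm(p_hi) - stats::qnorm(p_lo))
  fit <- match_quantiles(stats::qgamma, q, c(p_lo, p_hi),
                         init = c((m / s)^2, m / s^2))
  list(a = fit$par[1], b = fit$par[2],
       rounded = round(fit$par),
       residual = fit$residual)
}
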