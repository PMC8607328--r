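#' Precision requirement for sample size determination
#'
#' Bundles the precision requirement and the criterion under which a
#' sample size is sought.
#'
#' @param lmax Maximum interval length, on the scale of the parameter
#'   being estimated (> 0; for a proportion also < 1).
#' @param coverage Interval coverage `1 - alpha`, in (0, 1); default 0.95.
#' @param criterion `"alc"` (average length), `"acc"` (average coverage)
#'   or `"woc"` (modified worst outcome).
#' @param approach `"bayes"` (fully Bayesian), `"mbl"` (mixed
#'   Bayesian-likelihood: the prior generates the preposterior of the
#'   data, but post-sampling inference uses a non-informative analysis
#'   prior) or `"freq"` (closed-form frequentist, ignoring the criterion).
#' @param worst_level For WOC: the required assurance, i.e. the
#'   preposterior probability mass of data sets for which the precision
#'   requirement must hold, in (0, 1].
#' @return An object of class `"precision_spec"`.
#' @examples
#' precision_spec(lmax = 0.1, criterion = "woc", worst_level = 0.8)
#' @export
precision_spec <- function(lmax, coverage = 0.95,
                           criterion = c("alc", "acc", "woc"),
                           approach = c("bayes", "mbl", "freq"),
                           worst_level = 0.8) {
  criterion <- match.arg(criterion)
  approach <- match.arg(approach)
  stopifnot(is.numeric(lmax), length(lmax) == 1L, is.finite(lmax))
  if (lmax <= 0) stop("'lmax' must be positive", call. = FALSE)
  check_coverage(coverage)
  if (!is.numeric(worst_level) || length(worst_level) != 1L ||
      worst_level <= 0 || worst_level > 1) {
    stop("'worst_level' must be in (0, 1]", call. = FALSE)
  }
  structure(list(lmax = lmax, coverage = coverage, criterion = criterion,
                 approach = approach, worst_level = worst_level),
            class = "precision_spec")
}

#' @export
print.precision_spec <- function(x, ...) {
  cat(sprintf(
    "Precision requirement: lmax = %g, coverage = %g, %s (%s%s)\n",
    x$lmax, x$coverage, toupper(x$criterion), x$approach,
    if (x$criterion == "woc") sprintf(", worst level %g", x$worst_level)
    else ""))
  invisible(x)
}

#' Frequentist sample size for a population mean
#'
#' Closed-form sample size so that a normal-approximation confidence
#' interval for the mean has length at most `lmax`, given a prior point
#' estimate `sigma0` of the population standard deviation:
#' `n = ceiling((z_(1-alpha/2) * sigma0 / (lmax/2))^2)`, with a minimum
#' of 1.
#'
#' @param sigma0 Prior estimate of the population standard deviation
#'   (>= 0).
#' @param lmax Maximum confidence-interval length (> 0).
#' @param coverage Confidence level, default 0.95.
#' @return Integer sample size.
#' @examples
#' n_mean_freq(sqrt(0.70), lmax = 0.2)  # 269 from the rounded variance
#' @export
n_mean_freq <- function(sigma0, lmax, coverage = 0.95) {
  stopifnot(is.numeric(sigma0), length(sigma0) == 1L, is.finite(sigma0))
  if (sigma0 < 0) stop("'sigma0' must be non-negative", call. = FALSE)
  if (!is.numeric(lmax) || length(lmax) != 1L || lmax <= 0) {
    stop("'lmax' must be positive", call. = FALSE)
  }
  check_coverage(coverage)
  z <- stats::qnorm((1 + coverage) / 2)
  max(1L, as.integer(ceiling((z * sigma0 / (lmax / 2))^2 - 1e-9)))
}

#' Frequentist (Wald) sample size for a proportion
#'
#' Closed-form sample size so that the Wald (normal-approximation)
#' confidence interval for a binomial probability has length at most
#' `lmax`, given a prior point estimate `pi0`:
#' `n = ceiling(z^2 * pi0 * (1 - pi0) / (lmax/2)^2 + 1)`.
#'
#' @param pi0 Prior estimate of the proportion, in `[0, 1]`.
#' @param lmax Maximum confidence-interval length, in (0, 1).
#' @param coverage Confidence level, default 0.95.
#' @return Integer sample size.
#' @examples
#' n_prop_wald(0.495, lmax = 0.1)  # 386
#' @export
n_prop_wald <- function(pi0, lmax, coverage = 0.95) {
  stopifnot(is.numeric(pi0), length(pi0) == 1L, is.finite(pi0))
  if (pi0 < 0 || pi0 > 1) stop("'pi0' must be in [0, 1]", call. = FALSE)
  if (!is.numeric(lmax) || length(lmax) != 1L || lmax <= 0 || lmax >= 1) {
    stop("'lmax' must be in (0, 1)", call. = FALSE)
  }
  check_coverage(coverage)
  z <- stats::qnorm((1 + coverage) / 2)
  max(1L,
      as.integer(ceiling(z^2 * pi0 * (1 - pi0) / (lmax / 2)^2 + 1 - 1e-9)))
}
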