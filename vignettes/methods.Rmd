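---
title: "Sample size determination under design-parameter uncertainty: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample size determination under design-parameter uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdbayes)
```

## The problem

A survey is being planned to estimate either the mean of a (log-transformed)
continuous soil property over an administrative unit, or the areal fraction of
the unit satisfying a condition (for instance, the fraction with Zn
concentration below a deficiency threshold).  The planner states a precision
requirement — a maximum length `lmax` for a 95% interval estimate — and asks
for the smallest sample size `n` that meets it.

The classical closed forms need a point value for the *design parameter*: the
population standard deviation for a mean, the proportion itself for a
fraction.  `n_mean_freq()` and `n_prop_wald()` implement them:

$$n = \left(\frac{u_{1-\alpha/2}\,\sigma_0}{l_{max}/2}\right)^2,
\qquad
n = \frac{u_{1-\alpha/2}^2\,\pi_0(1-\pi_0)}{(l_{max}/2)^2} + 1,$$

rounded up, with a floor of 1.  Both are exquisitely sensitive to the design
parameter, about which the planner is always uncertain.  The Bayesian
formulation replaces the point value with a prior distribution and evaluates
the requirement over the *preposterior* distribution of the data that prior
implies — the marginal distribution of data sets not yet collected.

## Models and priors

**Mean.**  Observations are modelled as normal with mean $\mu$ and precision
$\lambda = 1/\sigma^2$, with the conjugate normal-gamma prior
$\lambda \sim \mathrm{Gamma}(a, b)$ (shape/rate) and
$\mu \mid \lambda \sim \mathrm{N}(\mu_0, 1/(n_0\lambda))$
(`normal_gamma_prior()`).  The prior mean of $\lambda$ is $a/b$ and its
coefficient of variation $1/\sqrt a$; $n_0$ is the prior information about
$\mu$ expressed as an equivalent number of observations.  The default design
analysis uses $n_0 = 0$, a flat prior on the mean: required sizes are then
conservative, and an informative prior would reduce them by $n_0$ points.
The posterior of $\mu$ (`posterior_mu()`) is a shifted and scaled t
distribution; with $n_0 = 0$ we use the $n_0 \to 0$ limit of the conjugate
update (degrees of freedom $2a + n$, $a' = a + n/2$, $b' = b + ss/2$).  A
coherent flat-prior derivation would instead give $2a + n - 1$ degrees of
freedom; the two conventions differ by at most one sampling unit in the
resulting sizes, and we adopt the limit convention throughout.

**Proportion.**  The number of successes in $n$ trials is binomial with
probability $\pi$, with conjugate prior $\pi \sim \mathrm{Beta}(c, d)$
(`beta_prior()`).  The preposterior of $z$ is beta-binomial
(`dbetabinom()`), and the posterior of $\pi$ is $\mathrm{Beta}(z+c,\,n-z+d)$.

**Mixed Bayesian-likelihood (MBL).**  A two-priors design: the informative
prior generates the preposterior of the data, but inference after collection
uses a non-informative analysis prior — the likelihood-only interval
$2\,t_{n-1,1-\alpha/2}\,s/\sqrt n$ for the mean, the
$\mathrm{Beta}(z+1,\,n-z+1)$ posterior for the proportion.  This matches the
common situation where legacy data are trusted enough to plan with, but not
enough to enter the final estimate.

## Criteria

Let $l(z, n)$ be the length of the $(1-\alpha)$ highest-posterior-density
(HPD) interval for data $z$, and $f(z \mid n)$ the preposterior.  All three
criteria are selected through `precision_spec()`:

* **ALC** (average length): smallest $n$ with
  $\mathrm{E}_z\, l(z, n) \le l_{max}$.
* **ACC** (average coverage): smallest $n$ such that the best-placed interval
  of fixed length $l_{max}$ has preposterior-average posterior probability at
  least $1-\alpha$.
* **WOC** (modified worst outcome): smallest $n$ such that
  $l(z, n) \le l_{max}$ holds with preposterior assurance `worst_level`
  (default 0.8), i.e. the preposterior probability of exceeding $l_{max}$ is
  at most `1 - worst_level`.  WOC with assurance level $w$ therefore
  guarantees that a fraction $w$ of the data sets the prior considers
  plausible will deliver the required precision.

## HPD numerics

The scaled-t posterior is symmetric, so its HPD interval is the equal-tail
interval.  For a beta posterior with an interior mode the HPD interval is
found by bisection on the lower bound $v$, with the upper bound implied by
the coverage through the quantile function; the bisection solves the
density-equality condition at the two endpoints, runs 64 halvings of the unit
interval (endpoint resolution far below 1e-7), and evaluates all probability
through `pbeta`/`qbeta`, never by quadrature of the density — this keeps
boundary cases accurate.  Monotone beta densities (`shape1 <= 1` or
`shape2 <= 1`) have one-sided HPD intervals abutting the support boundary;
the flat `Beta(1,1)` returns the interval anchored at 0 so that results are
deterministic; U-shaped densities have no interval HPD set and raise an error
unless an equal-tail fallback is requested.  The fixed-length coverage
problem (`max_coverage_beta()`) is solved by the same bisection pattern on
the placement of the interval.  Both solvers are vectorised over the outcome
space, which is what makes exact finite-sum criterion evaluation cheap.

## Evaluating the criteria

**Proportion: exact finite sums.**  The outcome space at size $n$ is
$\{0, \dots, n\}$, so every criterion is an exact sum of at most $n+1$ terms
weighted by the beta-binomial mass.  No simulation is involved.

**Mean with a flat prior on the mean: deterministic.**  The interval length
depends on the data only through the centred sum of squares $SS$; given
$\lambda$, $SS \sim \chi^2_{n-1}/\lambda$, and compounding over the gamma
prior gives $W = SS/(SS + 2b) \sim \mathrm{Beta}((n-1)/2,\, a)$.  ALC then
has a closed form through
$\mathrm{E}\,(1-W)^{-1/2} = B(k, a - \tfrac12)/B(k, a)$ (finite for
$a > 1/2$), WOC plugs the `worst_level` quantile of $W$ into the length
formula, and the MBL average length is a ratio of gamma functions.  The MBL
average coverage uses one-dimensional quadrature (`integrate()`) over $W$.
The fully Bayesian ACC is evaluated through an exact marginal identity: the
preposterior-average coverage of a length-$l_{max}$ interval centred at the
posterior mean equals
$2F_{t_{2a}}\!\big((l_{max}/2)\sqrt{a(n+n_0)/b}\big) - 1$,
whose crossing point is precisely the closed form implemented in
`n_mean_acc_closed()` — so the search and the closed form agree exactly by
construction.  (Averaging the limit-convention posterior coverage over the
preposterior of $SS$ instead differs from this identity by a few units in
the fourth decimal of coverage — the one-degree-of-freedom convention noted
above — which can move the ACC size by one unit; we treat the marginal
identity as definitive.)

**Mean with an informative prior on the mean.**  The fully Bayesian interval
also depends on $(\bar x - \mu_0)^2$, so ALC and WOC are evaluated by Monte
Carlo over the preposterior with a fixed seed (default $10^5$ draws).  The
uniform draws are fixed once and transformed by quantile functions for each
candidate $n$ (common random numbers), so the criterion varies smoothly in
$n$ and the search is reproducible; the result records the Monte Carlo
standard error of the achieved value.

## Search and minimality

For the mean the criteria are monotone in $n$: the search brackets the
answer by doubling from the frequentist size and bisects, then walks down if
needed so that the returned $n$ satisfies the criterion while $n-1$ does
not.

For the proportion the criteria are *not* guaranteed monotone, so
`ssd_prop()` scans upward linearly from half the Wald size at the prior mode
(restarting from zero if that starting point already satisfies the
requirement), which certifies that no smaller satisfying size was skipped.
The WOC assurance is a step function with a sawtooth near its crossing —
outcomes cross the length threshold one at a time — so the literal smallest
satisfying $n$ can be followed by violations a few units higher.  A sample
size recommendation should not be invalidated by adding observations, so for
WOC the returned value is the smallest $n$ from which the requirement holds
for this and every larger size (accepted after 60 consecutive satisfying
sizes); $n - 1$ still violates the requirement.  ALC and ACC crossings were
verified to be stable, so the two definitions coincide there.

## Reporting convention for informative beta priors

The returned `n` is always the number of new sampling locations.  For an
informative beta prior the result additionally reports `n_beyond_prior`,
the size net of the prior's effective sample size $c + d$: the figure to
quote when comparing a design that will *keep* the prior in the final
analysis against the information already in hand.  For example, with the
`Beta(21, 35)` prior elicited below, ALC requires 297 new points, which is
241 beyond the 56 points the prior is worth.  (Counting the prior's worth as
$c + d$ rather than the mode-parameterisation prior sample size $c + d - 2$
follows the source convention for this comparison; the two differ by the two
pseudo-observations of the uniform prior.)

## Elicitation

Four routes to hyperparameters, all in `elicitation.R`:

* `gamma_from_mean_cv(variance, cv)`: sets $\mathrm{E}\lambda = 1/\sigma^2_0$
  and $\mathrm{cv}(\lambda)$ to a chosen trust level; $a = 1/\mathrm{cv}^2$,
  $b = a\sigma^2_0$.  The case-study default `cv = 0.25` (so $a = 16$)
  expresses moderate trust in a legacy variance.
* `beta_from_mode_n0(pi0, n0)`: beta prior with mode at the legacy
  proportion; `n0 = 0` gives the uniform prior.
* `beta_from_quantiles(q_lo, q_hi)` and
  `gamma_from_variance_interval(v_lo, v_hi)`: two-dimensional root finding
  (damped Newton on the log parameters, normal-approximation start,
  Nelder-Mead polish) matching the 2.5% and 97.5% quantiles to an expert's
  plausible interval, to within 1e-6 in quantile space.  Variance intervals
  are inverted into precision intervals first.  The integer-rounded pair is
  reported alongside, and is what a case study quotes; a narrower interval
  must yield a larger $c + d$, which the tests verify.

## The case-study runner

`ssd_tables()` maps a legacy-summary table (district, legacy count, mean and
variance of the log variable, deficient proportion) to the full grid of
sample sizes: frequentist, and \{ALC, ACC, WOC\} × \{fully Bayesian, MBL\},
for the mean (default `lmax = 0.2` on the log scale) and the proportion
(default `lmax = 0.1`).  District priors follow the fixed recipe: gamma from
the legacy variance with `cv_lambda = 0.25`; flat prior on the mean; beta
prior with mode at the legacy proportion and prior sample size
`round(n_legacy / 1000)` (half rounds up) — the divisor keeps the beta prior
from becoming implausibly sharp given that legacy records are noisy and not
a probability sample.  `backtransform_length()` converts a log-scale length
$l$ to the original scale around a log-mean $\mu$ as $l\,e^{\mu}$.  Because
the bundled summaries are printed at two decimals, regenerated table cells
can differ from published ones by a few units; the package's tests allow
±3.  The deficiency threshold itself (0.9 mg/kg) never enters the
computation — the runner consumes proportions, it does not re-threshold raw
records.

## Simulation audits

`audit_mean()` and `audit_prop()` implement the direct forward simulation:
draw the parameter from the prior, simulate a data set of size $n$, compute
the interval, repeat, and average.  Draws from the prior are averaged with
equal weights — that is the plain Monte Carlo estimator of the preposterior
expectations; re-weighting prior draws by the prior density would count the
prior twice.  The audits are the package's independent check on its own
deterministic machinery: the exact binomial sums must lie within a few Monte
Carlo standard errors of the audited averages, and they do in the test
suite.  With a flat prior on the mean the interval geometry is invariant to
the true mean, which the audit fixes at 0.

What the audits emulate is sampling under the model: normal (or binomial)
data, simple random sampling, a correctly specified prior.  They do not
emulate spatial correlation, measurement error, preferential placement of
legacy samples, or non-normality of the untransformed variable — so passing
audits validate the numerics, not the applicability of the model to any
particular survey.

## Problem sizes and runtime choices

The test suite evaluates binomial criteria by exact sums up to $n$ of a few
hundred, compares HPD solvers against grid-search oracles at step 1e-5 to
1e-6, uses 200–4000 replicates in audits, and regenerates the full
13-district tables once; the whole suite runs in a few minutes on one core.
Monte Carlo paths default to $10^5$ draws, enough to pin the mean-case ALC
size to within its unit discreteness at the default precision requirements.

## Limitations

* HPD machinery covers unimodal posteriors only; multimodal or multivariate
  credible regions are out of scope.
* The binomial WOC convention (stable crossing) is one of several defensible
  readings of a non-monotone criterion; the literal pointwise minimum can be
  a few units smaller.
* Robust (multi-prior) designs, criteria on powers of the length, and
  median-based criteria are not implemented.
* The frequentist proportion size is Wald-based; other interval
  constructions would change it at extreme proportions.
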