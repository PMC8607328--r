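## Brute-force oracles, independent of the package's solvers: plain grid
## searches over candidate interval placements using only the
## distribution functions.

## Shortest interval with the given probability content, by grid search
## over the lower bound (upper bound from the quantile function).
grid_hpd_beta <- function(shape1, shape2, coverage, step = 1e-6) {
  v <- seq(0, qbeta(1 - coverage, shape1, shape2), by = step)
  u <- qbeta(pbeta(v, shape1, shape2) + coverage, shape1, shape2)
  i <- which.min(u - v)
  c(lower = v[i], upper = u[i])
}

grid_hpd_t <- function(df, loc, scale, coverage, step = 1e-4) {
  p_lo <- seq(1e-8, 1 - coverage, by = step * (1 - coverage))
  lo <- loc + scale * qt(p_lo, df)
  up <- loc + scale * qt(p_lo + coverage, df)
  i <- which.min(up - lo)
  c(lower = lo[i], upper = up[i])
}

## Maximal content of a fixed-length interval, by grid search over the
## placement.
grid_max_cov_beta <- function(shape1, shape2, l, step = 1e-6) {
  v <- seq(0, 1 - l, by = step)
  max(pbeta(v + l, shape1, shape2) - pbeta(v, shape1, shape2))
}

## Direct small-n implementation of the binomial criterion values using
## the grid oracles (used for brute-force equivalence at n <= 30).
oracle_prop_criterion <- function(n, shape1, shape2, criterion, lmax,
                                  coverage = 0.95, approach = "bayes",
                                  step = 1e-5) {
  z <- 0:n
  w <- exp(lchoose(n, z) + lbeta(z + shape1, n - z + shape2) -
             lbeta(shape1, shape2))
  if (approach == "mbl") {
    s1 <- z + 1
    s2 <- n - z + 1
  } else {
    s1 <- z + shape1
    s2 <- n - z + shape2
  }
  len <- numeric(n + 1)
  cov <- numeric(n + 1)
  for (i in seq_along(z)) {
    h <- grid_hpd_beta(s1[i], s2[i], coverage, step)
    len[i] <- h["upper"] - h["lower"]
    cov[i] <- grid_max_cov_beta(s1[i], s2[i], lmax, step)
  }
  switch(criterion,
         alc = sum(w * len),
         acc = sum(w * cov),
         woc = sum(w[len > lmax]))
}

table1_path <- function() {
  system.file("extdata", "andhra_districts.csv", package = "ssdbayes")
}
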