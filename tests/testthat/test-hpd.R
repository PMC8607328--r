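test_that("scaled-t HPD is symmetric and approaches the normal limit", {
  big <- hpd(scaled_t(df = 1e7), 0.95)
  expect_equal(big$length, 2 * qnorm(0.975), tolerance = 1e-5)

  h <- hpd(scaled_t(df = 5), 0.95)
  expect_equal(h$lower, -h$upper)
  expect_equal(h$length, h$upper - h$lower)
  expect_equal(h$coverage, 0.95)

  ## location/scale equivariance
  h2 <- hpd(scaled_t(df = 5, loc = 3, scale = 2), 0.95)
  expect_equal(h2$length, 2 * h$length)
  expect_equal((h2$lower + h2$upper) / 2, 3)
})

test_that("scaled-t HPD matches a grid-search shortest interval", {
  h <- hpd(scaled_t(df = 32, loc = -0.06, scale = 0.5), 0.95)
  g <- grid_hpd_t(32, -0.06, 0.5, 0.95)
  expect_equal(h$length, unname(g["upper"] - g["lower"]), tolerance = 1e-6)
})

test_that("beta HPD handles flat, symmetric and boundary-mode shapes", {
  ## uniform: any placement works; tie broken at the lower boundary
  u <- hpd(beta_dist(1, 1), 0.95)
  expect_equal(c(u$lower, u$upper), c(0, 0.95))

  ## symmetric density: interval symmetric about 1/2
  s <- hpd(beta_dist(2, 2), 0.9)
  expect_equal(s$lower, 1 - s$upper, tolerance = 1e-9)

  ## monotone densities abut the modal boundary
  lo <- hpd(beta_dist(0.7, 3), 0.9)
  expect_equal(lo$lower, 0)
  expect_equal(lo$upper, qbeta(0.9, 0.7, 3))
  hi <- hpd(beta_dist(3, 1), 0.9)
  expect_equal(hi$upper, 1)

  ## U-shaped: no interval HPD set
  expect_error(hpd(beta_dist(0.5, 0.5), 0.9), "U-shaped")
  et <- hpd(beta_dist(0.5, 0.5), 0.9, equal_tail = TRUE)
  expect_equal(pbeta(et$upper, 0.5, 0.5) - pbeta(et$lower, 0.5, 0.5), 0.9)
})

test_that("beta HPD endpoints agree with the grid-search oracle", {
  h <- hpd(beta_dist(3, 7), 0.95)
  g <- grid_hpd_beta(3, 7, 0.95)
  expect_equal(h$lower, unname(g["lower"]), tolerance = 1e-5)
  expect_equal(h$upper, unname(g["upper"]), tolerance = 1e-5)
  ## endpoint densities equal for an interior mode
  expect_equal(dbeta(h$lower, 3, 7), dbeta(h$upper, 3, 7),
               tolerance = 1e-5)
})

test_that("fixed-length maximal coverage matches direct computations", {
  expect_equal(max_coverage_beta(beta_dist(1, 1), 0.1)$coverage, 0.1)
  expect_equal(max_coverage_beta(beta_dist(2, 2), 1.0)$coverage, 1.0)
  expect_equal(max_coverage_beta(beta_dist(5, 15), 0.2)$coverage,
               grid_max_cov_beta(5, 15, 0.2), tolerance = 1e-6)
})

test_that("HPD numerics agree with grid oracles on randomized shapes", {
  set.seed(42)
  for (i in 1:25) {
    s1 <- runif(1, 1.2, 40)
    s2 <- runif(1, 1.2, 40)
    gamma <- runif(1, 0.5, 0.99)
    h <- hpd(beta_dist(s1, s2), gamma)
    g <- grid_hpd_beta(s1, s2, gamma, step = 1e-5)
    expect_equal(h$length, unname(g["upper"] - g["lower"]),
                 tolerance = 1e-5)
    ## HPD is no longer than the equal-tail interval
    et <- diff(qbeta(c((1 - gamma) / 2, (1 + gamma) / 2), s1, s2))
    expect_lte(h$length, et + 1e-9)

    df <- runif(1, 2, 60)
    sc <- runif(1, 0.1, 2)
    ht <- hpd(scaled_t(df, 0, sc), gamma)
    gt <- grid_hpd_t(df, 0, sc, gamma)
    expect_equal(ht$length, unname(gt["upper"] - gt["lower"]),
                 tolerance = 1e-4 * sc)
  }
})

test_that("length and coverage solvers are monotone and mutually inverse", {
  d <- beta_dist(6, 3)
  lens <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                 function(g) hpd(d, g)$length, 0)
  expect_true(all(diff(lens) > 0))
  covs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                 function(l) max_coverage_beta(d, l)$coverage, 0)
  expect_true(all(diff(covs) > 0))
  ## inverse property: the best interval of the HPD's length recovers
  ## at least the HPD's coverage
  for (g in c(0.5, 0.9, 0.95)) {
    l <- hpd(d, g)$length
    expect_gte(max_coverage_beta(d, l)$coverage, g - 1e-8)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(scaled_t(df = -1), "df")
  expect_error(beta_dist(0, 2))
  expect_error(hpd(scaled_t(5), 1.2), "coverage")
  expect_error(hpd(beta_dist(2, 2), 0), "coverage")
  expect_error(max_coverage_beta(beta_dist(2, 2), -0.1), "lmax")
})
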