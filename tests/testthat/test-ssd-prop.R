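test_that("beta-binomial pmf: uniform prior, empty sample, mass balance", {
  ## uniform prior: all outcomes equally likely
  expect_equal(dbetabinom(0:10, 10, beta_prior(1, 1)), rep(1 / 11, 11))
  expect_equal(dbetabinom(0, 0, beta_prior(3, 2)), 1)
  for (n in c(5, 50, 400)) {
    expect_equal(sum(dbetabinom(0:n, n, beta_prior(6.18, 15.82))), 1,
                 tolerance = 1e-12)
  }
  expect_error(dbetabinom(11, 10, beta_prior(1, 1)), "0..n")
})

test_that("beta-binomial pmf agrees with quadrature over the prior", {
  ## f(z|n) = integral of binomial(z; n, p) * beta(p; c, d) dp
  pr <- beta_from_mode_n0(0.259, 20)   # West Godavari prior
  n <- 100
  direct <- vapply(0:n, function(z) {
    integrate(function(p) dbinom(z, n, p) * dbeta(p, pr$shape1, pr$shape2),
              0, 1, rel.tol = 1e-10)$value
  }, 0)
  expect_equal(dbetabinom(0:n, n, pr), direct, tolerance = 1e-8)
  ## unimodal bump around the prior mode
  expect_equal(which.max(direct) - 1, 26, tolerance = 2)
})

test_that("posterior of the proportion: conjugate and uniform-analysis", {
  pr <- beta_prior(2, 2)
  expect_equal(unclass(posterior_pi(pr, 0, 0))[c("shape1", "shape2")],
               list(shape1 = 2, shape2 = 2))
  p1 <- posterior_pi(pr, 3, 10)
  expect_equal(c(p1$shape1, p1$shape2), c(5, 9))
  p2 <- posterior_pi(pr, 3, 10, approach = "mbl")
  expect_equal(c(p2$shape1, p2$shape2), c(4, 8))
  ## the mixed-approach posterior ignores the prior
  p3 <- posterior_pi(beta_prior(40, 7), 3, 10, approach = "mbl")
  expect_equal(c(p3$shape1, p3$shape2), c(4, 8))
  expect_error(posterior_pi(pr, 11, 10), "0..n")
})

test_that("criterion sums match a brute-force oracle at small n", {
  for (case in list(list(c = 1, d = 1), list(c = 2.5, d = 4))) {
    for (crit in c("alc", "acc", "woc")) {
      for (n in c(10, 25)) {
        got <- ssdbayes:::prop_criterion_value(
          n, beta_prior(case$c, case$d),
          precision_spec(0.4, criterion = crit, worst_level = 0.8))
        want <- oracle_prop_criterion(n, case$c, case$d, crit, 0.4)
        expect_equal(got, want, tolerance = 1e-5)
      }
    }
  }
})

test_that("uniform prior: fully Bayesian and mixed sizes coincide", {
  u <- beta_prior(1, 1)
  for (crit in c("alc", "acc", "woc")) {
    sp_b <- precision_spec(0.2, criterion = crit)
    sp_m <- precision_spec(0.2, criterion = crit, approach = "mbl")
    expect_identical(ssd_prop(u, sp_b)$n, ssd_prop(u, sp_m)$n)
  }
})

test_that("returned proportion sample sizes are minimal", {
  for (case in list(list(pr = beta_prior(1, 1), crit = "alc"),
                    list(pr = beta_prior(6.18, 15.82), crit = "acc"),
                    list(pr = beta_prior(4, 3), crit = "woc"))) {
    sp <- precision_spec(0.2, criterion = case$crit, worst_level = 0.8)
    r <- ssd_prop(case$pr, sp)
    expect_true(ssdbayes:::prop_criterion_ok(
      ssdbayes:::prop_criterion_value(r$n, case$pr, sp), sp))
    if (r$n > 0) {
      expect_false(ssdbayes:::prop_criterion_ok(
        ssdbayes:::prop_criterion_value(r$n - 1L, case$pr, sp), sp))
    }
  }
})

test_that("a near-full-support length requirement needs almost no data", {
  r <- ssd_prop(beta_prior(2, 3), precision_spec(0.999))
  expect_lte(r$n, 1L)
  expect_error(ssd_prop(beta_prior(2, 3), precision_spec(1.2)))
})

test_that("informative-prior results report the prior-credited size", {
  r <- ssd_prop(beta_prior(21, 35), precision_spec(0.1))
  expect_equal(r$n - r$n_beyond_prior, 56L)
  ## uniform prior carries no credit
  expect_null(ssd_prop(beta_prior(1, 1), precision_spec(0.2))$n_beyond_prior)
})
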