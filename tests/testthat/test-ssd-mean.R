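test_that("posterior of the mean: no-data and conjugate updates", {
  pr <- normal_gamma_prior(a = 16, b = 6.56, mu0 = -0.06, n0 = 38)
  marg <- posterior_mu(pr, normal_summary(0))
  expect_equal(marg$df, 32)
  expect_equal(marg$loc, -0.06)
  expect_equal(marg$scale, sqrt(6.56 / (16 * 38)))
  ## the printed prior-predictive scale, to its printed precision
  expect_equal(marg$scale, 0.103, tolerance = 1e-2)

  ## flat prior on the mean and no data: undefined
  expect_error(posterior_mu(normal_gamma_prior(a = 2, b = 1),
                            normal_summary(0)), "undefined")

  ## flat prior with data: location is the sample mean
  po <- posterior_mu(normal_gamma_prior(a = 2, b = 1),
                     normal_summary(5, xbar = 1.3, ss = 2.0))
  expect_equal(po$loc, 1.3)
  expect_equal(po$df, 2 * 2 + 5)
  expect_equal(po$scale, sqrt((1 + 2.0 / 2) / ((2 + 5 / 2) * 5)))
})

test_that("posterior of the mean matches a numerical Bayes computation", {
  pr <- normal_gamma_prior(a = 2, b = 1, mu0 = 0.5, n0 = 3)
  x <- c(0.2, 0.8, 1.1, 0.3)
  n <- length(x)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  post <- posterior_mu(pr, normal_summary(n, xbar, ss))

  ## unnormalised joint, integrated over lambda by quadrature
  marg <- function(mu) {
    vapply(mu, function(m) {
      integrate(function(lam) {
        lam^(pr$a - 1) * exp(-pr$b * lam) * sqrt(lam) *
          exp(-pr$n0 * lam * (m - pr$mu0)^2 / 2) *
          lam^(n / 2) * exp(-lam * (ss + n * (m - xbar)^2) / 2)
      }, 0, Inf, rel.tol = 1e-10)$value
    }, 0)
  }
  mu_grid <- seq(post$loc - 10 * post$scale, post$loc + 10 * post$scale,
                 length.out = 201)
  dens_num <- marg(mu_grid)
  dx <- diff(mu_grid[1:2])
  total <- sum((dens_num[-1] + dens_num[-length(dens_num)]) / 2) * dx
  dens_num <- dens_num / total
  dens_t <- dt((mu_grid - post$loc) / post$scale, post$df) / post$scale
  expect_equal(dens_num, dens_t, tolerance = 1e-3)
})

test_that("ACC closed form matches the numerical ACC search exactly", {
  for (pr in list(normal_gamma_prior(a = 16, b = 11.2),
                  normal_gamma_prior(a = 94, b = 68),
                  normal_gamma_prior(a = 4, b = 3, mu0 = 0, n0 = 10))) {
    closed <- n_mean_acc_closed(pr, 0.2)
    searched <- ssd_mean(pr, precision_spec(0.2, criterion = "acc"))
    expect_equal(searched$n, closed)
  }
  ## a strong enough prior needs no new data
  expect_equal(n_mean_acc_closed(
    normal_gamma_prior(a = 16, b = 11.2, n0 = 1e6), 0.2), 0L)
})

test_that("returned mean sample sizes are minimal", {
  pr <- normal_gamma_prior(a = 16, b = 11.2)
  for (crit in c("alc", "acc", "woc")) {
    for (ap in c("bayes", "mbl")) {
      sp <- precision_spec(0.2, criterion = crit, approach = ap)
      r <- ssd_mean(pr, sp)
      val_at <- function(n) switch(crit,
        alc = if (ap == "mbl") ssdbayes:::alc_mean_mbl(n, 16, 11.2, 0.95)
              else ssdbayes:::alc_mean_bayes(n, 16, 11.2, 0.95),
        acc = if (ap == "mbl") {
                ssdbayes:::acc_mean_mbl(n, 16, 11.2, 0.95, 0.2)
              } else {
                ssdbayes:::acc_mean_bayes(n, 16, 11.2, 0.95, 0.2)
              },
        woc = ssdbayes:::woc_mean_len(n, 16, 11.2, 0.95, 0.8,
                                      mbl = (ap == "mbl")))
      if (crit == "acc") {
        expect_gte(val_at(r$n), 0.95)
        expect_lt(val_at(r$n - 1L), 0.95)
      } else {
        expect_lte(val_at(r$n), 0.2)
        expect_gt(val_at(r$n - 1L), 0.2)
      }
    }
  }
})

test_that("mixed and fully Bayesian ALC sizes differ by at most 2 at n0=0", {
  for (pr in list(normal_gamma_prior(a = 16, b = 11.2),
                  normal_gamma_prior(a = 94, b = 68),
                  normal_gamma_prior(a = 16, b = 6.56))) {
    fb <- ssd_mean(pr, precision_spec(0.2, criterion = "alc"))$n
    ml <- ssd_mean(pr, precision_spec(0.2, criterion = "alc",
                                      approach = "mbl"))$n
    expect_gte(ml - fb, 0L)
    expect_lte(ml - fb, 2L)
  }
})

test_that("WOC brackets ALC as the worst level moves through 0.5 and 0.8", {
  pr <- normal_gamma_prior(a = 16, b = 11.2)
  alc <- ssd_mean(pr, precision_spec(0.2, criterion = "alc"))$n
  w50 <- ssd_mean(pr, precision_spec(0.2, criterion = "woc",
                                     worst_level = 0.5))$n
  w80 <- ssd_mean(pr, precision_spec(0.2, criterion = "woc",
                                     worst_level = 0.8))$n
  expect_lte(w50, alc)
  expect_lte(alc, w80)
})

test_that("a sharp precision prior recovers the frequentist size", {
  ## cv(lambda) -> 0 with the precision mean a/b = 1/sigma^2 held fixed
  sigma2 <- 0.70
  n_freq <- n_mean_freq(sqrt(sigma2), 0.2)
  for (crit in c("alc", "acc")) {
    ns <- vapply(c(1e2, 1e4, 1e6), function(a) {
      pr <- normal_gamma_prior(a = a, b = a * sigma2)
      ssd_mean(pr, precision_spec(0.2, criterion = crit))$n
    }, 0L)
    expect_true(all(diff(abs(ns - n_freq)) <= 0))
    expect_lte(abs(ns[3] - n_freq), 1L)
  }
})

test_that("informative mean priors reduce the required size", {
  pr0 <- normal_gamma_prior(a = 16, b = 11.2, n0 = 0)
  pr50 <- normal_gamma_prior(a = 16, b = 11.2, mu0 = 0, n0 = 50)
  n0v <- ssd_mean(pr0, precision_spec(0.2, criterion = "alc"))$n
  n50 <- ssd_mean(pr50, precision_spec(0.2, criterion = "alc"),
                  draws = 2e4, seed = 3)$n
  expect_lt(n50, n0v)
  ## Monte Carlo path reports its uncertainty
  r <- ssd_mean(pr50, precision_spec(0.2, criterion = "alc"),
                draws = 2e4, seed = 3)
  expect_gt(r$mc_error, 0)
  ## identical seed, identical result
  r2 <- ssd_mean(pr50, precision_spec(0.2, criterion = "alc"),
                 draws = 2e4, seed = 3)
  expect_identical(r$n, r2$n)
  expect_identical(r$achieved, r2$achieved)
})
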