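test_that("passenger rate m0 is calibrated from synonymous counts", {
  expect_equal(as.numeric(estimate_m0(10, 300, 100, 100)), 0.3)
  fb <- estimate_m0(0, 300, 100, 100, cohort_syn_rate = 0.05)
  expect_true(attr(fb, "s_fallback"))
  expect_equal(as.numeric(fb), 0.05 * 300 / 100)
  expect_error(estimate_m0(0, 300, 100, 100), "cohort_syn_rate")
})

test_that("mixture pmf matches its components and normalizes", {
  z <- 0:30
  expect_equal(mixture_pmf(z, 0.3, NA, 0, 1.51), dpois(z, 0.3))
  expect_equal(mixture_pmf(0, 0.1, 5, 0.01, 1.51), 0.8969, tolerance = 1e-4)
  zz <- 0:ceiling(10 * (5 + 10))
  expect_equal(sum(mixture_pmf(zz, 0.1, 5, 0.01, 1.51)), 1, tolerance = 1e-9)
  expect_error(mixture_pmf(-1, 0.1, 5, 0.01, 1.51), "nonnegative")
})

test_that("large gamma shape collapses the driver component to Poisson", {
  z <- 0:200
  tv <- 0.5 * sum(abs(mixture_pmf(z, 0.1, 5, 1, 1e6) - dpois(z, 5)))
  expect_lt(tv, 1e-3)
})

test_that("printed moment estimates reproduce the closed-form example", {
  est <- mom_estimates(0.149, 0.552263, 0.1, 1.51)
  expect_equal(est$m1, 5.0805, tolerance = 1e-4)
  expect_equal(est$eta, 0.00984, tolerance = 1e-3)
  expect_false(est$truncated)

  # mean at the passenger rate: no driver component
  e0 <- mom_estimates(0.1, 0.25, 0.1, 1.51)
  expect_equal(e0$eta, 0)

  # var == mean degenerate case: eta truncated to 1 and flagged
  ed <- mom_estimates(0.2, 0.2, 0.1, 1.51)
  expect_equal(ed$m1, (0 + 0.2 + 0.1 / 1.51) / (1 + 1 / 1.51), tolerance = 1e-9)
  expect_equal(ed$eta, 1)
  expect_true(ed$truncated)
})

test_that("exact moment inversion recovers parameters to machine precision", {
  est <- mom_estimates(0.149, 0.552263, 0.1, 1.51, method = "exact")
  expect_equal(est$m1, 5, tolerance = 1e-4)
  expect_equal(est$eta, 0.01, tolerance = 1e-4)

  set.seed(91)
  for (i in 1:200) {
    m0 <- runif(1, 0.01, 0.5)
    alpha <- runif(1, 0.2, 5)
    eta <- runif(1, 0.001, 0.5)
    m1 <- m0 + runif(1, 0.5, 10)
    mm <- analytic_moments(eta, m0, m1, alpha)
    est <- mom_estimates(mm["mean"], mm["var"], m0, alpha, method = "exact")
    expect_equal(est$m1, m1, tolerance = 1e-8)
    expect_equal(est$eta, eta, tolerance = 1e-8)
  }
})

test_that("printed formula stays within 5% of eta when m1 >= 20 m0 at alpha 1.51", {
  set.seed(92)
  worst <- 0
  for (i in 1:300) {
    m0 <- runif(1, 0.01, 0.3)
    eta <- runif(1, 0.001, 0.3)
    m1 <- m0 * runif(1, 20, 100)
    mm <- analytic_moments(eta, m0, m1, 1.51)
    est <- mom_estimates(mm["mean"], mm["var"], m0, 1.51)
    worst <- max(worst, abs(est$eta - eta) / eta)
  }
  expect_lt(worst, 0.05)
})

test_that("global alpha fit flags cohorts without overdispersion", {
  # pure-Poisson counts: either no gene is eligible (fallback to 1.51) or the
  # few chance-overdispersed genes push alpha to the search boundary
  set.seed(93)
  sim <- simulate_site_counts(30, 200, 0, 0.1, NA, 1.51)
  fit <- suppressWarnings(fit_alpha_global(sim$z, rep(0.1, 30)))
  expect_true(fit$boundary || fit$fallback)

  # genes that are all strictly non-overdispersed force the fallback
  z_flat <- replicate(5, rep(1L, 50), simplify = FALSE)
  expect_warning(fit2 <- fit_alpha_global(z_flat, rep(0.5, 5)), "falls back")
  expect_true(fit2$fallback)
  expect_equal(fit2$alpha, 1.51)
})

test_that("per-gene profile variant of the alpha fit also runs", {
  set.seed(94)
  sim <- simulate_site_counts(40, 300, 0.02, 0.1, 5, 1.51)
  fit <- fit_alpha_global(sim$z, rep(0.1, 40), profile = "per_gene")
  expect_false(fit$fallback)
  expect_true(fit$alpha > 0.05 && fit$alpha < 100)
})

test_that("driver-component LRT behaves at the null and under strong signal", {
  # no excess mean: statistic 0, p 1
  set.seed(95)
  z0 <- rpois(300, 0.1)
  r0 <- lrt_eta(z0, mean(z0) + 0.05, 1.51)
  expect_equal(r0$lrt_stat, 0)
  expect_equal(r0$lrt_p, 1)

  # one recurrent hotspot among passengers: decisively significant
  z <- rpois(500, 0.1)
  z[17] <- 20L
  expect_lt(lrt_eta(z, 0.1, 1.51)$lrt_p, 1e-4)
  expect_lt(lrt_eta(z, 0.1, 1.51, method = "ml")$lrt_p, 1e-4)

  # permutation invariance of the statistic
  r1 <- lrt_eta(z, 0.1, 1.51)
  r2 <- lrt_eta(sample(z), 0.1, 1.51)
  expect_equal(r1$lrt_stat, r2$lrt_stat)

  # the literal fixed-m0 null equals its hand-built construction
  est <- mom_estimates(mean(z), selscape:::.pop_var(z), 0.1, 1.51)
  l1 <- sum(mixture_pmf(z, 0.1, est$m1, est$eta, 1.51, log = TRUE))
  l0 <- sum(dpois(z, 0.1, log = TRUE))
  rm0 <- lrt_eta(z, 0.1, 1.51, null = "m0")
  expect_equal(rm0$lrt_stat, max(0, 2 * (l1 - l0)), tolerance = 1e-9)
  expect_equal(rm0$lrt_p, 0.5 * pchisq(rm0$lrt_stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # chi-square(2) reference is the more conservative configurable option
  r3 <- lrt_eta(z, 0.1, 1.51, df = "chisq2")
  expect_equal(r3$lrt_p, pchisq(r3$lrt_stat, 2, lower.tail = FALSE))
})

test_that("fit_mixture reports the implied gamma scale", {
  set.seed(96)
  z <- rpois(400, 0.1)
  z[c(5, 50)] <- c(8L, 12L)
  fit <- fit_mixture(z, 0.1, 1.51)
  expect_s3_class(fit, "mixture_fit")
  expect_true(fit$eta > 0)
  expect_equal(fit$beta, 1.51 / (fit$m1 - fit$m0))
  expect_equal(fit$loglik,
               sum(mixture_pmf(z, fit$m0, fit$m1, fit$eta, fit$alpha,
                               log = TRUE)))
})
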