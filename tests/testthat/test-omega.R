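test_that("component selection ratios match hand evaluation", {
  expect_equal(as.numeric(omega_pass(30, 10, 300, 100)), 1)
  expect_equal(as.numeric(omega_pass(0, 10, 300, 100)), 0)
  ss0 <- omega_pass(5, 0, 300, 100)
  expect_true(attr(ss0, "ss_substituted"))
  expect_true(is.na(omega_pass(0, 0, 300, 100)))

  od <- omega_dri(100, 10, 30, 10, 0.01, 300, 100)
  expect_equal(od$ns_star, 703, tolerance = 1e-9)
  expect_equal(od$omega_dri, 703 / 3, tolerance = 1e-9)
  expect_false(od$floored)
  expect_error(omega_dri(100, 10, 30, 10, 0, 300, 100), "eta")

  # negative adjusted ratio floored at zero with a flag
  od2 <- omega_dri(5, 10, 30, 10, 0.01, 300, 100)
  expect_true(od2$floored)
  expect_equal(od2$omega_dri, 0)
})

test_that("the component decomposition identity holds over random configurations", {
  set.seed(61)
  checked <- 0
  while (checked < 1000) {
    S <- sample(1:30, 1); N <- sample(0:200, 1)
    S_S <- sample(seq_len(S), 1); S_N <- if (N > 0) sample(seq_len(N), 1) else 0
    eta <- runif(1, 0.001, 0.999)
    L_N <- runif(1, 50, 2000); L_S <- runif(1, 20, 800)
    od <- omega_dri(N, S, S_N, S_S, eta, L_N, L_S)
    if (od$floored) next
    op <- as.numeric(omega_pass(S_N, S_S, L_N, L_S))
    cncs <- as.numeric(compute_cncs(N, S, L_N, L_S))
    expect_equal((1 - eta) * op + eta * od$omega_dri, cncs, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_equal(checked, 1000)
})

test_that("the passenger test is one-sided toward a deficit of mutated sites", {
  # exact null fit but deviation direction undefined -> never significant
  t0 <- omega_pass_test(30, 10, 300, 100)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p.value, 0.5)

  t1 <- omega_pass_test(20, 20, 300, 100)
  expect_equal(t1$statistic, 40 / 3, tolerance = 1e-6)
  expect_equal(t1$p.value, 0.0001303648, tolerance = 1e-4)

  expect_lt(omega_pass_test(0, 10, 300, 100)$p.value, 1e-3)

  # excess (not deficit) of nonsynonymous sites is never significant
  t2 <- omega_pass_test(39, 1, 300, 100)
  expect_gte(t2$p.value, 0.5)
})

test_that("site posteriors follow Bayes' rule and are monotone in the count", {
  expect_equal(site_posterior(0:10, 0.1, 5, 0, 1.51), rep(0, 11))
  expect_equal(site_posterior(0:10, 0.1, 5, 1, 1.51), rep(1, 11))
  expect_equal(site_posterior(3, 0.1, 5, 0.01, 1.51), 0.881, tolerance = 1e-3)
  q <- site_posterior(0:20, 0.1, 5, 0.01, 1.51)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("site-specific ratios interpolate between the components", {
  expect_equal(omega_site(2, 0, 1.51, 5, 0.8, 100), 0.8)
  expect_equal(omega_site(5, 1, 1.51, 5, 0.8, 100), 100)   # z = m1, Q = 1
  expect_equal(omega_site(3, 0.8811, 1.51, 5, 1, 234.33), 143.2,
               tolerance = 1e-3)
  # convex-combination bound
  set.seed(62)
  for (i in 1:50) {
    zk <- sample(0:15, 1); Q <- runif(1)
    op <- runif(1, 0, 2); od <- runif(1, 0, 300)
    shrunk <- ((zk + 1.51) / (5 + 1.51)) * od
    ok <- omega_site(zk, Q, 1.51, 5, op, od)
    expect_gte(ok, min(op, shrunk) - 1e-12)
    expect_lte(ok, max(op, shrunk) + 1e-12)
  }
})

test_that("posterior mass averages back to the driver fraction on model data", {
  set.seed(63)
  sim <- simulate_site_counts(1, 20000, 0.02, 0.1, 5, 1.51)
  q <- site_posterior(sim$z[[1]], 0.1, 5, 0.02, 1.51)
  expect_equal(mean(q), 0.02, tolerance = 0.25)
})

test_that("omega_decompose bundles the gene-level decomposition", {
  counts <- list(N = 100, S = 10, S_N = 30, S_S = 10,
                 z = c(rep(0L, 96), 40L, 30L, 20L, 10L))
  fit <- structure(list(m0 = 0.1, m1 = 5, eta = 0.01, alpha = 1.51),
                   class = "mixture_fit")
  om <- omega_decompose(counts, fit, 300, 100)
  expect_equal(om$omega_pass, 1)
  expect_equal(om$omega_dri, 703 / 3, tolerance = 1e-9)
  expect_equal(nrow(om$sites), 100)
  expect_true(all(om$sites$Q_k >= 0 & om$sites$Q_k <= 1))
})
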