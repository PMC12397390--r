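test_that("Mann-Whitney U follows the exact two-sided convention", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1) # 2 / choose(6, 3)
  expect_identical(r$method, "exact")

  # identical multisets: no separation, p = 1
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_true(same$ties)
})

test_that("MWU p-values equal full enumeration at the study sizes", {
  set.seed(40)
  for (sizes in list(c(4, 4), c(5, 10))) {
    for (rep in 1:3) {
      a <- rnorm(sizes[1])
      b <- rnorm(sizes[2], 0.8)
      r <- mann_whitney_u(a, b)
      expect_identical(r$method, "exact")
      expect_equal(r$p, oracle_mwu_p(a, b), tolerance = 1e-12)
    }
  }
})

test_that("Kolmogorov-Smirnov statistic and exact p behave correctly", {
  same <- kolmogorov_smirnov(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  sep <- kolmogorov_smirnov(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 1)

  set.seed(41)
  a <- rnorm(5)
  b <- rnorm(10, 0.5)
  r <- kolmogorov_smirnov(a, b)
  expect_equal(r$statistic, oracle_ks_D(a, b), tolerance = 1e-12)
  expect_identical(r$method, "exact")
})

test_that("BWS statistic matches the literal two-sum formulation", {
  sep <- bws_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, oracle_bws_B(1:3, 4:6), tolerance = 1e-12)
  # both extreme assignments achieve the maximal B: p = 2/20
  expect_equal(sep$p, 0.1)

  inter <- bws_test(c(1, 3, 5), c(2, 4, 6))
  expect_lt(inter$statistic, 0.5)
  expect_gt(inter$p, 0.5)
  expect_equal(inter$p, oracle_bws_p(c(1, 3, 5), c(2, 4, 6)),
    tolerance = 1e-12
  )
})

test_that("BWS permutation p equals full enumeration at 4v4 and 5v10", {
  set.seed(42)
  for (sizes in list(c(4, 4), c(5, 10))) {
    for (rep in 1:2) {
      a <- rnorm(sizes[1])
      b <- rnorm(sizes[2], 1)
      r <- bws_test(a, b)
      expect_identical(r$method, "exact_permutation")
      expect_equal(r$p, oracle_bws_p(a, b), tolerance = 1e-12)
    }
  }
})

test_that("BWS handles ties by midranks and flags them", {
  a <- c(1, 2, 2, 3)
  b <- c(2, 4, 5, 6)
  r <- bws_test(a, b)
  expect_true(r$ties)
  expect_equal(r$statistic, oracle_bws_B(a, b), tolerance = 1e-12)
  expect_equal(r$p, oracle_bws_p(a, b), tolerance = 1e-12)
})

test_that("BWS Monte Carlo and asymptotic paths are sane", {
  set.seed(43)
  a <- rnorm(5)
  b <- rnorm(10, 1.2)
  exact <- bws_test(a, b, method = "exact_permutation")
  mc <- bws_test(a, b, method = "monte_carlo", n_mc = 4000)
  expect_lt(abs(mc$p - exact$p), 0.03)

  # the asymptotic path is refused below pooled n = 20
  expect_error(bws_test(a, b, method = "asymptotic"), "refused")

  # classical critical value of the limiting distribution
  expect_equal(bws_asymptotic_cdf(2.4924), 0.95, tolerance = 1e-3)
  expect_equal(bws_asymptotic_cdf(1.9330), 0.90, tolerance = 1e-3)

  # at moderate sizes the asymptotic p tracks the permutation p
  set.seed(44)
  x <- rnorm(15)
  y <- rnorm(15, 0.9)
  pa <- bws_test(x, y, method = "asymptotic")$p
  pm <- bws_test(x, y, method = "monte_carlo", n_mc = 20000)$p
  expect_lt(abs(pa - pm), 0.02)
})

test_that("rank tests are invariant under monotone transformations", {
  set.seed(45)
  a <- rnorm(5)
  b <- rnorm(10, 0.6)
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    expect_equal(mann_whitney_u(f(a), f(b))$p, mann_whitney_u(a, b)$p)
    expect_equal(kolmogorov_smirnov(f(a), f(b))$p, kolmogorov_smirnov(a, b)$p)
    expect_equal(bws_test(f(a), f(b))$p, bws_test(a, b)$p)
  }
})

test_that("Holm adjustment is the literal step-down product", {
  h <- holm_bonferroni(c(0.013, 0.018, 0.019))
  expect_equal(h$p_adjusted, c(0.039, 0.036, 0.019))
  expect_true(all(h$significant))
  # the largest raw p is returned unchanged (no monotonization)
  expect_equal(h$p_adjusted[3], h$p[3])

  h2 <- holm_bonferroni(c(0.019, 0.032, 0.061))
  expect_equal(h2$p_adjusted, c(0.057, 0.064, 0.061))
  expect_false(any(h2$significant))

  single <- holm_bonferroni(0.04)
  expect_equal(single$p_adjusted, 0.04)
  expect_true(single$significant)
})

test_that("Holm decisions follow the sequential stop rule", {
  # adjusted: 0.003, 0.06, 0.04 -> the second stops the sequence even
  # though the third drops below alpha again
  h <- holm_bonferroni(c(0.001, 0.03, 0.04))
  expect_equal(h$p_adjusted, c(0.003, 0.06, 0.04))
  expect_identical(h$significant, c(TRUE, FALSE, FALSE))

  # adjusted values are capped at 1 and flagged
  h2 <- holm_bonferroni(c(0.8, 0.9))
  expect_equal(h2$p_adjusted, c(1, 0.9))
  expect_identical(h2$capped, c(TRUE, FALSE))

  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_bonferroni(0.02, alpha = 1.5), "alpha")
})

test_that("Holm invariants hold on random batteries", {
  set.seed(46)
  for (k in 1:20) {
    p <- runif(sample(2:6, 1))
    h <- holm_bonferroni(p)
    # adjusted >= raw everywhere; max raw unchanged
    expect_true(all(h$p_adjusted >= h$p - 1e-15))
    expect_equal(h$p_adjusted[length(p)], max(p))
    # significance is a prefix of the sorted battery
    sig <- h$significant
    expect_true(all(diff(sig) <= 0))
  }
})

test_that("Welch test matches the closed form and rejects degenerate input", {
  r <- welch_t_test(c(0, 1), c(10, 11))
  expect_equal(r$statistic, -10 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(r$df, 2, tolerance = 1e-10)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t_test(c(2, 2), c(2, 2)), "constant")
})

test_that("severity correlation reports Pearson and Spearman", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlate_severity(x * 2 + 1, x)
  expect_equal(r$statistic, 1)

  y <- exp(x)
  r2 <- correlate_severity(y, x)
  expect_equal(r2$spearman_rho, 1)
  expect_lt(r2$statistic, 1)

  expect_error(correlate_severity(rep(1, 5), x), "constant")
  expect_error(correlate_severity(1:4, 1:5), "equal length")

  # independent pairs at the study size carry no systematic correlation
  set.seed(47)
  rs <- replicate(1000, correlate_severity(rnorm(13), rnorm(13))$statistic)
  expect_lt(abs(mean(rs)), 0.1)
})
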