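# Pleiotropy tests: product-of-Z-scores (approximate and plug-in mixture),
# Sobel, maxP, and genome-wide nuisance-parameter estimation.

test_that("Wald Z-scores and two-sided p-values behave as expected", {
  expect_equal(compute_z(0, 0.1), 0)
  expect_equal(compute_z(0.3, 0.1), -compute_z(-0.3, 0.1))
  expect_error(compute_z(1, 0), "positive")
  expect_error(compute_z(1, -1), "positive")

  # reconstructing the Z implied by a reported (beta, p) pair: a trait-1
  # effect of -0.0316 with two-sided p = 6.8e-5 pins down the consistent se
  z_implied <- qnorm(6.8e-5 / 2)           # negative effect
  se <- 0.0316 / abs(z_implied)
  expect_equal(compute_z(-0.0316, se), z_implied, tolerance = 1e-12)
  expect_equal(p_from_z(compute_z(-0.0316, se)), 6.8e-5, tolerance = 1e-10)

  expect_equal(p_from_z(0), 1)
  expect_equal(p_from_z(1.959964), 0.05, tolerance = 1e-6)
  expect_true(is.finite(p_from_z(40, log.p = TRUE)))
  expect_lt(p_from_z(40, log.p = TRUE), -700)
})

test_that("Sobel statistic, tail and conventions", {
  r <- sobel_test(3, 4)
  expect_equal(r$statistic, 2.4)
  expect_equal(r$p_value, 2 * pnorm(-2.4), tolerance = 1e-12)

  expect_equal(sobel_test(0, 5)$statistic, 0)
  expect_equal(sobel_test(0, 5)$p_value, 1)

  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(sobel_test(a, b)$p_value, sobel_test(b, a)$p_value)

  expect_equal(sobel_test(0, 0)$p_value, 1)       # continuity convention
  expect_true(is.nan(sobel_test(0, 0, zero = "nan")$statistic))
})

test_that("maxP is the maximum single-trait p-value", {
  expect_equal(maxp_test(0.01, 0.2)$p_value, 0.2)
  expect_equal(maxp_test(0.37, 0.37)$p_value, 0.37)
  expect_equal(maxp_test(0, 1)$p_value, 1)
  expect_error(maxp_test(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(maxp_test(0.5, 1.2), "\\[0, 1\\]")
})

test_that("marginal variance estimation: null calibration, floor, retention", {
  set.seed(42)
  z1 <- rnorm(1e6); z2 <- rnorm(1e6)
  v <- estimate_marginal_variances(z1, z2)
  expect_gte(v$v1, 0.995); expect_lte(v$v1, 1.005)
  expect_gte(v$v2, 0.995); expect_lte(v$v2, 1.005)

  # sampled mean-square below 1 is floored at exactly 1
  set.seed(7)
  zs <- rnorm(20000, sd = 0.9)
  v2 <- estimate_marginal_variances(zs, rnorm(20000))
  expect_identical(v2$v1, 1)

  # only doubly-significant variants are excluded: one-trait hits retained
  z_hit <- c(rep(8, 500), rnorm(20000))       # strong trait-1-only signals
  z_oth <- c(rep(0, 500), rnorm(20000))
  v3 <- estimate_marginal_variances(z_hit, z_oth)
  expect_gt(v3$v1, 1.5)
  expect_equal(v3$n_used, 20500L)

  expect_error(estimate_marginal_variances(1, 1), "at least 2")
  expect_warning(estimate_marginal_variances(rnorm(100), rnorm(100)),
                 "genome-wide")
})

test_that("product test reduces to the plain product tail at unit variances", {
  z1 <- c(0, 1.3, -2.2, 3, 6)
  z2 <- c(2.0, 0, 1.1, 4, 5.5)
  r <- placo(z1, z2)
  expect_equal(r$log_p, normprod_tail(z1 * z2)$log_tail)
  expect_equal(r$p_value[z1 * z2 == 0], c(1, 1))
})

test_that("product test p-value grows with the marginal variances and is
           symmetric under sign flips and trait swaps", {
  z1 <- 2.5; z2 <- -3.1
  vs <- seq(1, 2, by = 0.1)
  p_v1 <- sapply(vs, function(v) placo(z1, z2, c(v, 1))$p_value)
  p_v2 <- sapply(vs, function(v) placo(z1, z2, c(1, v))$p_value)
  expect_true(all(diff(p_v1) > 0))
  expect_true(all(diff(p_v2) > 0))

  v <- c(1.04, 1.12)
  expect_equal(placo(z1, z2, v)$p_value, placo(-z1, z2, v)$p_value)
  expect_equal(placo(z1, z2, v)$p_value, placo(z1, -z2, v)$p_value)
  expect_equal(placo(z1, z2, v)$p_value, placo(z2, z1, rev(v))$p_value)

  expect_error(placo(1, 1, c(0.9, 1)), ">= 1")
})

test_that("a strong two-trait signal gives a product p-value below the
           single-trait-implied bound", {
  # trait 1: negative effect, p = 6.8e-5; trait 2: positive effect, p = 8.5e-9
  z1 <- qnorm(6.8e-5 / 2)
  z2 <- qnorm(8.5e-9 / 2, lower.tail = FALSE)
  p <- placo(z1, z2)$p_value
  expect_lt(p, 2.8e-9)
  # variance inflation only increases the p-value
  expect_gt(placo(z1, z2, c(1.05, 1.05))$p_value, p)
})

test_that("plug-in mixture evaluation degenerates correctly", {
  z1 <- c(1.5, 0, -2); z2 <- c(2.5, 3, 1)

  prm <- mixture_params(1, 0, 0)
  expect_equal(placo_exact(z1, z2, prm)$log_p,
               normprod_tail(z1 * z2)$log_tail)

  prm2 <- mixture_params(0.9, 0.05, 0.04, tau1_sq = 2, tau2_sq = 3)
  expect_equal(placo_exact(0, 4, prm2)$p_value, 0.9 + 0.05 + 0.04)

  prm3 <- mixture_params(0.7, 0.2, 0.05, 0, 0)   # scales coincide
  expect_equal(placo_exact(z1, z2, prm3)$p_value,
               pmin(1, 0.95 * normprod_tail(z1 * z2)$tail))

  expect_error(mixture_params(0.8, 0.3, 0.2), "sum")
  expect_error(mixture_params(0.5, 0.1, 0.1, tau1_sq = -1), "nonnegative")
})

test_that("composite-null error control holds with on-model hierarchical
           single-trait effects", {
  # moderate effect dispersion: the asymptotic approximation is valid for
  # small-to-moderate single-trait effects (the regime the hygiene filters
  # target); calibration is expected to degrade for much larger tau^2
  cfg <- sim_config(m_variants = 5e5,
                    class_proportions = c(0.995, 0.005, 0, 0),
                    effect_dist = "normal", tau2_sq = 2,
                    mode = "fast", seed = 61)
  s <- simulate_sumstats(cfg)
  vz <- estimate_marginal_variances(s$z1, s$z2, s$p1, s$p2)
  a <- 1e-4
  rate <- mean(placo(s$z1, s$z2, vz)$p_value < a)
  expect_lte(rate, a + 3 * sqrt(a * (1 - a) / 5e5))
})

test_that("mixture parameters are recovered from genome-scale input", {
  # all-null input: tiny pi estimates on the misclassification scale, tau ~ 0
  set.seed(11)
  z1 <- rnorm(2e5); z2 <- rnorm(2e5)
  est <- estimate_mixture_params(z1, z2)
  expect_lt(est$pi01, 5e-4)
  expect_lt(est$pi02, 5e-4)
  expect_lt(est$tau1_sq, 30)   # tau over misclassified nulls stays modest
  expect_gt(est$pi00, 0.999)

  # planted single-trait associations with near-complete power at the
  # classification threshold: class proportions recovered within 20%
  cfg <- sim_config(m_variants = 3e5,
                    class_proportions = c(0.991, 0.005, 0.004, 0),
                    or1 = 2.39, or2 = 2.39, mode = "fast", seed = 5)
  s <- simulate_sumstats(cfg)
  est2 <- estimate_mixture_params(s$z1, s$z2)
  expect_lt(abs(est2$pi01 / 0.005 - 1), 0.2)
  expect_lt(abs(est2$pi02 / 0.004 - 1), 0.2)

  # consistency with the degenerate plug-in evaluation on null-only input
  pe <- placo_exact(2, 2, est)
  expect_equal(pe$p_value, est$pi00 * normprod_tail(4)$tail, tolerance = 0.05)
})
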