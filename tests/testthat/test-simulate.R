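# Two-trait simulator: class assignment arithmetic, intercept calibration,
# individual-level case-control and quantitative generators, fast asymptotic
# mode, and agreement between the routes.

test_that("class assignment is exact largest-remainder arithmetic", {
  cfg <- sim_config(m_variants = 1000, class_proportions = c(1, 0, 0, 0))
  expect_equal(as.vector(table(assign_variant_classes(cfg))),
               c(1000L, 0L, 0L, 0L))

  # counts always sum to m for random proportion vectors
  set.seed(4)
  for (i in 1:25) {
    p <- runif(4); p <- p / sum(p)
    m <- sample(10:99991, 1)
    cfg <- sim_config(m_variants = m, class_proportions = p)
    cls <- assign_variant_classes(cfg)
    expect_equal(length(cls), m)
    counts <- table(cls)
    expect_true(all(abs(counts - m * p) <= 1))
  }
})

test_that("logistic intercept matches the target marginal prevalence", {
  expect_equal(solve_intercept(0.15, 0.05, 0), qlogis(0.15), tolerance = 1e-10)

  a <- solve_intercept(0.10, 0.05, log(1.15))
  gx <- dbinom(0:2, 2, 0.05)
  expect_equal(sum(gx * plogis(a + log(1.15) * (0:2))), 0.10, tolerance = 1e-8)

  # intercept decreases as prevalence decreases, at fixed effect
  expect_gt(solve_intercept(0.15, 0.05, log(1.15)),
            solve_intercept(0.10, 0.05, log(1.15)))
  expect_error(solve_intercept(0, 0.05, 0), "\\(0, 1\\)")
})

test_that("count-table Newton fits agree with glm logistic regression", {
  set.seed(8)
  for (i in 1:20) {
    cc <- rmultinom(1, 500, c(0.5, 0.35, 0.15))[, 1]
    ct <- rmultinom(1, 700, c(0.6, 0.3, 0.1))[, 1]
    fit <- pleioz:::.logistic_fit_counts(matrix(cc, 1), matrix(ct, 1))
    d <- data.frame(y = rep(c(1, 0), each = 3), x = rep(0:2, 2),
                    w = c(cc, ct))
    g <- suppressWarnings(glm(y ~ x, family = binomial, weights = w, data = d,
                              control = glm.control(epsilon = 1e-12,
                                                    maxit = 100)))
    expect_equal(fit$beta, unname(coef(g)[2]), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(diag(vcov(g)))[2]), tolerance = 1e-6)
  }
})

test_that("case-control generator: null calibration and effect direction", {
  cfg <- sim_config(m_variants = 20000, class_proportions = c(1, 0, 0, 0),
                    mode = "individual", seed = 303)
  s <- simulate_case_control_pair(cfg)
  # single-trait Wald test calibrated at alpha = 0.05, within 3 binomial SDs
  band <- 3 * sqrt(0.05 * 0.95 / 20000)
  expect_lt(abs(mean(s$p1 < 0.05) - 0.05), band)
  expect_lt(abs(mean(s$p2 < 0.05) - 0.05), band)
  # independent studies: null Z-scores uncorrelated
  expect_lt(abs(cor(s$z1, s$z2)), 3 / sqrt(20000))

  cfg2 <- sim_config(m_variants = 2000, class_proportions = c(0, 0, 0, 1),
                     or1 = 1.15, or2 = 1.15, mode = "individual", seed = 5)
  s2 <- simulate_case_control_pair(cfg2)
  expect_gt(mean(s2$z1), 0)
  expect_gt(mean(s2$z2), 0)

  cfg3 <- sim_config(m_variants = 2000, class_proportions = c(0, 0, 0, 1),
                     or1 = 1 / 1.15, or2 = 1.15, mode = "individual", seed = 5)
  s3 <- simulate_case_control_pair(cfg3)
  expect_lt(mean(s3$z1), 0)
})

test_that("shared controls induce the analytic Z-score correlation", {
  cfg <- sim_config(m_variants = 20000, class_proportions = c(1, 0, 0, 0),
                    shared_control_fraction = 1, mode = "individual",
                    seed = 303)
  s <- simulate_case_control_pair(cfg)
  r <- cor(s$z1, s$z2)
  rho <- rho_case_control(overlap_config(1000, 1000, 1000, 1000,
                                         n12_control = 1000))$rho
  mc_se <- (1 - rho^2) / sqrt(20000)
  expect_lt(abs(r - rho), 3 * mc_se)
})

test_that("quantitative generator: effect size identity and overlap correlation", {
  b <- sqrt(0.001 / (2 * 0.05 * 0.95))
  expect_equal(b, 0.10260, tolerance = 1e-4)

  cfg <- sim_config(m_variants = 4000, class_proportions = c(1, 0, 0, 0),
                    model = "quantitative", mode = "individual",
                    n1 = 1000, n2 = 1000, n12 = 0, trait_corr = 0, seed = 11)
  s <- simulate_quantitative_pair(cfg)
  expect_lt(abs(cor(s$z1, s$z2)), 4 / sqrt(4000))
  band <- 3 * sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(mean(s$p1 < 0.05) - 0.05), band)

  cfg2 <- sim_config(m_variants = 4000, class_proportions = c(1, 0, 0, 0),
                     model = "quantitative", mode = "individual",
                     n1 = 1000, n2 = 1000, n12 = 1000, trait_corr = 0.9,
                     seed = 12)
  s2 <- simulate_quantitative_pair(cfg2)
  mc_se <- (1 - 0.81) / sqrt(4000)
  expect_lt(abs(cor(s2$z1, s2$z2) - 0.9), 3 * mc_se)

  # associated variants recover the configured slope on average
  cfg3 <- sim_config(m_variants = 3000, class_proportions = c(0, 0, 0, 1),
                     model = "quantitative", mode = "individual",
                     var_explained1 = 0.01, var_explained2 = 0.01,
                     n1 = 2000, n2 = 2000, n12 = 2000, seed = 13)
  s3 <- simulate_quantitative_pair(cfg3)
  b3 <- sqrt(0.01 / (2 * 0.05 * 0.95))
  expect_equal(mean(s3$beta1), b3, tolerance = 0.02)
})

test_that("fast mode: null bivariate normal, determinism, class variances", {
  cfg <- sim_config(m_variants = 1e5, class_proportions = c(1, 0, 0, 0),
                    shared_control_fraction = 1, mode = "fast", seed = 99)
  s <- simulate_zscores_fast(cfg)
  expect_equal(mean(s$z1), 0, tolerance = 3 / sqrt(1e5))
  expect_equal(var(s$z1), 1, tolerance = 0.02)
  expect_equal(var(s$z2), 1, tolerance = 0.02)
  expect_equal(cor(s$z1, s$z2), 0.5, tolerance = 3 * 0.75 / sqrt(1e5))

  # identical seed and config -> identical output
  expect_identical(s, simulate_zscores_fast(cfg))

  # hierarchical effects: Var(Z1) -> 1 + tau1^2 for trait-1-associated class
  cfg2 <- sim_config(m_variants = 1e5, class_proportions = c(0, 0, 1, 0),
                     effect_dist = "normal", tau1_sq = 9, mode = "fast",
                     seed = 100)
  s2 <- simulate_zscores_fast(cfg2)
  se_var <- sqrt(2 * 10^2 / 1e5)   # Var of sample variance of N(0, 10)
  expect_lt(abs(var(s2$z1) - 10), 3 * se_var)
  expect_equal(var(s2$z2), 1, tolerance = 0.02)
})

test_that("fast and individual modes agree on single-trait power", {
  m <- 10000
  base <- list(m_variants = m, class_proportions = c(0, 0, 0, 1),
               or1 = 1.3, or2 = 1.3, seed = 55)
  s_ind <- simulate_case_control_pair(
    do.call(sim_config, c(base, mode = "individual")))
  s_fast <- simulate_zscores_fast(do.call(sim_config, c(base, mode = "fast")))
  pow_ind <- mean(s_ind$p1 < 1e-4)
  pow_fast <- mean(s_fast$p1 < 1e-4)
  mc_se <- sqrt(pow_ind * (1 - pow_ind) / m + pow_fast * (1 - pow_fast) / m)
  expect_lt(abs(pow_ind - pow_fast), 3 * mc_se)
})

test_that("simulated output converts to the scan input format", {
  cfg <- sim_config(m_variants = 500, mode = "fast", seed = 2)
  sim <- simulate_sumstats(cfg)
  st <- sim_to_sumstats(sim, cfg)
  expect_s3_class(st$study1, "sumstats")
  expect_equal(nrow(st$truth), 500L)
  expect_equal(st$study1$z, sim$z1)
  # files written from these tables are readable by the standard reader
  path <- write_sumstats_file(st$study2[, setdiff(names(st$study2), "z")])
  back <- read_sumstats(path)
  expect_equal(back$z, sim$z2, tolerance = 1e-6)
})
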