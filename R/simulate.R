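# Two-trait GWAS summary-statistics simulator with known variant classes:
# individual-level case-control studies (optionally with shared controls),
# individual-level correlated quantitative traits, and a fast asymptotic
# mode that draws Z-scores directly from their limiting bivariate normal.

#' Simulation configuration
#'
#' Defines the generative conditions for a two-trait simulation. Defaults
#' correspond to the canonical benchmarking design: independent bi-allelic
#' variants in Hardy-Weinberg equilibrium at MAF 5%, an additive logistic
#' disease model, 99% of variants under the global null, 0.5% associated
#' with trait 2 only, 0.4% with trait 1 only and 0.1% pleiotropic; odds
#' ratio 1.15 for singly-associated variants, baseline prevalences 15% and
#' 10%, and 1000 cases + 1000 controls per study.
#'
#' @param m_variants number of independent variants to simulate.
#' @param class_proportions proportions of variants under H00 (global null),
#'   H01 (trait 2 only), H02 (trait 1 only) and Ha (pleiotropic); must sum
#'   to 1.
#' @param maf population minor allele frequency (fixed across variants).
#' @param model `"case_control"` or `"quantitative"`.
#' @param or1,or2 odds ratios of singly-associated variants on traits 1 and 2
#'   (case-control model): a variant under H02 carries `log(or1)` on trait 1,
#'   one under H01 carries `log(or2)` on trait 2.
#' @param or1_ha,or2_ha odds ratios of pleiotropic (Ha) variants on the two
#'   traits; default equal to `or1`, `or2`. The benchmark design fixes the
#'   singly-associated effect at OR 1.15 and varies the pleiotropic pair.
#' @param prevalence1,prevalence2 baseline disease prevalences.
#' @param n1_case,n1_control,n2_case,n2_control per-study case/control counts.
#' @param shared_control_fraction fraction of controls shared between the two
#'   case-control studies (a single control pool reused in both fits).
#' @param n1,n2,n12 sample sizes and overlap count for the quantitative model.
#' @param var_explained1,var_explained2 trait-variance fractions explained by
#'   an associated variant (quantitative model); the per-trait effect is
#'   `beta_k = sqrt(var_explained_k / (2 maf (1 - maf)))`.
#' @param trait_corr phenotypic correlation of the two quantitative traits.
#' @param effect_dist `"fixed"` (the configured OR / variance-explained) or
#'   `"normal"` (fast mode only: latent effect means drawn N(0, tau_k^2),
#'   matching the hierarchical composite-null model).
#' @param tau1_sq,tau2_sq effect-mean dispersions for `effect_dist = "normal"`.
#' @param mode `"fast"` (asymptotic Z-score draws) or `"individual"`
#'   (individual-level data and per-variant model fits).
#' @param rho optional Z-score correlation override for fast mode; when NULL
#'   it is derived from the overlap design ([rho_case_control()] /
#'   [rho_quantitative()]).
#' @param seed integer seed; all simulators are fully reproducible from
#'   (config, seed).
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(m_variants,
                       class_proportions = c(h00 = 0.99, h01 = 0.005,
                                             h02 = 0.004, ha = 0.001),
                       maf = 0.05,
                       model = c("case_control", "quantitative"),
                       or1 = 1.15, or2 = 1.15,
                       or1_ha = or1, or2_ha = or2,
                       prevalence1 = 0.15, prevalence2 = 0.10,
                       n1_case = 1000, n1_control = 1000,
                       n2_case = 1000, n2_control = 1000,
                       shared_control_fraction = 0,
                       n1 = 2000, n2 = 2000, n12 = 0,
                       var_explained1 = 0.001, var_explained2 = 0.001,
                       trait_corr = 0,
                       effect_dist = c("fixed", "normal"),
                       tau1_sq = 0, tau2_sq = 0,
                       mode = c("fast", "individual"),
                       rho = NULL,
                       seed = 1L) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  effect_dist <- match.arg(effect_dist)
  if (length(class_proportions) != 4L || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-12)
    stop("'class_proportions' must be 4 nonnegative numbers summing to 1")
  if (m_variants < 1) stop("'m_variants' must be positive")
  if (maf <= 0 || maf > 0.5) stop("'maf' must be in (0, 0.5]")
  if (any(c(or1, or2, or1_ha, or2_ha) <= 0)) stop("odds ratios must be positive")
  if (any(c(prevalence1, prevalence2) <= 0 | c(prevalence1, prevalence2) >= 1))
    stop("prevalences must be in (0, 1)")
  if (any(c(n1_case, n1_control, n2_case, n2_control, n1, n2) <= 0))
    stop("sample sizes must be positive")
  if (shared_control_fraction < 0 || shared_control_fraction > 1)
    stop("'shared_control_fraction' must be in [0, 1]")
  if (n12 > min(n1, n2)) stop("'n12' cannot exceed either sample size")
  if (var_explained1 >= 1 || var_explained2 >= 1 ||
      var_explained1 < 0 || var_explained2 < 0)
    stop("'var_explained' must be in [0, 1)")
  if (abs(trait_corr) >= 1) stop("'trait_corr' must satisfy |trait_corr| < 1")
  if (tau1_sq < 0 || tau2_sq < 0) stop("tau^2 must be nonnegative")
  if (!is.null(rho) && abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  structure(list(m_variants = as.integer(m_variants),
                 class_proportions = class_proportions, maf = maf,
                 model = model, or1 = or1, or2 = or2,
                 or1_ha = or1_ha, or2_ha = or2_ha,
                 prevalence1 = prevalence1, prevalence2 = prevalence2,
                 n1_case = n1_case, n1_control = n1_control,
                 n2_case = n2_case, n2_control = n2_control,
                 shared_control_fraction = shared_control_fraction,
                 n1 = n1, n2 = n2, n12 = n12,
                 var_explained1 = var_explained1,
                 var_explained2 = var_explained2,
                 trait_corr = trait_corr, effect_dist = effect_dist,
                 tau1_sq = tau1_sq, tau2_sq = tau2_sq,
                 mode = mode, rho = rho, seed = as.integer(seed)),
            class = "sim_config")
}

#' Deterministic variant-class assignment
#'
#' Allocates exactly `round(m * pi)` variants per class by largest-remainder
#' rounding, so counts always sum to `m_variants` and, e.g., 10^7 variants at
#' proportions (0.99, 0.005, 0.004, 0.001) give exactly 9,900,000 / 50,000 /
#' 40,000 / 10,000 variants.
#'
#' @param cfg a [sim_config()] object.
#' @return factor of length `m_variants` with levels `H00`, `H01`, `H02`,
#'   `Ha`, in class-block order.
#' @export
assign_variant_classes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$m_variants
  p <- cfg$class_proportions
  base <- floor(m * p)
  rem <- m - sum(base)
  if (rem > 0) {
    frac <- m * p - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  factor(rep(c("H00", "H01", "H02", "Ha"), times = base),
         levels = c("H00", "H01", "H02", "Ha"))
}

#' Logistic-model intercept matching a target prevalence
#'
#' Solves `E_X[expit(alpha + beta X)] = prevalence` for `alpha`, with
#' `X ~ Binomial(2, maf)`, by monotone root-finding. This is the intercept of
#' the additive logistic disease model that yields the configured marginal
#' disease prevalence in the population.
#'
#' @param prevalence target marginal prevalence in (0, 1).
#' @param maf minor allele frequency.
#' @param beta log odds ratio per allele copy.
#' @return the intercept `alpha` (scalar).
#' @examples
#' solve_intercept(0.15, 0.05, 0)           # qlogis(0.15)
#' solve_intercept(0.10, 0.05, log(1.15))
#' @export
solve_intercept <- function(prevalence, maf, beta) {
  if (prevalence <= 0 || prevalence >= 1) stop("'prevalence' must be in (0, 1)")
  gx <- dbinom(0:2, 2, maf)
  f <- function(a) sum(gx * plogis(a + beta * (0:2))) - prevalence
  uniroot(f, c(-50, 50), tol = 1e-12)$root
}

# genotype distributions in cases and controls under the additive logistic
# model: P(x | case) prop. to P(x) expit(alpha + beta x)
.cc_geno_probs <- function(maf, prevalence, beta) {
  a <- solve_intercept(prevalence, maf, beta)
  gx <- dbinom(0:2, 2, maf)
  risk <- plogis(a + beta * (0:2))
  list(case = gx * risk / sum(gx * risk),
       control = gx * (1 - risk) / sum(gx * (1 - risk)))
}

# Maximum-likelihood logistic regression of case status on genotype from
# per-variant 2x3 count tables, Newton iteration to 1e-8 with capped steps.
# case_counts, control_counts: m x 3 matrices (genotypes 0, 1, 2).
.logistic_fit_counts <- function(case_counts, control_counts,
                                 tol = 1e-8, max_iter = 50L) {
  N <- case_counts + control_counts
  n_case <- rowSums(case_counts)
  n <- rowSums(N)
  x <- 0:2
  a <- qlogis(pmin(pmax(n_case / n, 1e-12), 1 - 1e-12))
  b <- numeric(nrow(N))
  converged <- rep(FALSE, nrow(N))
  for (it in seq_len(max_iter)) {
    eta0 <- a; eta1 <- a + b; eta2 <- a + 2 * b
    mu <- cbind(plogis(eta0), plogis(eta1), plogis(eta2))
    w <- N * mu * (1 - mu)
    r <- case_counts - N * mu
    Ua <- rowSums(r)
    Ub <- r[, 2] + 2 * r[, 3]
    Iaa <- rowSums(w)
    Iab <- w[, 2] + 2 * w[, 3]
    Ibb <- w[, 2] + 4 * w[, 3]
    det <- Iaa * Ibb - Iab^2
    det[det < 1e-300] <- NA  # separated / degenerate
    da <- (Ibb * Ua - Iab * Ub) / det
    db <- (Iaa * Ub - Iab * Ua) / det
    # step-halving cap keeps Newton stable when counts are near-separated
    step <- pmin(1, 5 / pmax(abs(da), abs(db), 1e-300))
    upd <- !converged & !is.na(da)
    a[upd] <- a[upd] + (step * da)[upd]
    b[upd] <- b[upd] + (step * db)[upd]
    converged <- converged | (!is.na(da) & pmax(abs(da), abs(db)) < tol)
    if (all(converged | is.na(da))) break
  }
  se <- sqrt(Iaa / det)
  bad <- is.na(det) | !is.finite(se)
  b[bad] <- 0
  se[bad] <- Inf
  list(beta = b, se = se, converged = converged & !bad)
}

# per-study effect sizes by class (rows H00, H01, H02, Ha)
.class_betas <- function(cfg) {
  if (cfg$model == "case_control") {
    b1 <- log(cfg$or1); b2 <- log(cfg$or2)
    b1_ha <- log(cfg$or1_ha); b2_ha <- log(cfg$or2_ha)
  } else {
    b1 <- b1_ha <- sqrt(cfg$var_explained1 / (2 * cfg$maf * (1 - cfg$maf)))
    b2 <- b2_ha <- sqrt(cfg$var_explained2 / (2 * cfg$maf * (1 - cfg$maf)))
  }
  cbind(beta1 = c(H00 = 0, H01 = 0, H02 = b1, Ha = b1_ha),
        beta2 = c(H00 = 0, H01 = b2, H02 = 0, Ha = b2_ha))
}

.sim_result <- function(labels, fit1, fit2) {
  z1 <- ifelse(is.finite(fit1$se), fit1$beta / fit1$se, 0)
  z2 <- ifelse(is.finite(fit2$se), fit2$beta / fit2$se, 0)
  out <- data.frame(class_label = labels, z1 = z1, z2 = z2,
                    p1 = p_from_z(z1), p2 = p_from_z(z2),
                    beta1 = fit1$beta, se1 = fit1$se,
                    beta2 = fit2$beta, se2 = fit2$se)
  attr(out, "n_nonconverged") <- sum(!fit1$converged) + sum(!fit2$converged)
  class(out) <- c("sim_variants", "data.frame")
  out
}

#' Individual-level simulation of two case-control studies
#'
#' For each variant and study, population genotypes follow
#' `X ~ Binomial(2, maf)` and disease status the additive logistic model with
#' the class-appropriate log odds ratio and an intercept solved to match the
#' configured prevalence ([solve_intercept()]). Cases and controls are then
#' sampled retrospectively: the genotypes of the first `n_case` cases (and
#' `n_control` controls) encountered in the population stream are iid from
#' the conditional genotype distribution given case (control) status, so they
#' are drawn directly from those conditionals — exactly equivalent to, and
#' much faster than, literal rejection sampling of the stream. Each study's
#' marginal logistic model is refit by Newton iteration and the Wald summary
#' statistics recorded.
#'
#' When `shared_control_fraction > 0`, a single shared control pool (drawn
#' from study 1's control genotype distribution) is reused in both studies'
#' fits; the shared individuals are controls for both traits by construction.
#'
#' @param cfg a [sim_config()] with `model = "case_control"`.
#' @return data frame of class `"sim_variants"`: `class_label`, `z1`, `z2`,
#'   `p1`, `p2`, `beta1`, `se1`, `beta2`, `se2`.
#' @export
simulate_case_control_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$model == "case_control")
  set.seed(cfg$seed)
  labels <- assign_variant_classes(cfg)
  betas <- .class_betas(cfg)
  m <- cfg$m_variants
  n_sh <- round(cfg$shared_control_fraction * min(cfg$n1_control, cfg$n2_control))

  case1 <- ctrl1 <- case2 <- ctrl2 <- matrix(0, m, 3)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    k <- length(idx)
    pr1 <- .cc_geno_probs(cfg$maf, cfg$prevalence1, betas[cl, "beta1"])
    pr2 <- .cc_geno_probs(cfg$maf, cfg$prevalence2, betas[cl, "beta2"])
    case1[idx, ] <- t(rmultinom(k, cfg$n1_case, pr1$case))
    case2[idx, ] <- t(rmultinom(k, cfg$n2_case, pr2$case))
    shared <- if (n_sh > 0) t(rmultinom(k, n_sh, pr1$control)) else matrix(0, k, 3)
    ctrl1[idx, ] <- shared +
      (if (cfg$n1_control > n_sh)
        t(rmultinom(k, cfg$n1_control - n_sh, pr1$control)) else 0)
    ctrl2[idx, ] <- shared +
      (if (cfg$n2_control > n_sh)
        t(rmultinom(k, cfg$n2_control - n_sh, pr2$control)) else 0)
  }
  .sim_result(labels,
              .logistic_fit_counts(case1, ctrl1),
              .logistic_fit_counts(case2, ctrl2))
}

#' Individual-level simulation of two correlated quantitative traits
#'
#' Per variant, genotypes `X ~ Binomial(2, maf)` for the union of the two
#' samples; the two traits are `Y_k = beta_k (X - 2 maf) + e_k` with
#' `(e_1, e_2)` bivariate normal (means 0, variances 1, correlation
#' `trait_corr`). Trait 1 is observed on the first `n1` individuals and
#' trait 2 on the last `n2`, so `n12` individuals carry both traits. Each
#' trait's simple linear regression gives the Wald summary statistics.
#'
#' @param cfg a [sim_config()] with `model = "quantitative"`.
#' @return data frame of class `"sim_variants"` (see
#'   [simulate_case_control_pair()]).
#' @export
simulate_quantitative_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$model == "quantitative")
  set.seed(cfg$seed)
  labels <- assign_variant_classes(cfg)
  betas <- .class_betas(cfg)
  b1 <- betas[as.integer(labels), "beta1"]
  b2 <- betas[as.integer(labels), "beta2"]
  m <- cfg$m_variants
  n_tot <- cfg$n1 + cfg$n2 - cfg$n12
  idx1 <- seq_len(cfg$n1)
  idx2 <- (n_tot - cfg$n2 + 1):n_tot
  rho_t <- cfg$trait_corr

  slope_fit <- function(X, Y) {
    n <- nrow(X)
    sx <- colMeans(X); sy <- colMeans(Y)
    sxx <- colSums(X^2) - n * sx^2
    sxy <- colSums(X * Y) - n * sx * sy
    syy <- colSums(Y^2) - n * sy^2
    beta <- sxy / sxx
    se <- sqrt(pmax(syy - beta * sxy, 0) / ((n - 2) * sxx))
    list(beta = beta, se = se, converged = is.finite(se) & se > 0)
  }

  out_b1 <- out_se1 <- out_b2 <- out_se2 <- numeric(m)
  chunk <- max(1L, floor(4e6 / n_tot))
  for (i in seq(1L, m, by = chunk)) {
    j <- i:min(i + chunk - 1L, m)
    k <- length(j)
    X <- matrix(rbinom(n_tot * k, 2, cfg$maf), n_tot, k)
    e1 <- matrix(rnorm(n_tot * k), n_tot, k)
    e2 <- rho_t * e1 + sqrt(1 - rho_t^2) * matrix(rnorm(n_tot * k), n_tot, k)
    Xc <- X - 2 * cfg$maf
    Y1 <- sweep(Xc, 2, b1[j], `*`) + e1
    Y2 <- sweep(Xc, 2, b2[j], `*`) + e2
    f1 <- slope_fit(X[idx1, , drop = FALSE], Y1[idx1, , drop = FALSE])
    f2 <- slope_fit(X[idx2, , drop = FALSE], Y2[idx2, , drop = FALSE])
    out_b1[j] <- f1$beta; out_se1[j] <- f1$se
    out_b2[j] <- f2$beta; out_se2[j] <- f2$se
  }
  .sim_result(labels,
              list(beta = out_b1, se = out_se1, converged = is.finite(out_se1)),
              list(beta = out_b2, se = out_se2, converged = is.finite(out_se2)))
}

# asymptotic standard error of the per-variant effect under each design
.fast_se <- function(cfg) {
  v_g <- 2 * cfg$maf * (1 - cfg$maf)
  if (cfg$model == "case_control") {
    phi1 <- cfg$n1_case / (cfg$n1_case + cfg$n1_control)
    phi2 <- cfg$n2_case / (cfg$n2_case + cfg$n2_control)
    c(1 / sqrt(v_g * (cfg$n1_case + cfg$n1_control) * phi1 * (1 - phi1)),
      1 / sqrt(v_g * (cfg$n2_case + cfg$n2_control) * phi2 * (1 - phi2)))
  } else {
    c(1 / sqrt(v_g * cfg$n1), 1 / sqrt(v_g * cfg$n2))
  }
}

# Z-score correlation implied by the overlap design
.fast_rho <- function(cfg) {
  if (!is.null(cfg$rho)) return(cfg$rho)
  if (cfg$model == "case_control") {
    n_sh <- round(cfg$shared_control_fraction * min(cfg$n1_control, cfg$n2_control))
    if (n_sh == 0) return(0)
    rho_case_control(overlap_config(cfg$n1_case, cfg$n1_control,
                                    cfg$n2_case, cfg$n2_control,
                                    n12_control = n_sh))$rho
  } else {
    rho_quantitative(cfg$n1, cfg$n2, cfg$n12, cfg$trait_corr)$rho
  }
}

#' Fast asymptotic simulation of Z-score pairs
#'
#' Draws Z-scores directly from their limiting model: `Z_k ~ N(ncp_k, 1)`
#' with the noncentrality implied by the class effect size, MAF and sample
#' design, and cross-study correlation `rho` (derived from the overlap
#' design, or overridden via `cfg$rho`) injected through the bivariate
#' normal. With `effect_dist = "normal"` the per-variant effect means are
#' drawn `N(0, tau_k^2)`, matching the hierarchical composite-null model
#' exactly. This is an approximation to the individual-level generators,
#' suitable for genome-scale replicate counts.
#'
#' @param cfg a [sim_config()] with `mode = "fast"`.
#' @return data frame of class `"sim_variants"` (see
#'   [simulate_case_control_pair()]); `beta` and `se` are the asymptotic
#'   reconstructions `beta = z * se`.
#' @export
simulate_zscores_fast <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  labels <- assign_variant_classes(cfg)
  m <- cfg$m_variants
  se <- .fast_se(cfg)
  rho <- .fast_rho(cfg)

  assoc1 <- labels %in% c("H02", "Ha")
  assoc2 <- labels %in% c("H01", "Ha")
  if (cfg$effect_dist == "fixed") {
    betas <- .class_betas(cfg)
    m1 <- betas[as.integer(labels), "beta1"] / se[1]
    m2 <- betas[as.integer(labels), "beta2"] / se[2]
  } else {
    m1 <- ifelse(assoc1, rnorm(m, 0, sqrt(cfg$tau1_sq)), 0)
    m2 <- ifelse(assoc2, rnorm(m, 0, sqrt(cfg$tau2_sq)), 0)
  }
  e1 <- rnorm(m)
  e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(m)
  z1 <- m1 + e1
  z2 <- m2 + e2
  .sim_result(labels,
              list(beta = z1 * se[1], se = rep(se[1], m), converged = rep(TRUE, m)),
              list(beta = z2 * se[2], se = rep(se[2], m), converged = rep(TRUE, m)))
}

#' Simulate two-trait summary statistics
#'
#' Dispatches on the configuration: `mode = "fast"` uses
#' [simulate_zscores_fast()]; otherwise the individual-level generator for
#' the configured model ([simulate_case_control_pair()] or
#' [simulate_quantitative_pair()]).
#'
#' @param cfg a [sim_config()] object.
#' @return data frame of class `"sim_variants"`.
#' @export
simulate_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode == "fast") simulate_zscores_fast(cfg)
  else if (cfg$model == "case_control") simulate_case_control_pair(cfg)
  else simulate_quantitative_pair(cfg)
}

#' Convert simulated variants to summary-statistics tables
#'
#' Packages a `"sim_variants"` result as two `"sumstats"` tables (synthetic
#' variant ids, chromosome 1, consecutive positions, alleles A/G, allele
#' frequency equal to the configured MAF) plus a truth-label table, i.e. the
#' same shape [read_sumstats()] produces and [placo_scan()] consumes.
#'
#' @param sim a `"sim_variants"` data frame.
#' @param cfg the [sim_config()] used to generate it.
#' @return list with `study1`, `study2` (class `"sumstats"`) and `truth`
#'   (variant_id, class_label).
#' @export
sim_to_sumstats <- function(sim, cfg) {
  m <- nrow(sim)
  id <- sprintf("var%08d", seq_len(m))
  mk <- function(beta, se, z, p) {
    out <- data.frame(variant_id = id, chrom = "1", pos = seq_len(m),
                      effect_allele = "A", other_allele = "G",
                      eaf = cfg$maf, beta = beta, se = se, p = p, z = z,
                      stringsAsFactors = FALSE)
    class(out) <- c("sumstats", "data.frame")
    out
  }
  list(study1 = mk(sim$beta1, sim$se1, sim$z1, sim$p1),
       study2 = mk(sim$beta2, sim$se2, sim$z2, sim$p2),
       truth = data.frame(variant_id = id, class_label = sim$class_label))
}
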