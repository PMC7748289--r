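# Evaluation harness: empirical type-I error and power with exact binomial
# confidence intervals, naive threshold comparators, BH-FDR adjustment, QQ
# tables with order-statistic bands, and scenario-level benchmark drivers.

#' Empirical rejection rate with exact confidence interval
#'
#' Proportion of variants in the selected classes with `p < alpha`, with an
#' exact Clopper-Pearson 95% interval (rates near 1e-4 with ~1e6 trials are
#' in the skewed regime where normal intervals misbehave).
#'
#' @param p_values numeric vector of test p-values.
#' @param labels class labels aligned with `p_values` (any vector; coerced to
#'   character). Use `NULL` to evaluate all p-values.
#' @param null_classes character vector of class labels to evaluate (e.g.
#'   `c("H00", "H01", "H02")` for type-I error, `"Ha"` for power).
#' @param alpha significance level(s); vectorized.
#' @return data frame with columns `alpha`, `rate`, `ci_low`, `ci_high`,
#'   `n_tests`.
#' @export
rejection_rate <- function(p_values, labels = NULL, null_classes = NULL,
                           alpha = 0.05) {
  if (!is.null(labels) && !is.null(null_classes)) {
    sel <- as.character(labels) %in% null_classes
    if (!any(sel)) stop("no variants in the selected classes")
    p_values <- p_values[sel]
  }
  n <- length(p_values)
  if (n == 0L) stop("no p-values to evaluate")
  out <- lapply(alpha, function(a) {
    x <- sum(p_values < a)
    ci <- binom.test(x, n)$conf.int
    data.frame(alpha = a, rate = x / n, ci_low = ci[1], ci_high = ci[2],
               n_tests = n)
  })
  do.call(rbind, out)
}

#' Naive two-threshold pleiotropy rules
#'
#' Declares pleiotropy when the trait-1 p-value is genome-wide significant
#' (`p1 < 5e-8`) and the trait-2 p-value passes a more liberal threshold:
#' `5e-5` for `"naive1"`, `5e-3` for `"naive2"`.
#'
#' @param p1,p2 numeric vectors of single-trait p-values.
#' @param variant `"naive1"` or `"naive2"`.
#' @return logical vector: pleiotropy declared?
#' @export
naive_test <- function(p1, p2, variant = c("naive1", "naive2")) {
  variant <- match.arg(variant)
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  thr2 <- if (variant == "naive1") 5e-5 else 5e-3
  p1 < 5e-8 & p2 < thr2
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, order-preserving.
#' Used for FDR-mode reporting of the product-test p-values.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values))) stop("p-values must be finite")
  p.adjust(p_values, method = "BH")
}

#' QQ-plot table with pointwise order-statistic confidence band
#'
#' Observed order statistics of the p-values against expected uniform
#' quantiles `i/(n+1)`, on the -log10 scale, with a pointwise band from the
#' Beta(i, n - i + 1) distribution of the i-th uniform order statistic.
#'
#' @param p_values numeric vector of p-values (n >= 2).
#' @param ci_level band coverage, default 0.95.
#' @return data frame with columns `expected`, `observed`, `band_low`,
#'   `band_high` (all -log10 p), sorted from most to least significant.
#' @export
qq_data <- function(p_values, ci_level = 0.95) {
  n <- length(p_values)
  if (n < 2L) stop("need at least 2 p-values")
  i <- seq_len(n)
  a <- (1 - ci_level) / 2
  data.frame(expected = -log10(i / (n + 1)),
             observed = -log10(sort(p_values)),
             band_low = -log10(qbeta(1 - a, i, n - i + 1)),
             band_high = -log10(qbeta(a, i, n - i + 1)))
}

#' Power benchmark over a grid of effect-size pairs
#'
#' For each effect pair, simulates pleiotropic (Ha) variants under the
#' configured design and estimates the power of the product test, Sobel,
#' maxP and the two naive rules at level `alpha`.
#'
#' @param cfg a [sim_config()] template; its class proportions are replaced
#'   by all-Ha and its effect sizes by each grid entry.
#' @param or_pairs list of length-2 numeric vectors: odds-ratio pairs
#'   (case-control model) or variance-explained pairs (quantitative model).
#' @param alpha significance level, default genome-wide 5e-8.
#' @param var_z marginal Z variances handed to [placo()]; in a genome-wide
#'   scan these come from [estimate_marginal_variances()] on the full variant
#'   set. Default `c(1, 1)`.
#' @param methods subset of
#'   `c("placo", "sobel", "maxp", "naive1", "naive2")`.
#' @return data frame with columns `or1`, `or2`, `method`, `power`,
#'   `ci_low`, `ci_high`, `n_tests`.
#' @export
benchmark_power <- function(cfg, or_pairs, alpha = 5e-8, var_z = c(1, 1),
                            methods = c("placo", "sobel", "maxp",
                                        "naive1", "naive2")) {
  stopifnot(inherits(cfg, "sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (k in seq_along(or_pairs)) {
    pair <- or_pairs[[k]]
    args <- unclass(cfg)
    args$class_proportions <- c(h00 = 0, h01 = 0, h02 = 0, ha = 1)
    args$seed <- cfg$seed + k
    if (cfg$model == "case_control") {
      args$or1 <- pair[1]; args$or2 <- pair[2]
      args$or1_ha <- pair[1]; args$or2_ha <- pair[2]
    } else {
      args$var_explained1 <- pair[1]; args$var_explained2 <- pair[2]
    }
    sim <- simulate_sumstats(do.call(sim_config, args))
    pv <- list(placo = placo(sim$z1, sim$z2, var_z)$p_value,
               sobel = sobel_test(sim$z1, sim$z2)$p_value,
               maxp = maxp_test(sim$p1, sim$p2)$p_value,
               naive1 = ifelse(naive_test(sim$p1, sim$p2, "naive1"), 0, 1),
               naive2 = ifelse(naive_test(sim$p1, sim$p2, "naive2"), 0, 1))
    for (mth in methods) {
      rr <- rejection_rate(pv[[mth]], alpha = alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(or1 = pair[1], or2 = pair[2], method = mth,
                   power = rr$rate, ci_low = rr$ci_low, ci_high = rr$ci_high,
                   n_tests = rr$n_tests)
    }
  }
  do.call(rbind, rows)
}

#' Type-I-error benchmark under the composite null
#'
#' Simulates the configured null mixture (any Ha proportion is reassigned to
#' H00), estimates the marginal Z variances from the simulated data itself —
#' as in a real genome-wide scan — and reports empirical rejection rates of
#' the product test, Sobel and maxP over the null variants at each level.
#' With `correct_overlap = TRUE` the Z-scores are first decorrelated using
#' the empirical correlation estimate; rates for both the uncorrected and
#' corrected product test are then reported.
#'
#' @param cfg a [sim_config()] object.
#' @param alphas significance levels, default `c(1e-2, 1e-3, 1e-4)`.
#' @param correct_overlap logical; also apply and report the
#'   decorrelation-corrected product test?
#' @return data frame with columns `method`, `alpha`, `rate`, `ci_low`,
#'   `ci_high`, `n_tests`; attribute `var_z`, and `rho_hat` when
#'   `correct_overlap`.
#' @export
benchmark_type1 <- function(cfg, alphas = c(1e-2, 1e-3, 1e-4),
                            correct_overlap = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  props <- cfg$class_proportions
  if (props[4] > 0) {  # fold the alternative back into the global null
    props[1] <- props[1] + props[4]
    props[4] <- 0
    args <- unclass(cfg)
    args$class_proportions <- props
    cfg <- do.call(sim_config, args)
  }
  sim <- simulate_sumstats(cfg)
  null_cl <- c("H00", "H01", "H02")
  res <- list()
  add <- function(method, p) {
    rr <- rejection_rate(p, sim$class_label, null_cl, alphas)
    res[[length(res) + 1L]] <<- cbind(data.frame(method = method), rr)
  }
  vz <- estimate_marginal_variances(sim$z1, sim$z2, sim$p1, sim$p2)
  add("placo", placo(sim$z1, sim$z2, vz)$p_value)
  rho_hat <- NA_real_
  if (correct_overlap) {
    rho_hat <- estimate_rho_empirical(sim$z1, sim$z2, sim$p1, sim$p2)$rho
    zd <- decorrelate(sim$z1, sim$z2, rho_hat)
    vzd <- estimate_marginal_variances(zd$z1, zd$z2)
    add("placo_corrected", placo(zd$z1, zd$z2, vzd)$p_value)
  }
  add("sobel", sobel_test(sim$z1, sim$z2)$p_value)
  add("maxp", maxp_test(sim$p1, sim$p2)$p_value)
  out <- do.call(rbind, res)
  attr(out, "var_z") <- vz
  attr(out, "rho_hat") <- rho_hat
  out
}
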