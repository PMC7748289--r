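# Pleiotropy tests under the composite null "at most one trait is associated":
# product-of-Z-scores test (asymptotic approximation and plug-in mixture
# evaluation), plus the Sobel and maxP comparators, and genome-wide
# nuisance-parameter estimation.

#' Wald Z-score from effect estimate and standard error
#'
#' @param beta numeric vector of effect estimates.
#' @param se numeric vector of positive standard errors.
#' @return numeric vector `beta / se`.
#' @export
compute_z <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("'se' must be positive and finite")
  beta / se
}

#' Two-sided normal p-value from a Z-score
#'
#' Computed in log space so extreme Z-scores (|z| ~ 40 and beyond) give a
#' finite log p rather than silently underflowing to 0.
#'
#' @param z numeric vector of Z-scores.
#' @param log.p logical; return the natural log of the p-value?
#' @return numeric vector of p-values (or log p-values).
#' @export
p_from_z <- function(z, log.p = FALSE) {
  if (any(!is.finite(z))) stop("'z' must be finite")
  lp <- log(2) + pnorm(-abs(z), log.p = TRUE)
  if (log.p) lp else exp(lp)
}

# common result container (one row per variant)
.test_result <- function(method, statistic, log_p) {
  log_p <- pmin(log_p, 0)
  data.frame(method = method, statistic = statistic,
             p_value = exp(log_p), log_p = log_p,
             stringsAsFactors = FALSE)
}

#' Sobel product-of-coefficients test
#'
#' Mediation-style comparator: `T = z1*z2 / sqrt(z1^2 + z2^2)` referred to a
#' standard normal. Valid asymptotics require at least one nonzero effect;
#' under the sparse global null typical of GWAS it is extremely conservative.
#'
#' @param z1,z2 numeric vectors of Z-scores for the two traits.
#' @param zero `"one"` (default) returns p = 1 at the removable singularity
#'   z1 = z2 = 0 (the limit of the statistic is 0); `"nan"` returns NaN there.
#' @return data frame with columns `method`, `statistic`, `p_value`, `log_p`.
#' @examples
#' sobel_test(3, 4)  # statistic 12/5 = 2.4
#' @export
sobel_test <- function(z1, z2, zero = c("one", "nan")) {
  zero <- match.arg(zero)
  denom <- sqrt(z1^2 + z2^2)
  stat <- z1 * z2 / denom
  stat[denom == 0] <- if (zero == "one") 0 else NaN
  lp <- rep(NaN, length(stat))
  ok <- !is.nan(stat)
  lp[ok] <- p_from_z(stat[ok], log.p = TRUE)
  .test_result("sobel", stat, lp)
}

#' maxP intersection-union test
#'
#' Conservative p-value for the intersection-union test of the composite
#' null: `max(p1, p2)`.
#'
#' @param p1,p2 numeric vectors of single-trait two-sided p-values in `[0, 1]`.
#' @return data frame with columns `method`, `statistic`, `p_value`, `log_p`.
#' @export
maxp_test <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE) ||
      any(!is.finite(c(p1, p2))))
    stop("p-values must lie in [0, 1]")
  p <- pmax(p1, p2)
  .test_result("maxp", p, log(p))
}

#' Marginal Z-score variances estimated genome-wide
#'
#' Under the hierarchical composite-null model, Var(Z1) = 1 + pi02 * tau1^2
#' and Var(Z2) = 1 + pi01 * tau2^2: variants associated with exactly one
#' trait inflate that trait's marginal Z variance above 1. The estimator is
#' the mean of Z^2 over all variants except those nominally associated with
#' *both* traits (both single-trait p-values below `exclusion_threshold`),
#' since putatively pleiotropic variants violate the composite null. Variants
#' associated with only one trait are retained: the model's marginal variance
#' derives precisely from them. Estimates are floored at 1 (the model form
#' cannot fall below 1).
#'
#' @param z1,z2 numeric vectors of Z-scores over (ideally genome-wide) variants.
#' @param p1,p2 optional single-trait p-values; derived from the Z-scores when
#'   missing.
#' @param exclusion_threshold variants with both p-values below this are
#'   excluded. Default 1e-4.
#' @return object of class `"marginal_variances"`: list with `v1`, `v2`,
#'   `n_used`, `exclusion_threshold`.
#' @export
estimate_marginal_variances <- function(z1, z2, p1 = NULL, p2 = NULL,
                                        exclusion_threshold = 1e-4) {
  if (length(z1) != length(z2)) stop("'z1' and 'z2' must have equal length")
  if (length(z1) < 2L) stop("need at least 2 variants to estimate variances")
  if (length(z1) < 10000L)
    warning("fewer than 10,000 variants: marginal-variance estimation is ",
            "intended for genome-wide input")
  if (is.null(p1)) p1 <- p_from_z(z1)
  if (is.null(p2)) p2 <- p_from_z(z2)
  keep <- !(p1 < exclusion_threshold & p2 < exclusion_threshold)
  if (sum(keep) < 2L) stop("fewer than 2 variants retained")
  structure(list(v1 = max(1, mean(z1[keep]^2)),
                 v2 = max(1, mean(z2[keep]^2)),
                 n_used = sum(keep),
                 exclusion_threshold = exclusion_threshold),
            class = "marginal_variances")
}

#' @export
print.marginal_variances <- function(x, ...) {
  cat("Marginal Z-score variances (composite-null model 1 + pi*tau^2)\n")
  cat(sprintf("  Var(Z1) = %.6f, Var(Z2) = %.6f  (n = %d variants, both-trait p < %g excluded)\n",
              x$v1, x$v2, x$n_used, x$exclusion_threshold))
  invisible(x)
}

#' Product-of-Z-scores pleiotropy test (asymptotic approximation)
#'
#' The default scan method. For observed Z-scores `z1`, `z2` the p-value is
#' `F(z1 z2 / sqrt(v1)) + F(z1 z2 / sqrt(v2)) - F(z1 z2)`, where `F` is the
#' two-sided tail of the normal product distribution ([normprod_tail()]) and
#' `v1`, `v2` are the marginal Z variances estimated genome-wide
#' ([estimate_marginal_variances()]). The three-term expression can exceed 1
#' by rounding near `z1*z2 = 0`; it is clamped to `[0, 1]` and the number of
#' clamped variants is recorded in the `"n_clamped"` attribute.
#'
#' @param z1,z2 numeric vectors of Z-scores for the two traits.
#' @param var_z marginal Z variances: a `"marginal_variances"` object or a
#'   numeric vector `c(v1, v2)` with both elements >= 1. Default `c(1, 1)`
#'   (no single-trait-association inflation), under which the p-value reduces
#'   to `normprod_tail(z1 * z2)$tail` exactly.
#' @return data frame with columns `method`, `statistic` (= z1*z2),
#'   `p_value`, `log_p`; attribute `n_clamped`.
#' @examples
#' placo(3, 4)
#' placo(3, 4, var_z = c(1.04, 1.02))
#' @export
placo <- function(z1, z2, var_z = c(1, 1)) {
  if (inherits(var_z, "marginal_variances")) var_z <- c(var_z$v1, var_z$v2)
  if (length(var_z) != 2L || any(!is.finite(var_z)) || any(var_z < 1))
    stop("'var_z' must be two finite variances, each >= 1")
  u <- abs(z1 * z2)
  l1 <- .np_log_tail(u / sqrt(var_z[1]))
  l2 <- .np_log_tail(u / sqrt(var_z[2]))
  l0 <- .np_log_tail(u)
  # F1 + F2 - F >= max(F1, F2) since F <= min(F1, F2); combine stably in logs
  m <- pmax(l1, l2)
  lp <- m + log(exp(l1 - m) + exp(l2 - m) - exp(l0 - m))
  n_clamped <- sum(lp > 0)
  out <- .test_result("placo_approx", z1 * z2, lp)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Composite-null mixture parameters
#'
#' Container for the mixture weights of the composite null (pi00: neither
#' trait associated; pi01: only trait 2; pi02: only trait 1) and the
#' dispersions tau_k^2 of the latent single-trait effect means
#' (mu_k ~ N(0, tau_k^2)).
#'
#' @param pi00,pi01,pi02 mixture probabilities, each in `[0, 1]`, summing to
#'   at most 1 (the remainder is the pleiotropic alternative).
#' @param tau1_sq,tau2_sq nonnegative effect dispersions.
#' @return object of class `"mixture_params"`.
#' @export
mixture_params <- function(pi00, pi01, pi02, tau1_sq = 0, tau2_sq = 0) {
  ps <- c(pi00, pi01, pi02)
  if (any(ps < 0 | ps > 1) || sum(ps) > 1 + 1e-12)
    stop("mixture weights must be in [0,1] and sum to at most 1")
  if (tau1_sq < 0 || tau2_sq < 0) stop("tau^2 must be nonnegative")
  structure(list(pi00 = pi00, pi01 = pi01, pi02 = pi02,
                 tau1_sq = tau1_sq, tau2_sq = tau2_sq),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Composite-null mixture: pi00 = %.4g, pi01 = %.4g, pi02 = %.4g\n",
              x$pi00, x$pi01, x$pi02))
  cat(sprintf("  effect dispersions: tau1^2 = %.4g, tau2^2 = %.4g\n",
              x$tau1_sq, x$tau2_sq))
  invisible(x)
}

#' Product-of-Z-scores pleiotropy test (plug-in mixture evaluation)
#'
#' Evaluates the composite-null mixture p-value
#' `pi00 F(z1 z2) + pi01 F(z1 z2 / sqrt(1 + tau2^2)) +
#'  pi02 F(z1 z2 / sqrt(1 + tau1^2))` with plug-in parameter estimates.
#' Provided as a diagnostic: the plug-in evaluation is sensitive to the
#' parameter estimates and can be quite conservative at genome-wide
#' significance levels; [placo()] is the default scan method.
#'
#' @param z1,z2 numeric vectors of Z-scores.
#' @param params a [mixture_params()] object.
#' @return data frame with columns `method`, `statistic`, `p_value`, `log_p`.
#' @export
placo_exact <- function(z1, z2, params) {
  if (!inherits(params, "mixture_params")) stop("'params' must be a mixture_params object")
  u <- abs(z1 * z2)
  lw <- log(c(params$pi00, params$pi01, params$pi02))
  L <- cbind(.np_log_tail(u) + lw[1],
             .np_log_tail(u / sqrt(1 + params$tau2_sq)) + lw[2],
             .np_log_tail(u / sqrt(1 + params$tau1_sq)) + lw[3])
  m <- pmax(L[, 1], L[, 2], L[, 3])
  lp <- ifelse(is.infinite(m) & m < 0, -Inf, m + log(rowSums(exp(L - m))))
  .test_result("placo_exact", z1 * z2, lp)
}

#' Method-of-moments estimation of the composite-null mixture parameters
#'
#' Classifies variants by single-trait significance at `p_threshold`:
#' `pi01` is the proportion with trait-2 p below threshold and trait-1 p at
#' or above it (`pi02` analogous); the doubly-significant proportion is
#' attributed to the pleiotropic alternative, and `pi00` is the remainder.
#' `tau_k^2` is `max(0, mean(Z_k^2) - 1)` over the variants classified to the
#' corresponding single-trait sub-null. Deterministic given the input.
#'
#' @param z1,z2 numeric vectors of Z-scores over genome-wide variants.
#' @param p_threshold classification threshold on the single-trait p-values.
#'   Default 1e-4.
#' @return a [mixture_params()] object with attribute `pi_alt` (the
#'   doubly-significant proportion).
#' @export
estimate_mixture_params <- function(z1, z2, p_threshold = 1e-4) {
  if (length(z1) != length(z2)) stop("'z1' and 'z2' must have equal length")
  p1 <- p_from_z(z1)
  p2 <- p_from_z(z2)
  i01 <- p2 < p_threshold & p1 >= p_threshold
  i02 <- p1 < p_threshold & p2 >= p_threshold
  ia  <- p1 < p_threshold & p2 < p_threshold
  tau_sq <- function(z, idx) {
    if (!any(idx)) {
      warning("empty classification cell: tau^2 set to 0")
      return(0)
    }
    max(0, mean(z[idx]^2) - 1)
  }
  out <- mixture_params(pi00 = 1 - mean(i01) - mean(i02) - mean(ia),
                        pi01 = mean(i01), pi02 = mean(i02),
                        tau1_sq = tau_sq(z1, i02), tau2_sq = tau_sq(z2, i01))
  attr(out, "pi_alt") <- mean(ia)
  out
}
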