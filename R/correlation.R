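# Correlation between the two studies' Z-scores induced by sample overlap:
# analytic formulas for case-control and quantitative designs, empirical
# estimation from null variants, and Z-score decorrelation.

#' Sample-overlap configuration for two case-control studies
#'
#' @param n1_case,n1_control,n2_case,n2_control per-study case and control
#'   counts.
#' @param n12_case,n12_control numbers of shared cases and shared controls
#'   between the two studies.
#' @return object of class `"overlap_config"`.
#' @export
overlap_config <- function(n1_case, n1_control, n2_case, n2_control,
                           n12_case = 0, n12_control = 0) {
  cnt <- c(n1_case, n1_control, n2_case, n2_control, n12_case, n12_control)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be nonnegative integers")
  if (n12_case > min(n1_case, n2_case))
    stop("shared cases cannot exceed either study's case count")
  if (n12_control > min(n1_control, n2_control))
    stop("shared controls cannot exceed either study's control count")
  structure(list(n1_case = n1_case, n1_control = n1_control,
                 n2_case = n2_case, n2_control = n2_control,
                 n12_case = n12_case, n12_control = n12_control),
            class = "overlap_config")
}

.corr_estimate <- function(rho, method, n_variants_used = NA_integer_) {
  structure(list(rho = rho, method = method, n_variants_used = n_variants_used),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("Z-score correlation rho = %.6f (%s%s)\n", x$rho, x$method,
              if (!is.na(x$n_variants_used))
                sprintf(", %d variants", x$n_variants_used) else ""))
  invisible(x)
}

#' Analytic Z-score correlation for two case-control studies with overlap
#'
#' Under the global null and ignoring variation in the standard errors,
#' `rho = [n12_control * sqrt(n1_case n2_case / (n1_control n2_control)) +
#'         n12_case   * sqrt(n1_control n2_control / (n1_case n2_case))] /
#'        sqrt(n1 n2)`.
#' With independent cases and controls at least as numerous as cases in each
#' study, `rho` lies in `[0, 0.5]`; the maximum 0.5 is attained when both
#' studies have equal size, equal case/control counts, and share all
#' controls.
#'
#' @param cfg an [overlap_config()] object.
#' @return a `"correlation_estimate"` (method `"analytic_cc"`).
#' @examples
#' rho_case_control(overlap_config(1000, 1000, 1000, 1000, 0, 1000))$rho # 0.5
#' @export
rho_case_control <- function(cfg) {
  if (!inherits(cfg, "overlap_config")) stop("'cfg' must be an overlap_config object")
  n1 <- cfg$n1_case + cfg$n1_control
  n2 <- cfg$n2_case + cfg$n2_control
  term_ctrl <- 0
  if (cfg$n12_control > 0) {
    if (cfg$n1_control == 0 || cfg$n2_control == 0 ||
        cfg$n1_case == 0 || cfg$n2_case == 0)
      stop("shared controls require positive case and control counts in both studies")
    term_ctrl <- cfg$n12_control *
      sqrt(cfg$n1_case * cfg$n2_case / (cfg$n1_control * cfg$n2_control))
  }
  term_case <- 0
  if (cfg$n12_case > 0) {
    if (cfg$n1_case == 0 || cfg$n2_case == 0 ||
        cfg$n1_control == 0 || cfg$n2_control == 0)
      stop("shared cases require positive case and control counts in both studies")
    term_case <- cfg$n12_case *
      sqrt(cfg$n1_control * cfg$n2_control / (cfg$n1_case * cfg$n2_case))
  }
  .corr_estimate((term_ctrl + term_case) / sqrt(n1 * n2), "analytic_cc")
}

#' Analytic Z-score correlation for two quantitative-trait studies with
#' overlapping samples
#'
#' `rho = (n12 / sqrt(n1 * n2)) * corr(Y1, Y2)` under the global null, where
#' `n12` is the number of individuals measured for both traits.
#'
#' @param n1,n2 per-trait sample sizes.
#' @param n12 number of overlapping samples (`<= min(n1, n2)`).
#' @param trait_corr phenotypic correlation between the traits, in `[-1, 1]`.
#' @return a `"correlation_estimate"` (method `"analytic_qt"`).
#' @export
rho_quantitative <- function(n1, n2, n12, trait_corr) {
  if (n12 > min(n1, n2)) stop("'n12' cannot exceed either sample size")
  if (abs(trait_corr) > 1) stop("'trait_corr' must lie in [-1, 1]")
  .corr_estimate(n12 / sqrt(n1 * n2) * trait_corr, "analytic_qt")
}

#' Empirical Z-score correlation from null variants
#'
#' Pearson correlation of the Z-score pairs over variants that show no
#' evidence of association with either trait (both single-trait p-values
#' above `p_threshold`). Used when overlap counts are unavailable, as is
#' typical with public summary statistics.
#'
#' @param z1,z2 numeric vectors of Z-scores over genome-wide variants.
#' @param p1,p2 optional single-trait p-values; derived from the Z-scores when
#'   missing.
#' @param p_threshold both-trait null-classification threshold. Default 1e-4.
#' @return a `"correlation_estimate"` (method `"empirical"`) recording the
#'   number of variants used.
#' @export
estimate_rho_empirical <- function(z1, z2, p1 = NULL, p2 = NULL,
                                   p_threshold = 1e-4) {
  if (length(z1) != length(z2)) stop("'z1' and 'z2' must have equal length")
  if (is.null(p1)) p1 <- p_from_z(z1)
  if (is.null(p2)) p2 <- p_from_z(z2)
  keep <- p1 > p_threshold & p2 > p_threshold
  if (sum(keep) < 100L)
    stop("fewer than 100 variants pass the null-classification filter")
  .corr_estimate(cor(z1[keep], z2[keep]), "empirical", sum(keep))
}

#' Decorrelate a pair of Z-score vectors
#'
#' Applies the symmetric (unique symmetric-positive-definite) inverse square
#' root of the exchangeable correlation matrix `R = [[1, rho], [rho, 1]]` to
#' each Z pair, so the transformed scores are uncorrelated with unit variance
#' under the null. In closed form, with
#' `a = (1/sqrt(1+rho) + 1/sqrt(1-rho)) / 2` and
#' `b = (1/sqrt(1+rho) - 1/sqrt(1-rho)) / 2`:
#' `Z1' = a Z1 + b Z2`, `Z2' = b Z1 + a Z2`.
#'
#' A warning is emitted for `|rho| > 0.5`: the decorrelated product test may
#' show inflated type I error for strongly correlated traits or studies
#' sharing more than half their subjects.
#'
#' @param z1,z2 numeric vectors of Z-scores.
#' @param rho Z-score correlation, `|rho| < 1`. A scalar or a
#'   `"correlation_estimate"`.
#' @return data frame with decorrelated columns `z1`, `z2`.
#' @export
decorrelate <- function(z1, z2, rho) {
  if (inherits(rho, "correlation_estimate")) rho <- rho$rho
  if (!is.finite(rho) || abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  if (abs(rho) > 0.5)
    warning("|rho| > 0.5: the decorrelated test may show inflated type I ",
            "error for strongly correlated traits")
  a <- (1 / sqrt(1 + rho) + 1 / sqrt(1 - rho)) / 2
  b <- (1 / sqrt(1 + rho) - 1 / sqrt(1 - rho)) / 2
  data.frame(z1 = a * z1 + b * z2, z2 = b * z1 + a * z2)
}
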