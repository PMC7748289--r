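# Reading, harmonizing, filtering and writing GWAS summary statistics, and
# the end-to-end two-study scan pipeline.

.sumstats_fields <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "p")

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text file with a header row and maps its columns onto
#' the standard fields `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `p`. `variant_id`, `effect_allele`
#' and `other_allele` are required, together with either `beta` + `se` or
#' `beta` + `p` (from which `se` is reconstructed via the implied Z-score).
#' Alleles are normalized to uppercase. Rows whose numeric fields fail to
#' parse are dropped with a message reporting the count. The Wald Z-score
#' and, when absent, the two-sided p-value are derived.
#'
#' @param path file path of a delimited text file (separator sniffed by
#'   `data.table::fread`).
#' @param column_map named character vector mapping standard field names to
#'   column names in the file, e.g. `c(variant_id = "SNP", beta = "BETA")`.
#'   Unmapped standard fields are looked up under their own names.
#' @return data frame of class `"sumstats"` with the standard fields plus
#'   derived `z`; attribute `n_dropped` counts unparseable rows.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = "character")
  map <- stats::setNames(.sumstats_fields, .sumstats_fields)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .sumstats_fields)
    if (length(bad)) stop("unknown fields in column_map: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  present <- map[map %in% names(raw)]
  required <- c("variant_id", "effect_allele", "other_allele", "beta")
  missing <- setdiff(required, names(present))
  if (!("se" %in% names(present) || "p" %in% names(present)))
    missing <- c(missing, "se or p")
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  out <- as.data.frame(raw[, present, drop = FALSE])
  names(out) <- names(present)
  for (al in c("effect_allele", "other_allele")) out[[al]] <- toupper(out[[al]])
  num_fields <- intersect(c("pos", "eaf", "beta", "se", "p"), names(out))
  for (f in num_fields) out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  ok <- complete.cases(out[, intersect(c("beta", "se", "p"), names(out)), drop = FALSE])
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with unparseable numeric fields dropped")
  out <- out[ok, , drop = FALSE]
  if ("se" %in% names(out)) {
    if (any(out$se <= 0)) stop("standard errors must be positive")
    out$z <- out$beta / out$se
    if (!("p" %in% names(out))) out$p <- p_from_z(out$z)
  } else {
    # reconstruct Z from p and effect direction: Z = sign(beta) * qnorm(1 - p/2)
    out$z <- sign(out$beta) * qnorm(out$p / 2, lower.tail = FALSE)
    out$se <- ifelse(out$z != 0, out$beta / out$z, NA_real_)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("sumstats", "data.frame")
  out
}

# derive z (from beta/se) and p (from z) for tables built in memory
.ensure_zp <- function(s) {
  if (!("z" %in% names(s))) s$z <- compute_z(s$beta, s$se)
  if (!("p" %in% names(s))) s$p <- p_from_z(s$z)
  s
}

#' Harmonize two studies' summary statistics to a common effect allele
#'
#' Inner join on `variant_id`. Where study 2 reports the same allele pair
#' with effect and other allele swapped, the sign of study 2's effect (and
#' Z-score) is flipped; where the allele sets differ the variant is dropped
#' as an allele mismatch. Strand-ambiguous (palindromic A/T and C/G) variants
#' are retained by default with a logged count — public summary statistics
#' rarely carry strand information, so their handling is left to the caller.
#'
#' @param study1,study2 `"sumstats"` data frames (see [read_sumstats()]).
#' @param drop_palindromic logical; drop A/T and C/G variants? Default FALSE.
#' @return data frame of class `"variant_pairs"` with per-variant columns
#'   from both studies (`beta1`, `se1`, `z1`, `p1`, `eaf1`, and the same for
#'   study 2); attributes `n_mismatch`, `n_flipped`, `n_palindromic`,
#'   `n_palindromic_dropped`.
#' @export
harmonize <- function(study1, study2, drop_palindromic = FALSE) {
  study1 <- .ensure_zp(study1)
  study2 <- .ensure_zp(study2)
  for (s in list(study1, study2)) {
    dup <- unique(s$variant_id[duplicated(s$variant_id)])
    if (length(dup))
      stop("duplicate variant_id within a study: ",
           paste(head(dup, 5L), collapse = ", "),
           if (length(dup) > 5L) ", ..." else "")
  }
  i <- match(study2$variant_id, study1$variant_id)
  keep2 <- which(!is.na(i))
  s1 <- study1[i[keep2], , drop = FALSE]
  s2 <- study2[keep2, , drop = FALSE]

  same <- s1$effect_allele == s2$effect_allele & s1$other_allele == s2$other_allele
  swap <- s1$effect_allele == s2$other_allele & s1$other_allele == s2$effect_allele
  mismatch <- !(same | swap)

  flip <- swap & !mismatch
  s2$beta[flip] <- -s2$beta[flip]
  s2$z[flip] <- -s2$z[flip]
  if ("eaf" %in% names(s2)) s2$eaf[flip] <- 1 - s2$eaf[flip]

  ok <- !mismatch
  s1 <- s1[ok, , drop = FALSE]
  s2 <- s2[ok, , drop = FALSE]

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- s1$effect_allele == unname(comp[s1$other_allele]) &
    !is.na(comp[s1$other_allele])
  n_pal <- sum(pal)
  n_pal_dropped <- 0L
  if (drop_palindromic && n_pal > 0) {
    n_pal_dropped <- n_pal
    s1 <- s1[!pal, , drop = FALSE]
    s2 <- s2[!pal, , drop = FALSE]
  }
  if (n_pal > 0)
    message(n_pal, " strand-ambiguous (palindromic) variant(s)",
            if (drop_palindromic) " dropped" else " retained")

  grab <- function(s, k) {
    d <- data.frame(beta = s$beta, se = s$se, z = s$z, p = s$p)
    d$eaf <- if ("eaf" %in% names(s)) s$eaf else NA_real_
    names(d) <- paste0(names(d), k)
    d
  }
  out <- data.frame(variant_id = s1$variant_id,
                    chrom = if ("chrom" %in% names(s1)) s1$chrom else NA_character_,
                    pos = if ("pos" %in% names(s1)) s1$pos else NA_integer_,
                    effect_allele = s1$effect_allele,
                    other_allele = s1$other_allele,
                    stringsAsFactors = FALSE)
  out <- cbind(out, grab(s1, "1"), grab(s2, "2"))
  rownames(out) <- NULL
  attr(out, "n_mismatch") <- sum(mismatch)
  attr(out, "n_flipped") <- sum(flip)
  attr(out, "n_palindromic") <- n_pal
  attr(out, "n_palindromic_dropped") <- n_pal_dropped
  class(out) <- c("variant_pairs", "data.frame")
  out
}

#' Quality filters on harmonized variant pairs
#'
#' Retains autosomal variants with minor allele frequency at least `maf_min`
#' in both studies (where allele frequencies are available) and
#' `max(z1^2, z2^2) <= zsq_max`. The Z-squared rule removes variants with
#' extremely strong single-trait effects, which can disproportionately
#' influence the product test (rule is a strict `>`: `z^2` exactly at the
#' threshold is retained). Filters never fail; per-rule drop counts are
#' recorded as attributes and always satisfy
#' `input = retained + sum(drops)`.
#'
#' @param pairs a `"variant_pairs"` data frame (see [harmonize()]).
#' @param maf_min minimum minor allele frequency, default 0.01.
#' @param zsq_max maximum allowed squared Z-score in either study, default 80.
#' @return filtered `"variant_pairs"` with attributes `n_dropped_maf`,
#'   `n_dropped_zsq`, `n_dropped_chrom`.
#' @export
filter_variants <- function(pairs, maf_min = 0.01, zsq_max = 80) {
  chrom <- gsub("^chr", "", as.character(pairs$chrom), ignore.case = TRUE)
  auto <- is.na(chrom) | chrom %in% as.character(1:22)
  maf1 <- pmin(pairs$eaf1, 1 - pairs$eaf1)
  maf2 <- pmin(pairs$eaf2, 1 - pairs$eaf2)
  maf_ok <- (is.na(maf1) | maf1 >= maf_min) & (is.na(maf2) | maf2 >= maf_min)
  zsq_ok <- pmax(pairs$z1^2, pairs$z2^2) <= zsq_max
  # sequential attribution so drop counts partition the input
  n_chrom <- sum(!auto)
  n_maf <- sum(auto & !maf_ok)
  n_zsq <- sum(auto & maf_ok & !zsq_ok)
  out <- pairs[auto & maf_ok & zsq_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_chrom") <- n_chrom
  attr(out, "n_dropped_maf") <- n_maf
  attr(out, "n_dropped_zsq") <- n_zsq
  class(out) <- c("variant_pairs", "data.frame")
  out
}

#' Write per-variant pleiotropy results
#'
#' Tab-delimited output with variant identity, both studies' Z-scores and
#' p-values, and for each requested test its p-value and log10 p-value. The
#' log10 column is written from the log-space value, so p-values far below
#' double-precision underflow (e.g. 1e-300 and smaller) survive a
#' write/read round trip.
#'
#' @param results data frame as produced by [placo_scan()] (or any aligned
#'   table of variant columns and test columns).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(format(results, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end two-study pleiotropy scan
#'
#' Harmonizes two summary-statistics tables, applies quality filters,
#' optionally corrects for sample overlap (user-supplied or empirically
#' estimated Z-score correlation), estimates the marginal Z variances
#' genome-wide, and runs the product test alongside the Sobel and maxP
#' comparators.
#'
#' @param study1,study2 `"sumstats"` data frames.
#' @param rho known Z-score correlation from sample overlap, or `NULL`.
#' @param estimate_rho logical; estimate `rho` empirically from null variants
#'   ([estimate_rho_empirical()])? Ignored when `rho` is supplied.
#' @param var_threshold both-trait exclusion threshold for marginal-variance
#'   estimation, default 1e-4.
#' @param maf_min,zsq_max quality-filter settings (see [filter_variants()]).
#' @return data frame with per-variant columns `variant_id`, `chrom`, `pos`,
#'   `z1`, `z2`, `p1`, `p2`, `placo_p`, `placo_log10p`, `sobel_p`, `maxp_p`;
#'   attributes `var_z` (the marginal variances), `rho`, and all filter
#'   counts.
#' @export
placo_scan <- function(study1, study2, rho = NULL, estimate_rho = FALSE,
                       var_threshold = 1e-4, maf_min = 0.01, zsq_max = 80) {
  pairs <- harmonize(study1, study2)
  counts <- attributes(pairs)[c("n_mismatch", "n_flipped", "n_palindromic")]
  pairs <- filter_variants(pairs, maf_min = maf_min, zsq_max = zsq_max)
  counts <- c(counts, attributes(pairs)[c("n_dropped_chrom", "n_dropped_maf",
                                          "n_dropped_zsq")])
  z1 <- pairs$z1
  z2 <- pairs$z2
  rho_used <- NA_real_
  if (is.null(rho) && estimate_rho)
    rho <- estimate_rho_empirical(z1, z2, pairs$p1, pairs$p2)
  if (!is.null(rho)) {
    if (inherits(rho, "correlation_estimate")) rho <- rho$rho
    zd <- decorrelate(z1, z2, rho)
    z1 <- zd$z1
    z2 <- zd$z2
    rho_used <- rho
  }
  vz <- estimate_marginal_variances(z1, z2, exclusion_threshold = var_threshold)
  pl <- placo(z1, z2, vz)
  so <- sobel_test(z1, z2)
  mx <- maxp_test(p_from_z(z1), p_from_z(z2))
  out <- data.frame(variant_id = pairs$variant_id, chrom = pairs$chrom,
                    pos = pairs$pos, z1 = z1, z2 = z2,
                    p1 = p_from_z(z1), p2 = p_from_z(z2),
                    placo_p = pl$p_value, placo_log10p = pl$log_p / log(10),
                    sobel_p = so$p_value, maxp_p = mx$p_value,
                    stringsAsFactors = FALSE)
  attr(out, "var_z") <- vz
  attr(out, "rho") <- rho_used
  attr(out, "n_clamped") <- attr(pl, "n_clamped")
  for (nm in names(counts)) attr(out, nm) <- counts[[nm]]
  out
}
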