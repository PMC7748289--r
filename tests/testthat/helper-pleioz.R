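# Shared test helpers: an adaptive-quadrature oracle for the normal-product
# tail (independent of the package's series / Gauss-Laguerre evaluation), and
# small programmatic summary-statistics fixtures.

# log of F(u) = (2/pi) Int_u^Inf K0, by adaptive quadrature. For u >= 1 the
# exponentially scaled integrand is used so the oracle stays finite far below
# double-precision underflow.
oracle_log_tail <- function(u) {
  vapply(u, function(uu) {
    uu <- abs(uu)
    if (uu == 0) return(0)
    if (uu < 1) {
      inner <- integrate(function(x) besselK(x, 0), 0, uu,
                         rel.tol = 1e-13)$value
      log1p(-2 / pi * inner)
    } else {
      f <- function(s) besselK(uu + s, 0, expon.scaled = TRUE) * exp(-s)
      -uu + log(integrate(f, 0, Inf, rel.tol = 1e-13, abs.tol = 0)$value) +
        log(2 / pi)
    }
  }, numeric(1))
}

# minimal well-formed sumstats data frame
make_sumstats <- function(ids, ea = "A", oa = "G", beta = 0.1, se = 0.05,
                          eaf = 0.3, chrom = "1") {
  n <- length(ids)
  data.frame(variant_id = ids,
             chrom = rep_len(chrom, n), pos = seq_len(n),
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = rep_len(eaf, n), beta = rep_len(beta, n),
             se = rep_len(se, n),
             p = p_from_z(rep_len(beta, n) / rep_len(se, n)),
             stringsAsFactors = FALSE)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# read a written sumstats table back with full precision
read_plain <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
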