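Package: pleioz
Title: Pleiotropy Testing for Two Traits from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant-level tests of pleiotropy between two traits using only
    genome-wide association study (GWAS) summary statistics, under the
    composite null hypothesis that at most one trait is associated. The main
    test compares the product of the two Wald Z-scores against the normal
    product distribution (density K0(|x|)/pi), with an asymptotic
    approximation whose nuisance variances are estimated genome-wide.
    Includes comparator tests (Sobel, maxP, naive threshold rules),
    analytic and empirical correction for sample overlap between studies
    via Z-score decorrelation, summary-statistics input/output with allele
    harmonization and quality filters, a two-trait simulator (individual-level
    case-control and quantitative designs, plus a fast asymptotic mode), and a
    benchmarking harness for type-I-error, power, QQ and FDR evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
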