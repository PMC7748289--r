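---
title: "Testing pleiotropy of two traits from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing pleiotropy of two traits from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioz)
```

## The problem

A variant is *pleiotropic* when it is associated with both of two traits.
Given only per-variant summary statistics (effect estimate $\hat\beta_k$,
standard error $\hat\sigma_k$, Wald score $Z_k = \hat\beta_k/\hat\sigma_k$,
two-sided p-value $p_k$) from two GWAS, the null hypothesis of *no
pleiotropy* is not the usual global null but the composite

$$H_0 : H_{00} \cup H_{01} \cup H_{02},$$

where $H_{00}: \beta_1 = \beta_2 = 0$, $H_{01}: \beta_1 = 0, \beta_2 \ne 0$
and $H_{02}: \beta_1 \ne 0, \beta_2 = 0$ — "at most one trait is
associated". Rejecting a *global* null test at a variant strongly associated
with only one trait would wrongly declare pleiotropy; genome-wide, where
single-trait associations vastly outnumber shared ones, this matters.

Two classical options bracket the difficulty:

* **maxP** (intersection–union test): reject when both single-trait tests
  reject; p-value $\max(p_1, p_2)$. Valid but extremely conservative at
  stringent levels — both traits must independently clear the bar.
* **Sobel** (mediation-style product test): $T = Z_1 Z_2/\sqrt{Z_1^2+Z_2^2}$
  against N(0, 1). Its normal asymptotics require at least one truly nonzero
  effect; under the sparse global null that dominates GWAS it is grossly
  conservative and nearly powerless.

## The product test

The package's main test uses the product $Z_1 Z_2$ directly. For
independent standard normal scores the product has the *normal product
distribution* with density

$$f(x) = \frac{K_0(|x|)}{\pi}, \qquad -\infty < x < \infty,$$

where $K_0$ is the modified Bessel function of the second kind of order 0.
The density has an integrable logarithmic pole at 0 and Gaussian-like tails;
its two-sided tail probability is
$F(u) = \tfrac{2}{\pi}\int_{|u|}^{\infty} K_0(x)\,dx$.

### The composite-null mixture

Model the three sub-nulls hierarchically: $H_{00}$ holds with probability
$\pi_{00}$, under which $Z_1, Z_2 \sim N(0,1)$ independently; under $H_{01}$
(probability $\pi_{01}$) the trait-2 score has a latent mean
$\mu_2 \sim N(0, \tau_2^2)$, so marginally $Z_2 \sim N(0, 1+\tau_2^2)$;
$H_{02}$ symmetrically with $\tau_1^2$. The exact mixture p-value for
observed scores $z_1, z_2$ is

$$p = \pi_{00}\,F(z_1 z_2)
    + \pi_{01}\,F\!\left(\frac{z_1 z_2}{\sqrt{1+\tau_2^2}}\right)
    + \pi_{02}\,F\!\left(\frac{z_1 z_2}{\sqrt{1+\tau_1^2}}\right),$$

implemented as `placo_exact()` with parameters estimated once genome-wide by
`estimate_mixture_params()` (method of moments on the single-trait
classification at p < 1e-4). The plug-in evaluation is sensitive to those
estimates and can be quite conservative at genome-wide levels, so it is
exposed as a diagnostic.

### The asymptotic approximation (default)

The default scan method, `placo()`, uses the approximation

$$\hat p = F\!\left(\frac{z_1 z_2}{\sqrt{v_1}}\right)
         + F\!\left(\frac{z_1 z_2}{\sqrt{v_2}}\right)
         - F(z_1 z_2),$$

where $v_k = \mathrm{Var}(Z_k)$ are the *marginal* score variances under the
hierarchical model, $v_1 = 1 + \pi_{02}\tau_1^2$ and
$v_2 = 1 + \pi_{01}\tau_2^2$. These need no mixture decomposition:
`estimate_marginal_variances()` takes the mean of $Z_k^2$ over all variants
*except* those nominally associated with both traits (both $p_k$ below the
`exclusion_threshold`, default 1e-4), because doubly-associated variants
violate the composite null and would inflate the estimate. Variants
associated with exactly one trait are retained — the inflation
$\pi\,\tau^2$ above 1 derives precisely from them. Estimates are floored at
1, the model form's lower bound.

The approximation is accurate when the nonzero single-trait effects are
small to moderate. For very strong single-trait effects it becomes
anti-conservative — a variant with an enormous effect on one trait and none
on the other can reach genome-wide significance on the product scale. This
is the rationale for the standard hygiene filter that removes variants with
$Z^2 > 80$ in either study before analysis (`filter_variants()`), and it is
why the package's on-model calibration checks use moderate effect
dispersions ($\tau^2 \le 4$; at $\tau^2 = 9$ the measured composite-null
rejection rate at $\alpha = 10^{-4}$ is roughly $2.5\times$ the nominal
level).

## Numerical implementation of the product tail

Everything runs in log space end to end: genome-wide scans report p-values
near $10^{-17}$ and the tail itself underflows doubles around
$u \approx 708$. `normprod_tail()` therefore returns both `tail` and
`log_tail`, and all test p-values carry a `log_p` column.

Two regimes, switching at $u = 2$:

* $u < 2$: $F(u) = 1 - \tfrac{2}{\pi}\int_0^u K_0$, with the inner integral
  summed from the ascending series of $K_0$, whose logarithmic singularity
  integrates in closed form term by term. `log1p` keeps full precision as
  $F \to 1$.
* $u \ge 2$: $\int_u^\infty K_0 = e^{-u}\int_0^\infty
  \tilde K_0(u+s)\,e^{-s}\,ds$ with $\tilde K_0(x) = K_0(x)e^{x}$ the
  exponentially scaled Bessel function. The integrand is smooth, free of
  singularities and of underflow, and is handled by fixed 90-node
  Gauss–Laguerre quadrature; only $-u$ plus the log of an $O(u^{-1/2})$
  factor is ever formed. The same expression is valid at $u = 700$ and
  beyond, so no separate asymptotic-series branch is needed at run time; the
  leading asymptotic term is used only as an independent oracle in the test
  suite, alongside adaptive quadrature and a $10^8$-draw Monte-Carlo check.

Both regimes agree with adaptive quadrature to better than $10^{-10}$
relative on $u \in [10^{-6}, 700]$, and a vectorized million-point
evaluation takes a few seconds.

Assembling $\hat p = F_1 + F_2 - F$ is stable because
$F \le \min(F_1, F_2)$ (larger scale, larger tail), so
$\hat p \ge \max(F_1, F_2)$ and the subtraction never cancels
catastrophically. Rounding near $z_1 z_2 = 0$ can still push the sum above
1; it is clamped to $[0,1]$ and the number of clamped variants is recorded
(`attr(, "n_clamped")`).

## Correlated studies: sample overlap

When the two studies share samples the null scores are correlated and the
product test inflates. For two case-control studies sharing
$n_{12,\mathrm{control}}$ controls (and $n_{12,\mathrm{case}}$ cases),

$$\rho \approx \frac{
  n_{12,\mathrm{control}}\sqrt{\frac{n_{1,\mathrm{case}}\,n_{2,\mathrm{case}}}
       {n_{1,\mathrm{control}}\,n_{2,\mathrm{control}}}}
+ n_{12,\mathrm{case}}\sqrt{\frac{n_{1,\mathrm{control}}\,n_{2,\mathrm{control}}}
       {n_{1,\mathrm{case}}\,n_{2,\mathrm{case}}}}}{\sqrt{n_1 n_2}}.$$

With independent cases and controls at least as numerous as cases, $\rho$
ranges over $[0, 0.5]$, the maximum at equal-sized studies with 1:1
case-control ratio sharing all controls (`rho_case_control()`). For
quantitative traits, $\rho \approx (n_{12}/\sqrt{n_1 n_2})\,
\mathrm{corr}(Y_1, Y_2)$ (`rho_quantitative()`). When overlap counts are
unknown — the common case with public summary data —
`estimate_rho_empirical()` uses the Pearson correlation of the score pairs
over variants null for both traits (both $p > 10^{-4}$; the threshold is a
parameter, applied to *both* traits).

`decorrelate()` applies $R^{-1/2}$ for
$R = \begin{pmatrix}1&\rho\\\rho&1\end{pmatrix}$ to each score pair. The
*symmetric* square root is used — for the 2×2 exchangeable matrix it has the
closed form $a = (\frac{1}{\sqrt{1+\rho}} + \frac{1}{\sqrt{1-\rho}})/2$,
$b = (\frac{1}{\sqrt{1+\rho}} - \frac{1}{\sqrt{1-\rho}})/2$ — rather than a
Cholesky factor, which would impose an arbitrary ordering of the two
traits. The transform treats the traits symmetrically and is its own
functional inverse family. Decorrelation restores calibration for moderate
correlation; for $|\rho| > 0.5$ (more than half the subjects shared) the
corrected test can remain inflated, so the function warns there and only
errors at $|\rho| \ge 1$.

## The simulator

`sim_config()` + `simulate_sumstats()` generate two-trait summary statistics
with known truth labels. Defaults are the canonical benchmarking
conditions: independent bi-allelic variants in Hardy–Weinberg equilibrium,
MAF 5%, additive genetic model, class proportions
$(\pi_{00}, \pi_{01}, \pi_{02}, \pi_a) = (0.99, 0.005, 0.004, 0.001)$,
odds ratio 1.15 for singly-associated variants, baseline prevalences 15%
and 10%, and 1000 cases + 1000 controls per study. Class counts are exact
by largest-remainder rounding (`assign_variant_classes()`), so $10^7$
variants give exactly 9.99 million null and 10,000 pleiotropic variants.

**Case-control (individual mode).** Disease risk follows
$\mathrm{logit}\,P(Y=1\mid X) = \alpha + \beta X$ with $\alpha$ solved so
the marginal prevalence matches the configuration (`solve_intercept()`,
monotone root-finding to $10^{-10}$ over the three genotype states).
Sampling is retrospective: the genotypes of the first $n_\mathrm{case}$
cases in an iid population stream are themselves iid from
$P(X \mid \mathrm{case}) \propto P(X)\,\mathrm{expit}(\alpha+\beta X)$, so
the generator draws genotype counts directly from that conditional
multinomial — exactly equivalent to literal rejection sampling of the
stream, at a small fraction of the cost, and with no failure mode at low
prevalence. Shared controls are a single pool drawn once (from study 1's
control distribution) and reused in both studies' fits; they are controls
for both traits by construction. Each study's marginal logistic model is
then refit from the per-variant 2×3 count table by vectorized Newton
iteration (convergence $10^{-8}$, capped steps for near-separated tables;
agreement with `glm` verified in the test suite), yielding
$\hat\beta$, $\widehat{se}$, $Z$, $p$.

**Quantitative (individual mode).** $Y_k = \beta_k (X - 2\,\mathrm{maf}) +
e_k$ with $(e_1, e_2)$ bivariate normal (variances 1, correlation
`trait_corr`); an associated variant explains `var_explained` of the trait
variance, so $\beta_k = \sqrt{\mathrm{ve}_k / (2p(1-p))}$. Trait 1 is
observed on the first $n_1$ individuals, trait 2 on the last $n_2$, giving
$n_{12}$ doubly-phenotyped individuals. Per-variant least-squares fits are
vectorized over memory-bounded chunks.

**Fast mode.** $Z_k \sim N(\mathrm{ncp}_k, 1)$ drawn directly from the
asymptotic model, with $\mathrm{ncp}_k = \beta_k/\mathrm{se}_k^\infty$ and
the design-implied cross-study correlation injected through the bivariate
normal; `effect_dist = "normal"` draws latent means $N(0, \tau_k^2)$,
matching the hierarchical model exactly. Fast mode is documented as an
approximation and is checked against the individual-level generators
(single-trait power agreement within Monte-Carlo error, and simulator
versus analytic correlation across the shared-control grid).

**What the simulator does not emulate.** Variants are independent (no
linkage disequilibrium), allele frequency is fixed, there are no
covariates, confounders, relatedness or population structure, and
individual-mode effects are fixed at the configured odds ratio rather than
drawn from the hierarchical prior. Passing calibration and power checks on
these data therefore says nothing about LD-induced dependence of
neighbouring tests, stratification artefacts, or miscalibration at low
minor allele counts; those must be handled upstream of the summary
statistics, as in any real scan.

## Benchmark harness

`rejection_rate()` estimates type-I error or power over selected truth
classes with exact Clopper–Pearson intervals — at rates near $10^{-4}$ with
$10^6$ trials the normal interval is visibly skewed. `naive_test()`
implements the conjunction rules ($p_1 < 5\times10^{-8}$ and
$p_2 < 5\times10^{-5}$ or $5\times10^{-3}$) used as scan-and-lookup
baselines. `bh_fdr()` exposes the Benjamini–Hochberg mode used when
comparing against FDR-controlling methods. `qq_data()` produces QQ tables
with pointwise Beta order-statistic bands (the exact pointwise distribution
of uniform order statistics; a simultaneous band was the open alternative,
but pointwise bands are what the comparison figures use and are far less
conservative in the extreme tail).

Calibration checks run at $\alpha \in \{10^{-2}, 10^{-3}, 10^{-4}\}$ on
$10^6$ fast-mode null variants: resolving genome-wide $5\times10^{-8}$
empirically would need on the order of $10^{10}$ null draws, whereas power
at $5\times10^{-8}$ needs only $10^4$ non-null variants and is run at the
genome-wide threshold directly. Those are also the problem sizes used by
the package's test suite, chosen so the full suite completes in a few
minutes: $10^6$ fast-mode variants for calibration and parameter recovery,
$10^5$ individual-mode variants for the shared-control end-to-end check,
$10^4$ individual-mode variants for the Sobel power bound, $10^8$
Monte-Carlo draws for the tail oracle.

## Parameter reference

| Parameter | Default | Where | Why |
|---|---|---|---|
| `exclusion_threshold` | 1e-4 | `estimate_marginal_variances()` | excludes putatively pleiotropic variants (both traits nominally associated) from variance estimation; 1e-4 separates "associated" from noise genome-wide without discarding the singly-associated variants the estimand needs |
| `p_threshold` | 1e-4 | `estimate_rho_empirical()`, `estimate_mixture_params()` | both-trait null classification for correlation / mixture estimation |
| `maf_min` | 0.01 | `filter_variants()` | Wald asymptotics are unreliable at low minor allele counts |
| `zsq_max` | 80 | `filter_variants()` | removes extreme single-trait effects that inflate the product approximation (strict `>`: 80 exactly is retained) |
| `scale` switch | u = 2 | `normprod_tail()` | series and scaled-quadrature regimes overlap at machine precision there |
| `or1`, `or2` | 1.15 | `sim_config()` | singly-associated effect size of the benchmark design |
| `prevalence1/2` | 0.15 / 0.10 | `sim_config()` | baseline disease prevalences of the benchmark design |
| `maf` | 0.05 | `sim_config()` | population MAF of the benchmark design |

## Degenerate inputs and conventions

* `sobel_test(0, 0)`: the statistic's limit along any ray is 0, so p = 1 by
  continuity; set `zero = "nan"` to propagate NaN instead.
* `dnormprod(0)` raises an error (log pole); integrate across 0 instead.
* `normprod_tail(0)` is exactly 1; negative `u` uses the symmetric tail.
* Variance estimates below 1 (sampling noise) are floored at exactly 1.
* Empty mixture classification cells give $\hat\tau^2 = 0$ with a warning.
* Duplicate variant ids within a study are an error in `harmonize()`;
  allele-set mismatches are dropped and counted; palindromic (A/T, C/G)
  variants are retained by default with a logged count, since strand
  information is rarely available — `drop_palindromic = TRUE` opts into
  dropping them.
* Coordinates are 1-based; non-autosomal records are dropped (with a count)
  by `filter_variants()`; no liftover is attempted.

## Known limitations

* The asymptotic p-value is anti-conservative for variants with very strong
  effects on exactly one trait; the $Z^2 > 80$ filter is part of the
  method, not an optional nicety.
* Decorrelation is reliable up to moderate correlation; beyond
  $|\rho| \approx 0.5$ residual inflation remains (warned).
* Two traits only; no gene- or set-level aggregation; no LD-aware
  correlation estimation (a user-supplied $\rho$, e.g. from cross-trait
  LD-score regression, can be passed to `placo_scan()`).
* The test detects statistical association with both traits; it cannot by
  itself distinguish biological pleiotropy from mediation or from LD
  between distinct causal variants.
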