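---
title: "Methods: two-sample MR for microbiome-disease screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for microbiome-disease screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromr)
```

## The design

micromr implements two-sample Mendelian randomization from summary
statistics only: variant–exposure associations come from one study
population (quantitative exposures on a per-SD scale, e.g. microbial taxon
abundances), variant–outcome associations from a non-overlapping
case-control study (log-odds scale). The causal estimand is the log odds of
disease per SD of exposure. Identification rests on the three instrumental
variable assumptions — relevance (the variant predicts the exposure),
exchangeability (the variant is independent of exposure–outcome
confounders), and exclusion restriction (no effect on the outcome except
through the exposure). The pipeline enforces relevance empirically
(significance and F screens) and probes directionality (Steiger); the other
two assumptions are unverifiable from summary data, which is why the
synthetic module makes their violation simulable rather than pretending it
is detectable.

## Pipeline stages and the parameters that matter

**Significance filter.** Keep variants with p strictly below `p_threshold`
(default 1e-8). This default is deliberately stricter than the conventional
genome-wide 5e-8; it is the screening threshold of the study design this
package reproduces, and it is exposed as a parameter. A variant at exactly
the threshold is excluded — boundary behavior is fixed so results are
reproducible bit for bit.

**LD clumping.** Greedy: repeatedly take the remaining candidate with the
smallest p-value as an index variant and discard candidates on the same
chromosome within `clump_window_bp` (default 10 Mb, inclusive at both ends)
whose squared correlation with it exceeds `clump_r2` (default 0.001 — near
"no residual correlation", appropriate when downstream estimators assume
independent instruments). Ties on p-value break by (chrom, pos, variant_id),
so output is invariant to input row order. The signed reference r is squared
for the test; cross-chromosome pairs are never clumped, whatever the
reference stores. A candidate missing from the LD reference is an error
rather than a silent r = 0: absence of evidence of LD is not evidence of
independence.

**Weak-instrument screen.** Single-variant F = (beta/se)^2, the squared z
score; variants with F < `min_f` (default 10, the conventional
weak-instrument rule of thumb) are dropped, F exactly 10 is retained. The
textbook alternative F = r2(n-2)/(1-r2) with r2 = z^2/(z^2+n-2) is exposed
as an option but is algebraically identical for a single variant. Filter
order is significance → clump → F; the order matters only for which index
variants survive (an index dropped by the F screen does not resurrect the
variants it clumped away) and is fixed and logged.

**Harmonization.** Outcome effects are re-expressed on the exposure's
effect allele: identical orientation copies, swapped alleles negate beta
and reflect the allele frequency, strand-complemented configurations are
complemented first. Palindromic pairs (A/T, C/G) are excluded outright on
either side — the package never attempts frequency-based strand inference,
which is why a missing exposure eaf is tolerated on read. Allele sets that
match under neither swap nor complement are excluded as `allele_mismatch`
(the remaining "ambiguity" class for biallelic SNVs). The MAF rule excludes
variants with minor-allele frequency at or below `maf_threshold` (0.01,
inclusive), using the exposure-study frequency — the exposure defines the
instrument — with the aligned outcome frequency as fallback. The boundary is
implemented as `eaf <= t || eaf >= 1 - t`, which is the same set in exact
arithmetic but immune to the floating-point artifact that makes
`1 - 0.99 > 0.01`.

**Estimation.** Per-instrument Wald ratios theta_j = beta_y/beta_x. The
default SE is the first-order delta method se_y/|beta_x|
(`wald_se_order = 1`), matching the dominant convention in summary-data MR
toolchains; `wald_se_order = 2` adds the exposure-noise term
beta_y^2 se_x^2 / beta_x^4 under the square root. The first-order form is
exact under the null (the beta_x noise cancels from the test statistic) but
under-covers for large true effects: the neglected variance fraction is
(theta se_x / se_y)^2, independent of instrument strength. The package's
own recovery test therefore uses the second-order form at theta = 0.5,
while null calibration uses the default. Pooling is fixed-effect IVW;
random-effects variants are deliberately absent because the target designs
carry 1–2 instruments per exposure, where heterogeneity models are
undefined — Cochran's Q is still reported when at least two instruments
survive. Results are reported as OR = exp(theta) with a `ci_level` (0.95)
normal interval and a two-sided Wald p computed in the upper-tail form, so
deep tails (|z| > 8) keep full precision; p is clamped to stay in (0, 1].
`pvalue_from_or_ci()` inverts a printed OR/CI triplet back to its p-value
and is used to check published triplets for internal consistency.

**Steiger directionality.** Per-side explained variance is the sum over
instruments of z^2/(z^2 + n - 2). For the binary outcome this is a
pseudo-r2 on the test-statistic scale using the total sample size; the
paper-trail for binary-trait r2 conventions is thin, so this approximation
is documented rather than hidden, and `steiger_effective_n = TRUE` switches
to the effective case-control size 4/(1/n_case + 1/n_control). Direction is
"forward" (exposure → outcome) when r2_x > r2_y strictly; a tie is
conservatively not-forward. The p-value compares Fisher-z-transformed
correlations with variance 1/(n-3) per side. No multiplicity correction is
applied beyond the nominal `alpha` = 0.05 — mirroring the screening design —
though downstream users can apply any correction to the returned p-values.

## The synthetic world

`simulate_sumstats()` draws summary statistics directly from their sampling
distribution ("fast" mode): standardized marginal exposure effects
b_x = R gamma (R the block-diagonal AR(1) LD matrix), estimates
N(b_x, R/n_x); outcome log-odds effects b_y = R(theta gamma + phi) with
per-variant sd 1/sqrt(n_y c(1-c)) (logistic score approximation at case
fraction c) and R-correlated noise. Effects are converted to the per-allele
scale by 1/sqrt(2f(1-f)) with each study's own allele frequency; frequencies
are Uniform(0.05, 0.95) in the exposure study and shared with the outcome up
to Normal(0, 0.002) jitter — about the magnitude of frequency differences
between large European-ancestry panels; chosen once, not tuned. Alleles are
drawn from the eight non-palindromic ordered pairs, so default data loses
nothing to the palindrome exclusion and power properties are interpretable.

Defaults state the world the calibration tests live in: n_x = 1800,
n_y = 11600 at case fraction 0.41 — one tenth of the consortium magnitudes
the design mirrors, keeping Monte-Carlo runs in seconds — three loci of five
variants (rho = 0.5), one causal variant per locus with per-SD effect
sqrt(100/n_x), i.e. expected F ≈ 100: unambiguously strong instruments, so
selection is essentially deterministic and calibration results measure the
estimator, not selection noise. The recovery test strengthens instruments
to F ≈ 400 (effect sqrt(400/n_x)) so the Wald ratio's known O(1/F)
finite-sample bias (about 1% of theta at F = 100) sits below Monte-Carlo
resolution; this was set from the bias formula, not tuned on outcomes.

`reverse = TRUE` swaps the causal roles before generation: instruments
drive the outcome trait and the exposure inherits theta times its
liability, so the genetic signal migrates to the outcome side — the
scenario Steiger is meant to catch. Confounder loadings
(`confounder_effect_x/_y`) deserve a note: because instruments are
independent of the confounder by construction, they contribute **no**
per-variant bias to either GWAS in expectation — confounding distorts the
observational X–Y association, not the genetic associations. They therefore
only constrain variance budgets in fast mode and enter the individual-level
liability explicitly; "confounding-only" scenarios yielding nominal type-I
error is precisely the IV premise stated as a testable property. Horizontal
pleiotropy (`phi` on instruments) does bias the estimator, and the test
suite demonstrates the inflation rather than hiding it.

The "individual" mode exists solely as a distributional oracle: it
generates genotypes, a confounder, the exposure trait, and Bernoulli
outcomes, then regresses per variant (linear / logistic). Genotypes are
Gaussian dosages linearly mapped to the allele-count scale rather than
thresholded binomial haplotypes: thresholding attenuates realized LD below
the reference R, which would make fast-vs-individual agreement fail for
reasons unrelated to the claim being tested. Consequences: agreement checks
compare exposure-side moments (where the linear model is exact), and the
generator makes no claim to genotype realism.

What the generator does **not** emulate — and hence what a green test does
not establish: zero-inflated, compositional microbiome abundance
distributions; population stratification; sample overlap between exposure
and outcome studies; winner's curse from in-sample instrument discovery;
indels and multi-allelic sites; realistic LD beyond block AR(1).

## Numerical and degenerate-input choices

- All threshold comparisons are strict or inclusive exactly as printed in
  the interface docs (keep p < t; drop F < f_min; exclude MAF <= t), so a
  value at a boundary behaves identically on every platform.
- An exposure whose best p-value misses the threshold yields a
  `no_instruments` result row, never an error or a silent drop; a
  malformed exposure file is isolated as an `error` row while shared
  inputs (outcome, LD reference) fail fast.
- Empty result collections write a header-only table with a warning.
- `wald_ratio()` refuses beta_x = 0 (undefined ratio); `ivw_pool()` of one
  element returns it with Q = 0 identically, so Wald-ratio and IVW code
  paths coincide exactly at n_iv = 1.
- Steiger r2 sums are capped just below 1 before the atanh transform.
- Tables round-trip through their TSVs at 12 significant digits.

## Known limitations

Fixed-effect IVW only (no MR-Egger, weighted median/mode, or outlier
sensitivity analyses); no proxy-variant rescue for instruments missing in
the outcome; variant matching is by identifier, not position; the binary
Steiger r2 is an approximation, and with a single instrument the Steiger
comparison has low power; the synthetic LD reference replaces, and is
simpler than, a genotype reference panel.
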