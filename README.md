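# micromr

Two-sample Mendelian randomization (MR) from GWAS summary statistics, built
for causal screens of many weakly heritable quantitative exposures — the
motivating case is gut microbial taxon abundances — against one binary
disease outcome such as multiple sclerosis. Observational microbiome–disease
associations are prone to confounding and reverse causation; MR sidesteps
both by using genetic variants as instrumental variables: alleles are
randomized at conception, so a variant that raises a taxon's abundance and
also raises disease risk is evidence for a causal effect of the taxon,
provided the variant is strong, independent of confounders, and affects the
outcome only through the exposure.

## What it computes

For each exposure *X* (per-SD scale) against the outcome *Y* (log-odds
scale):

1. **Instrument selection** — keep variants with *p* < 1×10⁻⁸, greedily
   LD-clump them (*r*² ≤ 0.001 within a 10 Mb window, most significant
   variant kept as index), and drop weak instruments with
   *F* = (β̂ₓ/se)² < 10.
2. **Harmonization** — re-express each outcome association on the
   exposure's effect allele (allele swap → sign flip; strand flip →
   complement), excluding palindromic (A/T, C/G) variants, unresolvable
   allele sets, and variants with MAF ≤ 0.01.
3. **Estimation** — per-instrument Wald ratios θ̂ⱼ = β̂yⱼ/β̂xⱼ with
   delta-method SEs, pooled by fixed-effect inverse-variance weighting:
   θ̂ = Σwⱼθ̂ⱼ/Σwⱼ, se = (Σwⱼ)^(−1/2), wⱼ = seⱼ⁻²; reported as
   OR = exp(θ̂) with 95% CI and two-sided Wald *p*, plus Cochran's *Q*.
4. **Directionality** — the Steiger test compares instrument-explained
   variance on the two sides via Fisher-z-transformed correlations,
   flagging associations whose genetic signal actually lives on the
   outcome side (reverse causation).

A synthetic-data module generates paired exposure/outcome summary
statistics with known ground truth (causal effect, block LD, pleiotropy,
confounding, reverse causation), so calibration and recovery are testable
offline — no real GWAS downloads are needed anywhere in the package.

## Worked example

```r
library(micromr)

# Synthetic panel: 3 taxa with true causal effects +0.7, 0, -0.7
# (log odds per SD of abundance) on a shared binary outcome
paths <- make_panel(k_taxa = 3, thetas = c(0.7, 0, -0.7),
                    dir = "demo", seed = 42)
run <- mr_run(mr_config(paths$exposure_paths, paths$outcome_path,
                        paths$ld_dir))
run$results[, c("exposure_id", "n_iv", "or", "ci_low", "ci_high",
                "pvalue", "steiger_direction")]
```

```
       exposure_id n_iv    or ci_low ci_high   pvalue steiger_direction
1 exposure_taxon01    3 1.794  1.656   1.943 1.91e-46           forward
2 exposure_taxon02    3 1.032  0.934   1.140 5.39e-01           forward
3 exposure_taxon03    3 0.545  0.498   0.596 8.01e-41           forward
```

Taxon 1 (true θ = 0.7, true OR = e^0.7 ≈ 2.01) is recovered as a risk
factor with OR 1.79 (the small gap is sampling noise at these sample
sizes), taxon 3 as protective (true OR ≈ 0.50, estimated 0.55), and the
null taxon 2 is correctly non-significant (p = 0.54). `forward` means the
Steiger test supports exposure → outcome causation for all three.
`forest_data(run)` returns the significant rows ordered for a forest plot:

```
             label    or ci_low ci_high   pvalue      class
2 exposure_taxon01 1.794  1.656   1.943 1.91e-46       risk
1 exposure_taxon03 0.545  0.498   0.596 8.01e-41 protective
```

Each `mr_run()` also emits per-variant selection and exclusion logs and a
JSON run report with per-stage instrument counts (candidates → significant
→ post-clump → post-F → harmonized).

A command-line front end covers the same three entry points:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "micromr", package = "micromr"))')
Rscript $CLI simulate --k 3 --thetas 0.7,0,-0.7 --seed 42 --out demo
Rscript $CLI run --exposures demo/exposure_taxon01.tsv --outcome demo/outcome.tsv \
    --ld-dir demo/ld --out demo/results
```

## File formats

All files are tab-separated with headers. Summary statistics:
`variant_id chrom pos effect_allele other_allele eaf beta se pvalue n`
(binary outcome adds `n_case n_control`). LD reference: a directory with
`positions.tsv` (`variant_id chrom pos`) and `ld.tsv` (`id_a id_b r`,
sparse signed correlations; absent pairs mean r = 0). See the methods
vignette (`vignettes/micromr-methods.Rmd`) for the statistical model,
parameter choices, and known limitations.
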