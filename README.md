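# regeqtl

Case/control association analysis over **brain-regulatory eQTLs**, with
gene-level Bayesian integration of eQTL and association evidence.

Genome-wide scans of a binary trait spend their multiple-testing budget
on millions of variants, most with no interpretable mechanism. This
package implements the alternative strategy of testing only expression
quantitative trait loci (eQTLs) that sit in regulatory chromatin:
significant brain eQTLs are intersected with accessibility peaks
(histone ChIP-seq / ATAC / DNase) and Hi-C loop-anchor territory, the
surviving variants get a quality-controlled additive logistic
association with covariates, LD clumping picks one index variant per
block (lowest p, r² ≥ 0.6), and Benjamini–Hochberg FDR < 0.1 over the
indices defines the significant loci. Hits are replicated against an
independent case cohort and aggregate allele-frequency controls
(Fisher exact on reconstructed 2×2 allele tables plus direction
consistency), and genes are scored by

LBF = Σᵢ log₁₀( π₁·bfᵢ + (1 − π₁) ),  bfᵢ = √(Vᵢ/(Vᵢ+W)) · exp(zᵢ²W / 2(Vᵢ+W))

— a Wakefield approximate-Bayes-factor mixture in which eQTLs
unsupported by association evidence (bf < 1) pull the gene score down.
Genes need LBF > 0 and permutation p < 5e−3 in **both** cohorts, and a
protein-coding annotation, to be selected. Expression
(covariate-adjusted logistic DE with permutation empirical p-values and
sex-stratified specificity calls) and EHR carrier contrasts
(per-diagnosis Fisher tests under BH) complete the follow-up.

Every input can be simulated with planted ground truth
(`sim_config()` + the `simulate_*()` generators), so the whole chain is
validated end to end: planted odds ratios are recovered without bias,
null cohorts stay calibrated (uniform p, λ ≈ 1), and every printed
threshold is enforced exactly.

## Worked example

Simulate a cohort of 300 cases / 150 controls with one planted risk
eQTL (odds ratio 1.67 per alt allele at MAF 0.3, lowering expression of
gene G0001) and run the full pipeline:

```r
library(regeqtl)
cfg <- sim_config(n_cases = 300, n_controls = 150, n_variants = 600,
                  n_genes = 50, seed = 2)
run <- run_pipeline(cfg, B_lbf = 999)
print(run)
#> regulatory-eQTL pipeline run
#>   significant_eqtl_rows        339
#>   candidate_variants           66
#>   in_accessibility             47
#>   in_accessibility_and_loops   42
#>   post_qc                      42
#>   index_eqtls                  42
#>   significant_indices          1
#>   replicated_loci              1
#>   selected_genes               0
#>   lambda_gc                    1.0220
```

The funnel reads top to bottom: 339 significant catalog rows collapse
to 66 candidate variants, 42 survive the regulatory (peak ∩ loop
anchor) restriction and QC, clumping leaves 42 indices, and one index
clears FDR < 0.1 — the planted variant:

```r
run$clumped[run$clumped$significant,
            c("variant_id", "or_", "ci_lo", "ci_hi", "p", "q_index")]
#>   variant_id  or_ ci_lo ci_hi       p q_index
#> 1    v000300 1.68  1.21  2.34 0.00206  0.0867

run$replication[, c("variant_id", "p_array", "retained", "reason")]
#>   variant_id  p_array retained     reason
#> 1    v000300 2.19e-08     TRUE replicated
```

The estimated OR 1.68 (95% CI 1.21–2.34) brackets the planted 1.67,
λ = 1.02 shows no inflation from the remaining null variants, and the
locus replicates against the simulated array cohort and aggregate
control frequencies with a consistent direction. (`selected_genes` is 0
here because at a 42-variant permutation pool the gene-level empirical
p cannot reach 5e−3; see the methods vignette.)

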