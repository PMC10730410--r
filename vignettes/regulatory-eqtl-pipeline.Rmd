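---
title: "Methods: regulatory-eQTL case/control association and gene-level integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-eQTL case/control association and gene-level integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regeqtl)
```

## The analysis

`regeqtl` implements a genomic association analysis that prioritizes
brain expression quantitative trait loci (eQTLs) lying in regulatory
regions, rather than scanning the whole genome. The motivation is
statistical: restricting the test set to variants with a plausible
mechanism (they alter gene expression, and they sit in chromatin that is
open and engaged in enhancer contacts) cuts the multiple-testing burden
by orders of magnitude and concentrates power on interpretable signals.
The pipeline has six analysis stages, each exposed as ordinary R
functions, plus a synthetic-data module that generates every input with
planted, recoverable structure.

1. **Test-set construction.** An eQTL catalog over 13 brain regions is
   filtered to rows with FDR < 0.05 (strict) in at least one region; the
   deduplicated variant set forms the association candidates. Candidates
   are then restricted to *regulatory regions*, defined as the interval
   intersection of (a) the union of all accessibility peaks (histone
   ChIP-seq, ATAC, DNase assays) and (b) the union of chromatin-loop
   anchor intervals. A survival funnel reports counts at each stage.
2. **Sample QC.** Windowed LD pruning; genotype PCA (variants
   standardized by mean $2p$ and SD $\sqrt{2p(1-p)}$); ancestry
   estimated per sample as a mixture over five reference-population
   centroids in top-10 PC space, solved by generalized least squares
   under the Mahalanobis metric of the pooled within-population PC
   covariance, clamped to the simplex; samples retained at European
   weight ≥ 0.90. Relatedness by the PLINK-style method-of-moments
   IBS→IBD decomposition; pairs with $\hat\pi > 0.12$ lose one random
   (seeded) member.
3. **Association.** Per-call masking (DP < 20 or GQ ≤ 30 → missing),
   then per-variant QC: fail when non-biallelic, MAF ≤ 0.05, or missing
   fraction > 0.1. Each passing variant gets an additive logistic
   regression of case status on dosage with sex and 10 ancestry
   covariates; Wald $z$, two-sided $p$, OR and 95% CI as exp
   transforms. Genomic inflation $\lambda$ = median $\chi^2$ /
   `qchisq(0.5, 1)`. Greedy LD clumping (sort by $p$; assign unclaimed
   variants with $r^2 \ge 0.6$ within 1 Mb to the current index) is
   followed by Benjamini–Hochberg FDR over the *index* p-values only;
   indices with $q < 0.1$ are the significant loci.
4. **Replication.** Significant indices are contrasted against an
   independent case cohort and an aggregate control panel where only
   allele counts exist. The statistic is a two-sided Fisher exact test
   on the reconstructed 2×2 allele table with a Woolf CI
   (Haldane–Anscombe 0.5 on zero cells); a locus is retained iff the
   case-cohort contrast is nominally significant (p < 0.05), its
   direction matches the discovery direction, and the aggregate-panel
   contrast direction matches as well.
5. **Gene-level integration.** Each gene's significant eQTLs are scored
   by a log10 Bayes factor built from Wakefield approximate Bayes
   factors,
   $\mathrm{bf}_i = \sqrt{V_i/(V_i+W)}\,
   \exp\!\left(z_i^2 W / (2(V_i+W))\right)$,
   mixed with the prior probability $\pi_1$ that an eQTL is also
   trait-associated:
   $\mathrm{LBF} = \sum_i \log_{10}\!\big(\pi_1 \mathrm{bf}_i +
   (1-\pi_1)\big)$.
   Because $E_0[\mathrm{bf}] = 1$, null eQTLs contribute ≈ 0 and
   sub-null eQTLs (bf < 1) contribute negatively — a gene is penalized
   when some of its eQTLs carry no association signal, which is the
   qualitative contract of Bayesian eQTL/GWAS integration scores.
   Significance is empirical: B size-matched random eQTL sets from the
   tested-variant pool, $p = (b+1)/(B+1)$. Final genes must have
   LBF > 0 and $p < 5\times10^{-3}$ in *both* cohorts and be annotated
   protein-coding.
6. **Expression and EHR follow-up.** Differential expression runs the
   regression in the direction the analysis specifies — group as
   outcome, z-scored expression as predictor — with sex and age (and
   study, when more than one) as covariates, BH FDR across genes;
   small-sample datasets use permutation empirical p-values with labels
   permuted within study strata. Sex-stratified runs call a gene
   male-specific iff FDR < 0.05 in males but > 0.05 in females (and
   mirrored). EHR carrier contrasts use per-category Fisher exact tests
   with BH across the 15 diagnostic categories, rank-sum for age,
   Fisher for sex, and an optional sex/age-adjusted logistic
   sensitivity model.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| eQTL FDR threshold | 0.05 (strict) | catalog significance per region |
| MAF floor | 0.05 (strict) | minor-allele frequency in analyzed samples |
| DP / GQ mask | keep DP ≥ 20, GQ > 30 | per-call quality gates |
| missing ceiling | 0.10 | variant call-missingness tolerance |
| clump $r^2$ | 0.6, window 1 Mb | LD block membership |
| index FDR | 0.1 (strict) | BH over index p-values after clumping |
| ancestry gate | EUR weight ≥ 0.90 | sample retention |
| $\hat\pi$ gate | > 0.12 | third-degree-or-closer relatedness |
| $W$ | 0.1 (log-odds$^2$) | prior effect variance at a true joint signal |
| $\pi_1$ | 0.1 | prior probability an eQTL is trait-associated |
| B | 999 (gene), 1000 (DE) | permutations |
| gene selection | LBF > 0, p < 5e-3, both cohorts, coding | final list |

All thresholds are strict inequalities, matching how the rules are
printed; this is enforced by dedicated boundary tests. The clump window
(1 Mb) and the number of ancestry covariates in the association model
(10) are our choices where the procedure leaves them open; both are
arguments. MAF is computed on cases and controls combined.

## The synthetic-data generator

The generator's defaults are the study conditions: 986 cases and 415
controls; one planted risk eQTL with odds ratio 1.67 per alt allele at
MAF 0.3, targeting gene G0001 with a negative expression beta; a
13-region catalog; per-call low-quality fractions of 2%; diagnostic
prevalences matching the curated category table (pain 0.695, anxiety
0.526, bipolar disorder 0.423, ...). Genotypes are two binomial allele
draws at the population frequency; case status follows a logistic model
whose intercept is calibrated to the case fraction, and exact
case/control quotas are filled by retrospective sampling from a
population pool — retrospective sampling shifts only the intercept of a
logistic model, so the planted odds ratios are recoverable without bias
by the downstream fit (verified to ±0.1 over replicates). A single run
seed drives everything; each generator draws from a deterministically
derived sub-stream, so any module's inputs can be regenerated
independently and runs are byte-identical under a fixed seed.

Catalog rows are generated as effect estimates with noise: planted and
"true" background eQTLs carry effects large enough that their
within-region BH FDR falls below 0.05 by construction, while decoy rows
are genuine null draws, so the decoy FDR ensemble behaves like a null
BH ensemble (a handful of chance sub-0.05 decoys can occur, as in real
catalogs). Regulatory tracks cover each significant eQTL position with
a peak and a loop anchor independently at the configured fractions, so
expected survival of the peak∩loop selection is their product;
background intervals are placed away from candidate positions so the
fractions are exact.

What the generator does **not** emulate: realistic LD beyond chance
correlation (no haplotype or coalescent structure — clumping is
exercised on engineered correlated blocks in the tests instead),
genotype-calling error modes beyond the DP/GQ tails, catalog
effect-size/allele-frequency coupling, expression count noise (values
are Gaussian on a normalized scale), and ICD-code adjudication (the
category table is taken as given). Passing tests therefore demonstrate
the statistical machinery is correct and calibrated, not that real
cohorts would yield comparable yields at each funnel stage.

Sex and age are drawn independently of genotype; the 10 emitted
ancestry-covariate columns are standard-normal placeholders standing in
for computed PCs, because the default cohort is a single homogeneous
population in which genotype PCs carry no structure (computing them at
study scale would cost an $O(n^2 m)$ SVD for no statistical content).
`compute_pca` itself is exercised on structured two-population cohorts
(Balding–Nichols divergence) in the sample-QC tests.

## Numerical choices and degenerate inputs

- **Coordinates.** All interval containers are `GRanges` (1-based
  closed); BED/BEDPE 0-based half-open input is converted exactly once
  at ingest, so a BED interval $[s,e)$ becomes $[s+1, e]$ and the
  membership rule "1-based position $p$ is inside $[s,e)$ iff
  $s \le p-1 < e$" is preserved verbatim (boundary-enumerated in the
  tests).
- **λ denominator** is `qchisq(0.5, 1)` (= 0.45494 to the printed
  precision) so that a degenerate scan with all $p = 0.5$ gives
  exactly λ = 1.
- **Separation.** Perfect or quasi-separation flags the fit unstable; a
  Firth (Jeffreys-penalty) refit is available behind an argument.
  Aliased (collinear) covariate columns get NA standard errors rather
  than poisoning the whole fit; constant covariates within a stratum
  (e.g. sex inside a single-sex run) are dropped from the design.
- **Zero cells** in 2×2 tables get the Haldane–Anscombe 0.5 correction
  for the OR and CI only; exact p-values are computed on the raw table.
- **Ties in clumping** are broken by position then alt allele, and pair
  removal in relatedness pruning processes pairs by descending
  $\hat\pi$ then pair id, making both deterministic and
  row-order-invariant.
- **Empirical p-values** are never zero: $(b+1)/(B+1)$ throughout.
- **Ancestry weights**: the equality constraint (weights sum to 1) is
  imposed by a Lagrange correction inside the GLS solve, then negative
  weights are clamped and renormalized. An unconstrained regression can
  return uninterpretable negative "proportions"; the clamp is the
  documented trade-off. Pooled (not per-population) within-population
  covariance defines the Mahalanobis metric.

## Design decisions where the procedure was open

- "Overlap between the accessibility and loop layers" is implemented as
  the intersection of the assay-peak union with the loop-*anchor* union
  (not the full loop span): anchors are the enhancer-like territory,
  while spans would cover most of the genome. The union of the two
  layers is available by passing the accessibility set alone.
- The replication statistic is not dictated by a frequency-only control
  resource; we adopt Fisher's exact test on reconstructed allele counts
  with a direction-consistency requirement, and no multiplicity
  correction at this confirmatory stage (few loci). Genotype-level
  replication applies when genotypes exist for the replication cohort.
- The gene score is a documented Wakefield-ABF mixture surrogate for
  black-box Bayesian integration tools: it reproduces the qualitative
  contract (positive score ⇔ support; unsupported eQTLs penalize) with
  two interpretable priors ($W$, $\pi_1$) rather than claiming any
  specific published tool's three-class model.
- DE permutations are stratified by study so permuted datasets preserve
  study margins exactly; unstratified permutation would let the study
  covariate absorb permuted signal inconsistently.
- FDR for index selection is computed after clumping, over index
  variants only; applying FDR before clumping is deliberately not
  supported.
- In the acceptance script the planted-recovery run sets the regulatory
  overlap fractions to 1: the planted locus models a *regulatory* risk
  eQTL, so recovery is measured conditional on membership in the test
  set rather than convolved with the Bernoulli coverage draw.

## Problem sizes used in the shipped checks

Module tests run on cohorts of 150–400 samples and 300–600 variants.
The calibration checks use a global-null cohort of 10,000 variants at
the full 986/415 sample size (uniform p by Kolmogorov–Smirnov,
λ ∈ [0.95, 1.05]), 200 small null replicates for index-FDR control,
and 200 genes for the permutation-null rate. Parameter recovery runs
100 replicates at 986/415 with the planted OR 1.67 / MAF 0.3 eQTL among
40 variants, requiring detection (index $q < 0.1$) plus cross-cohort
replication in ≥ 80%, and 50 of those replicates feed the
planted-vs-decoy gene ranking. The acceptance script scales the full
pipeline to 4,000 variants / 300 genes. These sizes are our choices for
a demonstrably calibrated desk-scale harness; headline yields of the
original cohort-scale analysis (hundreds of thousands of catalog rows)
are not reproducible from synthetic data and are not claimed.

## Known limitations

- The permutation pool for the gene-level empirical p contains the
  gene's own eQTLs; at desk-scale pools (tens to hundreds of variants)
  the re-draw probability puts a floor under $p_{\mathrm{emp}}$ for
  strong single-eQTL genes. At realistic pool sizes (10^5 variants) the
  floor is negligible. The pipeline reports the score and p as
  computed; tests assert calibration, not yield.
- IBD moment estimates assume complete genotypes per pair and
  reasonably well-estimated allele frequencies; KING-robust kinship and
  haplotype-aware pruning are out of scope.
- The Firth fallback is a plain Jeffreys-penalty Newton iteration
  without step-halving; extreme designs may need the default Wald path
  plus the separation flag instead.
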