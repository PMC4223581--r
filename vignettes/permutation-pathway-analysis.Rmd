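---
title: "Permutation-based pathway analysis for GWAS: models, parameters and design"
author: "permpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based pathway analysis for GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permpath)
```

## The statistical model

`permpath` tests whether biochemical pathways are over-represented among
the genes implicated by a case–control GWAS, and uses permutation nulls
to separate genuine enrichment from artefacts of the SNP-to-gene
mapping.

The chain of models is:

1. **Per-SNP association.** Genotypes are coded additively (0/1/2 minor
   alleles). The default test is the Cochran–Armitage trend test, the
   1-df score test of the additive model, computed through the identity
   `chi2 = N * r^2` with `r` the genotype–phenotype correlation over
   non-missing samples. A covariate-adjusted logistic regression (Wald
   or likelihood-ratio, 1 df) is available for the unpermuted analysis;
   the two agree asymptotically without covariates. Population
   stratification is handled by genomic control: the inflation factor
   λ is the median observed chi-square divided by the 1-df chi-square
   median (≈ 0.4549), clamped at 1, and statistics are deflated by λ.
   The clamp (no *inflation* of significance when λ < 1) is the
   standard convention; it is a choice, not a theorem.

2. **Gene significance.** A gene is significant iff at least one SNP
   mapped to it has p < α (strict inequality; α defaults to 0.05, and
   the GC-adjusted p is used whenever genomic control was applied).
   Multi-gene SNPs count for all their genes. Per-SNP p-values are
   deliberately *not* multiplicity-adjusted at this stage. Under the
   null a gene with *m* independent SNPs is significant with
   probability 1 − (1 − α)^m — the size bias that motivates everything
   that follows. Size-normalised alternatives
   (`normalized_gene_score()`: significant-SNP count divided by SNP
   count or gene length) are provided; they remove the bias but need a
   user-chosen score cutoff for which no principled default exists, so
   the binary rule remains the default.

3. **Over-representation.** Exact hypergeometric tails for enrichment
   and depletion, computed in log space (`lchoose` + log-sum-exp), so
   they remain accurate for universes up to ~1e5 genes. Pathways with
   fewer than two genes in the universe are excluded before testing;
   we read "fewer than two genes located onto the pathway" as a
   condition on universe genes (i), not significant genes (k), because
   a k-based rule would exclude most pathways under permutation nulls —
   the k-based variant is available via `exclude_on = "significant"`.
   Benjamini–Hochberg adjustment is applied separately to the enriched
   and depleted p-value families (mixing tails in one family would make
   the two tails compete; a joint mode exists).

4. **Permutation nulls.** Three constructions, each preserving a
   different aspect of the data:

   | strategy   | shuffles            | preserves                       | destroys |
   |------------|---------------------|---------------------------------|----------|
   | columns    | case–control labels | LD, gene sizes, (cases, controls) | genotype–phenotype link |
   | rows I     | SNP ↔ p assignment  | p multiset, significant-SNP count | LD, SNP–gene clustering |
   | rows II    | gene labels         | significant-gene count, pathway sizes | gene-size bias structure |

   For pathway R, `p_perm = #{n : p_n ≤ p_original} / N`, ties counting
   as at-least-as-significant (conservative), with an optional
   pseudo-count `(count+1)/(N+1)` to avoid exact zeros. The comparison
   uses unadjusted tail p-values: BH is a monotone within-run transform,
   so it cannot change which runs beat the original, and it is
   ill-defined across runs. Row II is exactly the hypergeometric model
   — its permutation p converges to `p_enriched` by construction — so
   it can only confirm the analytic test, never diagnose its size bias;
   columns and rows I can.

## Tunable parameters

* `alpha` (per-SNP significance, default 0.05): the gene rule's
  threshold. Decreasing it to 0.01/0.001/0.0001 collapses the
  significant-gene set very quickly (most genes enter through exactly
  one borderline SNP); `alpha_sweep()` quantifies this.
* `n_perms` (default 2,000): see the convergence analysis below.
* QC thresholds (`qc_thresholds()`): MAF ≥ 0.03, call rate > 0.95
  (the boundary itself excluded), HWE α = 0.05 in controls and 0.001 in
  cases; the case-stratum rule can be disabled (`NA`) for designs that
  screen controls only, and a 1% MAF floor fits rarer-variant panels.
* `pseudo_count` (default off): the raw estimator is unbiased but can
  be zero; the pseudo-count version is preferred when `p_perm` feeds a
  CV (division by a zero mean) or a log scale.
* `recompute_gc` (columns strategy, default off): with the flag off,
  permuted runs are deflated by the *original* run's λ so that original
  and permuted p-values live on the same scale — comparing a
  GC-adjusted original against unadjusted permutations mis-calibrates
  `p_perm` whenever λ > 1. Turning the flag on recomputes the median
  λ inside every run (the fully self-contained variant; costlier and,
  under label exchange, nearly identical since each permuted λ
  estimates the same quantity).

## The synthetic generator

`simulate_gwas()` emulates the statistical structure the analysis
assumes, not human genetics per se:

* **LD** by a block-copy haplotype model: each of a sample's two
  haplotypes copies the block-anchor allele with probability `ld_r`,
  else draws independently at the SNP's own frequency. This creates the
  clustered-significant-SNP structure that makes rows-I permutations
  anticonservative, with a single tunable correlation, at a fraction of
  the cost of a coalescent. It does not produce realistic LD decay,
  recombination hotspots or allele-frequency spectra.
* **Gene sizes** from a shifted negative binomial (mean + dispersion),
  rescaled to sum exactly to `n_snps`; small dispersion yields the
  long-gene tail that drives the size bias. Genes are identifier-based:
  no genomic coordinates are simulated because the analysis only ever
  uses the SNP→gene relation. The SNP-to-gene assignment rule of real
  annotation pipelines (window sizes, manufacturer annotations) is thus
  made explicit rather than imitated.
* **Phenotypes** by retrospective quota sampling: a logistic disease
  model with per-allele log-odds `log(causal_odds_ratio)` at each
  causal SNP, intercept calibrated by root-finding to a marginal case
  fraction of 0.3 (so quota rejection sampling stays cheap), genotype
  batches drawn until exactly `n_cases`/`n_controls` are retained. The
  default cohort scale (909 cases / 2,120 controls) matches a typical
  dilated-cardiomyopathy screening cohort; tests and examples scale
  down. Allele frequencies are drawn once per configuration — they are
  a property of the simulated array, shared by all batches.
* **Pathways** with uniform sizes, a configurable shared-gene fraction
  (0 switches to exactly disjoint sampling) and causal pathways forced
  to contain the genes of their planted SNPs.

What passing tests on this generator do **not** show: robustness to
population structure and admixture (only the global λ correction is
modelled), imputation artefacts, X-chromosome coding, quantitative
traits, or annotation-driven mapping biases beyond SNP count.

## Numerical choices

* Hypergeometric tails: log-space term sums with log-sum-exp; terms
  outside the support carry `C(i, j) = 0` and vanish. Verified to 1e-12
  against exhaustive placement enumeration for universes up to 20
  genes, and against the standard distribution functions elsewhere.
* Trend test degeneracies: zero genotype variance (or identical group
  distributions) gives chi2 = 0, p = 1; an all-missing column is
  undefined and dropped. Logistic fits that separate (boundary fitted
  probabilities) or fail to converge raise classed errors; the
  association stage drops such SNPs with a warning.
* HWE: 1-df chi-square goodness-of-fit on genotype counts per phenotype
  stratum (allele frequency estimated, hence one df), matching the
  long-standing default behaviour of GWAS toolchains; an exact test is
  deliberately out of scope. Cells with zero expectation contribute
  zero.
* Seeding: every stage derives per-purpose streams from a single base
  seed (a Lehmer-style integer map), and the permutation engine derives
  one stream per run index, so results are identical regardless of
  execution order.
* `subsample_cv()` draws without replacement from the *realized* runs;
  the per-subsample success count of such a draw is hypergeometric, so
  counts are generated directly from that distribution —
  distributionally identical to enumerating the draws and much faster.
  The analytic cross-check is
  `cv = sqrt((1-p)(N-m) / (p m (N-1)))`, the CV of a finite-population
  proportion estimate; note the factor (N−m) forcing CV → 0 as m → N.

## How many permutations?

Subsampling m of N = 20,000 realized runs for a borderline pathway
(p_perm ≈ 0.05) and re-estimating p_perm on 1,000 random drawings per
size gives a CV that falls below the conventional 10% criterion at
m = 2,000 (closed form: 0.0925). Very significant pathways converge far
sooner; pathways with p_perm near the 1/N floor need the pseudo-count
estimate for the CV to be defined at all. This is the basis of the
package default `n_perms = 2000` — together with α = 0.05 per SNP,
case–control permutations, and a 0.05 pathway threshold.

The combinatorial headroom differs enormously between strategies
(`count_case_control_permutations()`): a study with x cases and y
controls admits C(x+y, y) label permutations but up to z! SNP and
(number of genes)! gene permutations; since z ≫ x + y in any GWAS,
the row strategies can always supply more distinct shuffles, which is
what makes them usable fallbacks when raw genotypes are unavailable.

## Scale of the shipped analyses

The package's own test battery and examples run at deliberately reduced
scale, chosen so each check is statistically decisive yet quick on one
core: synthetic studies of 200–2,000 samples and 500–3,000 SNPs in
100–500 genes, 12–100 pathways, and permutation batteries of 2,000 runs
(20,000 for the row-II/hypergeometric convergence check, where the
Monte-Carlo standard error must be small compared to per-pathway
p-values). The parameter-recovery check uses 20 replicates at 200+200
samples, 2,000 SNPs and 2,000 permutations.

## Known limitations

* Gene-level evidence is binary (any-significant-SNP); no SNP-set
  statistics (min-p per gene, Fisher combination, kernel tests).
* Only set-based enrichment: pathway topology is ignored.
* Genomic control is the only stratification correction (no principal
  components or mixed models).
* The permutation-count analysis conditions on the realized run set;
  tail approximations (e.g. fitting a generalized Pareto distribution
  to the extreme permutation tail) that extrapolate below the 1/N
  floor are intentionally not implemented.
* QC is computed once, on the original labels; the column strategy does
  not re-stratify HWE inside each shuffle.
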