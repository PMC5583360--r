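---
title: "Gene-level population differentiation from rare and common variants"
author: "pdrc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level population differentiation from rare and common variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrc)
```

## The problem

The fixation index F\_st, the workhorse measure of population
differentiation (PD), is bounded by the minor-allele frequency of the
variant it is computed from: a variant carried by a handful of
chromosomes cannot produce a large F\_st no matter how unevenly its
copies are distributed across populations.  Sequencing cohorts are
dominated by exactly such variants.  In a multi-ethnic whole-exome
cohort, the vast majority of sites have MAF below a few percent, so
scanning for "any variant with F\_st above 0.25" only ever finds common
variation and says nothing about the rare variation that makes up most
of a gene.

`pdrc` addresses this by moving the unit of analysis from the variant to
the gene and by letting rare variants speak through weights.

## The gene statistic

For a gene with $q$ member variants in a cohort of $s$ populations,
variant $k$ contributes an $s \times 2$ contingency table of
minor/major allele counts $n_{ijk}$ ($i$ = population, $j$ = allele).
Under the null hypothesis of no differentiation, conditional on the
table margins, each table follows a multiple hypergeometric
distribution.  Writing $n_k$ for the free cells (the minor-allele counts
of the first $s-1$ populations), $\mu_k$ for their conditional
expectation and $V_k$ for their conditional covariance, the gene
statistic is the weighted generalized Cochran–Mantel–Haenszel quadratic
form

$$
L^2 \;=\; \Big[\textstyle\sum_k w_k (n_k - \mu_k)\Big]'
          \Big[\textstyle\sum_k w_k^2 V_k\Big]^{-1}
          \Big[\textstyle\sum_k w_k (n_k - \mu_k)\Big],
$$

which is asymptotically $\chi^2_{s-1}$ (df 4 for five populations).
The weight matrix is scalar, $B_k = w_k I$, and the weight appears in
both the numerator and the variance, so $L^2$ is invariant to rescaling
all weights by a constant.

Three weighting schemes are provided (`variantWeights()`): equal
($w_k = 1$), inverse MAF ($1/\mathrm{MAF}_k$) and inverse squared MAF
($1/\mathrm{MAF}_k^2$).  The MAF is always the *pooled* cohort MAF —
one weight per table, and the only definition that is well defined for
a cross-population statistic.  With equal weights the statistic is
dominated by common variants, whose per-table variances are orders of
magnitude larger; the maximum attainable contribution of a table grows
linearly with its MAF, which is the gene-level echo of the F\_st
ceiling.  Dividing by the MAF flattens that gradient (the unit test on
extremal fixed-margin tables asserts both facts), so rare variants
contribute on even terms, at the price of extra Monte-Carlo-visible
discreteness when minor counts are tiny.

### Numerical choices

* $M = \sum_k w_k^2 V_k$ is inverted through a symmetric
  eigendecomposition, never an explicit inverse.  Eigenvalues below
  $10^{-10} \lambda_{max}$ are treated as null directions; the statistic
  then uses the Moore–Penrose inverse and reports the rank as the
  effective degrees of freedom.  Rank deficiency arises naturally when a
  population has no successfully genotyped alleles at any selected
  variant.
* Variants with pooled MAF = 0 are refused by `gcmhComponents()` and
  removed by `selectVariants()` under every strategy: an inverse-MAF
  weight is undefined there and a constant column carries no signal.
* When the pooled frequency is exactly 0.5 the ALT allele is labelled
  minor (a deterministic tie-break, documented in `PDCohort`).
* Missing genotypes (including half-calls such as `0/.`) remove the
  sample from that variant's denominators; no imputation.  Sex
  chromosomes are excluded by default.
* A rejection at level $\alpha$ means $p \le \alpha$; with tiny counts
  $L^2 = 0$ (hence $p = 1$) has positive probability, and this
  convention keeps the $\alpha = 1$ edge case exact.

## Variant selection

Three strategies decide which variants enter the statistic: all
polymorphic variants; rare/less-common variants (pooled MAF
$\le$ 0.05 — "common" is defined as MAF > 0.05, and the boundary is
placed inclusively on the rare side, a choice that only affects variants
exactly at the threshold); and protein-altering variants, taken from the
annotation as given.  Selection is idempotent, order-preserving, and an
empty selection marks a gene untestable rather than erroring.

## Fixation index

Per-variant F\_st uses the Weir–Cockerham variance-component estimator
in its allele-count (haploid) form: the pipeline carries allele counts,
not genotypic heterozygosity, and the haploid form is the standard
choice in that situation.  It remains unbiased under unequal sample
sizes, and negative estimates are reported as-is.

Combining loci deserves care.  The arithmetic mean of per-locus ratios
$a_k/(a_k+b_k)$ is biased downward — severely so with two populations,
where the between-population component has a single degree of freedom —
whereas the ratio of summed components
$\sum_k a_k / \sum_k (a_k + b_k)$ (`multiLocusFst()`) recovers the
differentiation parameter of a Balding–Nichols model; the acceptance
suite demonstrates parameter recovery of $F = 0.1$ to within $\pm 0.02$
with 500 variants.  Gene-level reporting (`geneFstSummary()`) follows
the conventional rule: a gene is highly differentiated when at least one
variant exceeds F\_st 0.25.

## Mantel–Haenszel odds ratios

To say *which* population drives a gene's differentiation, each
population is contrasted against the baseline population (the last
label by default, European in the motivating cohort) through a weighted
Mantel–Haenszel odds ratio over the gene's variants,

$$
\hat\theta_{MH} = \frac{\sum_k w_k\, a_k d_k / T_k}
                       {\sum_k w_k\, b_k c_k / T_k}.
$$

The variance of $\log \hat\theta$ extends the
Robins–Breslow–Greenland estimator with one extra $w_k$ factor in each
numerator term, so each stratum carries its squared weight exactly once.
This is the unique placement that both reduces to the classical formula
at unit weights *and* keeps the confidence interval invariant to weight
rescaling; putting no extra factor in (applying the classical three-term
formula verbatim to weighted $R_k, S_k$) makes the variance scale as
$1/c$ under $w \mapsto c\,w$, which cannot be right for an estimate that
does not move.  Strata with both cross-products zero are skipped;
one-sided evidence yields 0 or $\infty$ with a flagged one-sided
interval.

## The cohort simulator

`simulateCohort()` generates diploid dosages for a cohort specified by
`cohortSpec()`.  Its defaults emulate the motivating five-ancestry
whole-exome cohort:

* **Population sizes** 2025/2164/1938/2199/4518 diploids (African
  American, East Asian, American Hispanic, South Asian, European
  baseline); tests use a small five-population preset of 500 diploids
  each where full scale is not needed.
* **Site-frequency spectrum.** The rare-heavy default draws the
  ancestral MAF from $0.03\,\mathrm{Beta}(0.5, 5)$ with probability
  0.975 and $\mathrm{Uniform}(0.03, 0.5)$ otherwise, so 97.5% of
  variants sit below 3% — the observed exome proportion the package
  calibrates to.  A common-heavy preset
  ($\mathrm{Uniform}(0.05, 0.5)$) exists to demonstrate that the test's
  calibration does not depend on the spectrum.
* **Differentiation.** Under `balding_nichols`, population $i$'s
  frequency is drawn from
  $\mathrm{Beta}\!\big(p(1-F)/F,\,(1-p)(1-F)/F\big)$ around the
  ancestral $p$: mean $p$, variance $F\,p(1-p)$.
* **Linkage disequilibrium.** `block` LD draws each haplotype from an
  equicorrelated Gaussian copula (latent correlation $\rho$ within
  consecutive blocks) thresholded at the population frequency, the
  genotype being the sum of two haplotypes.  Thresholding attenuates
  the realized allele-level correlation, increasingly so for rare
  variants — but note the limitation below.
* **Conditioning on polymorphism.** Variants monomorphic in the pooled
  sample are regenerated (whole blocks under block LD, to preserve the
  dependence structure), so every returned variant is usable.  All
  generation is bit-reproducible given the spec's seed, and the spec is
  stored in the cohort's metadata.

### What the simulator does not emulate

The copula gives every within-block pair the same latent correlation.
Real rare variants are recent mutations arising on single haplotype
backgrounds: their pairwise allelic correlation is close to zero even
inside strong LD blocks.  The copula's rare-rare pairs retain
substantial correlation at matching rare frequencies, i.e. the
simulator is *harder* on rare-variant statistics than real data.  Consequently the
LD/permutation study below is scoped to rare-only genes, and passing it
says that inverse-MAF weighting helps in that regime of the generator —
not that chi-square p-values are trustworthy under strong LD in
general (they are not; that is what `permutationNull()` is for).

## Calibration studies and the scales they use

These are the study conditions frozen into the acceptance suite; each
was chosen for scientific reasons stated here, not tuned.

* **Null distribution.** Genes of 10 independent rare-heavy variants,
  five populations of 500 diploids: over 10,000 replicates the
  empirical mean of $L^2$ matches df = 4 within Monte-Carlo error and
  the empirical distribution passes a KS comparison against
  $\chi^2_4$ at the 1% level.  The mean identity is exact in
  expectation — the summed covariance *is* the exact conditional
  covariance — so the estimated df recovered by the acceptance script
  is an honest measurement, not a restatement.
* **Type-I error.** Genes of 200 variants (exome genes in the
  motivating application carry hundreds of variants; their median
  rare-variant count is about 300) at the full five-population scale,
  5,000 replicates, both spectra, all three schemes, band
  [0.042, 0.058].  At much smaller gene sizes the inverse-MAF schemes
  run conservative: with a handful of ultra-rare variants the exact
  conditional distribution is visibly discrete, and no continuity
  correction is applied (none is part of the method).  At realistic
  gene sizes the rates are nominal, though the inverse-MAF-squared
  scheme stays mildly conservative under the rare-heavy spectrum, so
  single 5,000-replicate realizations tend to sit in the lower half of
  the band.
* **LD and permutation.** Null cohorts whose genes are single
  10-variant LD blocks ($\rho = 0.8$) of rare variants only — the
  rare-variant LD regime is the one the permutation analysis is about —
  in the small preset, 200 genes, 999 permutations.  Agreement between
  asymptotic and permutation inference is measured where it matters,
  at the 5% rejection rate; inverse-MAF weighting brings the asymptotic
  rate closer to the permutation rate than equal weighting does.  With
  mixed spectra the comparison can invert for an instructive reason: a
  lone common variant dominates the equal-weight statistic, making it
  effectively single-variant and hence immune to cross-variant LD.
* **Parameter recovery.** Balding–Nichols $F = 0.1$, two populations of
  1,000 diploids, 500 variants with common ancestral frequencies (so
  every locus is informative): `multiLocusFst()` within $\pm 0.02$.

## Decision rules in the scan

`pdrcScan()` evaluates every gene under every requested strategy and
scheme and applies two rules: Bonferroni (multiplying by the number of
genes actually tested under that strategy/scheme, overridable to an
external family size such as 48) and the empirical top-percentile rule
(flagging genes whose statistic exceeds the 95th percentile of all
testable genes' statistics, the percentile computed with linear
interpolation between order statistics — the type-7 convention, so the
95th percentile of 1..100 is 95.05).  Untestable genes appear in the
report with a status flag and are excluded from both the family size
and the percentile.

## Known limitations

* The chi-square reference assumes independent variants; under real LD
  use `permutationNull()`.
* The asymptotics degrade for genes of very few ultra-rare variants
  (conservative, not anti-conservative, in all measured regimes).
* r = 2 allele categories only (biallelic SNVs); multiallelic records
  are skipped at ingestion.
* The annotation's protein-altering flags are taken as given; no
  consequence prediction is attempted.
* Pairwise-population F\_st matrices and FDR procedures other than
  Bonferroni are out of scope.
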