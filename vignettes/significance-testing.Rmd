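---
title: "Significance testing for mixed-model GWAS in family-structured populations"
author: "mlmaSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significance testing for mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`mlmaSig` studies how significance should be declared in a single-SNP
mixed linear model association (MLMA) analysis of a livestock-type
population: a few thousand animals with strong sib structure, genotyped at
moderate-to-high SNP density, with a single quantitative phenotype that has
already been corrected for systematic environmental effects (so the only
fixed effect besides the tested SNP is the mean).

The association model for each SNP is

$$y = 1\mu + x b + u + e,\qquad
  u \sim N(0,\, K\sigma^2_g),\quad e \sim N(0,\, I\sigma^2_e),$$

where $x$ holds allele dosages coded 0/1/2 and $K$ is a relationship
matrix. Three choices of $K$ are first-class citizens, because comparing
them is the point of the exercise:

* the whole-genome Yang et al. kinship (`grmYang()`),
* its leave-one-chromosome-out variant (`grmLoco()`, `gwasLoco()`), where
  the tested SNP's chromosome is excluded so the SNP is not fitted twice,
* the pedigree additive relationship matrix (`pedigreeA()`, tabular
  method).

`Me = 1/Var(G_ij)`, the effective number of independent chromosome
segments, is deliberately computed from a *different* kinship — VanRaden
method 1 on all chromosomes (`grmVanRaden1()`) — so the two scalings are
separate code paths throughout.

## REML and the per-SNP test

`remlFit()` maximizes the restricted likelihood of the no-SNP null model
over the variance ratio $\sigma^2_g/\sigma^2_e$ after a single rotation
onto the eigenbasis of $K$. Each likelihood evaluation is then $O(n)$, so
one $O(n^3)$ eigendecomposition per kinship is the dominant cost; at the
package's design scale ($n \le 5{,}000$) this is seconds. The ratio is
searched on the log scale in $[10^{-8}, 10^{6}]$ with a convergence
tolerance of $10^{-8}$; $\sigma^2_g$ is projected to the zero boundary
when the profile is maximized there (`@boundary`). Mildly negative
eigenvalues of $K$ — an expected artifact of the Yang diagonal estimator at
modest SNP counts — are clipped to zero ("bending"); a matrix whose most
negative eigenvalue exceeds 10% of the largest is refused rather than
repaired.

`assocScan()` holds the variance components fixed at the null-model
estimates of the same kinship (the standard MLMA protocol; per-chromosome
re-estimation happens inside `gwasLoco()`), and computes per SNP the GLS
effect, its standard error and the 1-df Wald $\chi^2 = (b/se)^2$. The
standard error is rescaled by the per-SNP whitened residual variance
$\hat\phi = RSS_V/(n-p-1)$. This choice has two consequences we consider
features: with $K = I$ the scan reduces *exactly* to ordinary least
squares (which gives the package a sharp external oracle), and under a
permuted phenotype the statistics stay calibrated even when the fitted
$V$ is not the truth. p-values are never reported as exactly zero; they
are floored at the smallest positive double.

## Genomic control

`inflationFactor()` implements
$\lambda = \mathrm{median}(\chi^2_{obs}) / \mathrm{median}(\chi^2_1)$
genome-wide and per chromosome, computing the $\chi^2_1$ median constant
numerically from the CDF rather than hard-coding 0.455. Raw (possibly
deflated, $\lambda < 1$) values are reported; `applyGenomicControl()`
floors $\lambda$ at 1 when adjusting, so control can deflate but never
inflate significance, keeps the uncontrolled statistics alongside, and
refuses to run twice on the same table (a metadata flag, because dividing
by a second $\lambda$ is statistically meaningless but numerically
silent). FDR procedures are computed on raw p-values: genomic control and
FDR both rescale the null distribution, and combining them entangles the
two corrections; the pipeline therefore never chains them.

## Threshold procedures

* `bonferroniThreshold(alpha, nTests)` accepts a real-valued `nTests` so
  the same code serves the total-SNP count and `Me`.
* `meFromGrm()` uses the population (denominator-$n$) variance of the
  strictly off-diagonal entries by default, switchable to $n-1$; the two
  differ negligibly at realistic $n$ but the tests pin both down.
* `fdrBH()` / `fdrBY()` implement the step-up rule with a non-strict
  inequality $p_{(i)} \le i\alpha/m$ (and the harmonic-sum factor
  $c(m)=\sum 1/i$ for BY), treating the strict "<" sometimes printed in
  textbook recipes as a typographical variant — the difference matters only
  at exact ties, where we sort stably by (p, SNP id) so results are
  deterministic. An empty rejection set reports its threshold as `+Inf`
  on the $-\log_{10}$ scale.
* `permutationThreshold()` shuffles the phenotype over individuals,
  re-runs the full scan per replicate, and takes the nearest-rank 95th
  percentile of the recorded per-replicate maxima. Variance components are
  re-estimated per replicate by default, because shuffling changes the
  phenotype–kinship covariance (`refitReml = FALSE` freezes them for
  speed). Each replicate's genome-wide $\lambda$ is recorded alongside.

`clusterRegions()` forms QTL regions greedily: the most significant
remaining SNP becomes a peak and annexes every significant SNP within
0.5 Mb on its chromosome. Regions do not merge transitively — a
significant SNP 0.7 Mb from a peak founds its own region even if an
intermediate significant SNP chains them — and ties in significance are
broken toward the lower position, so the procedure is deterministic.
Region bounds are reported as the nominal peak ± 0.5 Mb span.

## The synthetic population

Since the motivating data (a commercial pig line) are proprietary, the
package carries a simulator whose **defaults are the study conditions**:

* Mating design: 20 sires × 15 dams × one litter of expected size 3.2
  (~960 genotyped offspring from 320 founders), giving on average ~2.2
  full sibs per animal — the published population average — and a GRM
  whose ten largest eigenvalues carry ~17% of the variance, the spectral
  footprint of strong family structure reported for the real data.
  `litterSize` may be fractional; litter sizes are drawn as
  `floor + Bernoulli(frac)`.
* Genome: 5 chromosomes × 400 SNPs over 100 Mb each. Founder haplotypes
  follow a first-order Markov chain per chromosome: stationary frequencies
  from Uniform(0.05, 0.5) and adjacent-site allelic correlation
  `ldRho = 0.7`, so $E[r^2]$ between sites $k$ apart decays geometrically
  as $\rho^{2k}$ — a closed form every LD test can be checked against. A
  coalescent simulator would be more realistic but not analytically
  checkable at this scale. When the target correlation is unattainable for
  a frequency pair (Fréchet bound), transition probabilities are clipped,
  capping the realized correlation; the exact-decay tests therefore pin
  frequencies at 0.5.
* Meiosis: gene dropping with crossovers from a Poisson process at
  1 cM/Mbp (Haldane, no interference), the standard livestock
  approximation. Individuals must have both parents known or neither —
  half-founders are rejected to keep the A-matrix recursion simple.
* Trait: three QTL with allele-substitution effects (−0.13, 0.34, −0.15) —
  the magnitudes reported for the motivating trait — plus a polygenic
  background with $h^2_{poly} = 0.3$ and a residual chosen so the total
  phenotypic variance is ~1. The motivating study does not report the
  trait's heritability or QTL variance fractions; 0.3 with a handful of
  sub-5% QTL is a defensible livestock default and is exposed in the
  design. The polygenic term is drawn either by pedigree gene flow
  (founders $N(0, \sigma^2_g)$, offspring mid-parent plus Mendelian
  sampling) or as a sum of many small SNP effects rescaled exactly to
  $\sigma^2_g$ (`polygenicMode = "snp"`); the SNP mode is used whenever a
  genomic-kinship model is meant to be able to capture the signal.
* Reproducibility: one master seed fans out to named substreams
  (haplotypes, pedigree, gene drop, phenotype, QTL choice, permutation),
  so stages can be regenerated independently and seeded runs are
  bit-identical.

What the simulator does *not* emulate: sequence-level mutation,
imputation error, multi-generation pedigrees, varying LD along a
chromosome, selection, or the X chromosome. Tests passing on this
population show that the *procedures* behave as the theory says under a
faithful dependence structure; they do not certify behaviour under, e.g.,
imputation artifacts.

## The designed experiments

The package's own acceptance experiments (in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) deserve a
note on their design, since each involves a choice:

* **Permutation calibration.** One chromosome of 2,000 LD-structured SNPs
  in ~960 pedigreed individuals with a purely polygenic trait; 200
  replicates. The mean per-replicate $\lambda$ comes out at ~0.95–0.97.
  The small deficit from 1 is real and instructive: per replicate, REML's
  non-negativity boundary trims exactly those replicates in which the
  shuffled phenotype happens to align with family axes (which would
  otherwise show $\lambda \gg 1$), while the median of strongly dependent
  $\chi^2$ values sits slightly below its independence expectation in
  typical replicates. At the full study's sample size both effects shrink;
  at desk scale they leave a visible but small bias.
* **Relationship contrast.** Ten simulated polygenic populations; in every
  one, the whole-genome kinship yields $\lambda \approx 1$ (replicate mean
  within [0.9, 1.1]) while LOCO and pedigree kinships inflate
  ($\lambda \approx 1.3$–1.6, each replicate strictly above its full-G
  value). The mechanism is the one the motivating study identified: with
  strong families, the tested chromosome's polygenic share is family-
  structured, and a kinship that excludes that chromosome (or knows only
  expected, not realized, relationships) cannot absorb it.
* **Fixed-QTL refit.** This experiment uses a trait dominated by three
  major QTL strong enough that their peaks at $n \approx 960$ are "highly
  significant" in the sense the refit protocol presumes ($-\log_{10} p$
  from ~5 up to ~36), with no diffuse polygenic term. The reason is identifiability: with the default diffuse trait,
  fitting three QTL as fixed covariates removes their peaks but leaves the
  genome-wide median — dominated by polygenic family inflation that LOCO
  cannot correct — unchanged or noisier. With a QTL-dominated trait the
  genome-wide $\lambda$ decreases strictly upon refitting, isolating the
  phenomenon the experiment is about.
* **Šidák oracle.** The permutation threshold is checked against
  $-\log_{10}(1 - 0.95^{1/m})$ for independent markers at $n = 500$: at
  much smaller $n$ the 1-df $\chi^2$ approximation of the permutation $t$
  tail is visibly conservative in the extreme tail and the comparison
  would measure that approximation rather than the procedure.

## Numerical and degenerate-input policy

* Monomorphic SNPs: excluded from GRMs (with a configurable MAF filter,
  default 0.01) and dropped from scans with a message; monomorphic pairs
  are skipped in LD decay.
* Missing dosages: mean-imputed per SNP before GRM construction and
  testing, keeping the centering exact.
* Allele frequencies are always estimated from the analyzed individuals.
* $K = I$ degeneracy: the variance split is unidentifiable; REML returns
  the boundary solution $\sigma^2_g = 0$, $\sigma^2_e = \mathrm{Var}(y)$.
* Ties: FDR sorts stably by (p, id); region peaks break significance ties
  toward the lower bp; the permutation percentile is nearest-rank
  (`ceil(q·n)`-th ordered maximum).
* Problem sizes used by the test suite (hundreds of individuals, a few
  thousand SNPs, 60–1,000 permutation replicates) were chosen so each
  experiment's Monte-Carlo error is comfortably inside its assertion band.

## Known limitations

* The eigendecomposition REML is dense: memory and time scale as $n^2$
  and $n^3$; populations beyond ~10⁴ individuals need the usual sparse or
  low-rank machinery this package intentionally omits.
* Permutation with the LOCO protocol re-rotates every chromosome's context
  per replicate; it is exact but the most expensive path.
* The per-SNP $\hat\phi$ rescaling of the standard error differs (by a
  factor converging to 1) from tools that keep $\sigma^2_e$ fixed across
  SNPs; comparisons at few decimal places should expect that.
* Region clustering is a literal ±0.5 Mb peak rule, not an LD-aware
  clumping; it is meant for counting association signals, not fine-mapping.
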