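---
title: "Methods: variance components, polygenic scores and genetic correlation in family cohorts"
author: "famvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance components, polygenic scores and genetic correlation in family cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The variance-component model

`famvar` decomposes the phenotypic variance of a trait measured on a
cohort of nuclear families as

$$ y = Xb + g + k + f + c + s + e $$

with independent random effects whose covariance structures are the
genomic relationship matrix $G$ (SNP-tagged additive genetic
variance), the pedigree numerator relationship matrix $K$ (expected
additive relationship, capturing genetic variance not tagged by the
array), and the three \{0,1\} block-indicator structures $F$ (nuclear
family), $C$ (couple) and $S$ (full siblings).  The model assumes
additivity, no gene-environment interaction or correlation, random
mating, and that shared environments act identically on every member
of the sharing set.  The couple, sibling and family supports are
nested by construction ($C, S \subseteq F$), which makes the full
five-component model weakly identified in small cohorts — the reason
the package pairs it with stepwise selection rather than reporting the
full model alone.

$G$ is the usual allele-frequency-standardised estimator
$A_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$ with
sample frequencies, per-SNP mean imputation and a per-pair denominator
counting only SNPs observed in both individuals.  $K$ is computed by
the tabular recursion, so inbred pedigrees get the correct
$1+F_{inb}$ diagonal even though the simulator never produces them.

## REML estimation

`remlFit()` maximises the restricted likelihood with one
expectation-maximisation step followed by average-information updates.
Each AI step is guarded twice: a step that leaves the positive-definite
region is halved (up to 30 times), and a step that decreases the
restricted likelihood is abandoned in favour of an EM step from the
previous point, which cannot decrease it.  Convergence is declared
when the log-likelihood changes by less than $10^{-6}$ between
iterations (at most 100).  The identity-only model bypasses iteration:
its REML solution is the ordinary-least-squares residual variance with
the $n-p$ denominator, and the suite checks this equivalence to
$10^{-8}$.

Components are constrained non-negative by default: a component
stepping below zero is pinned just above it ($10^{-8}$ of the
phenotypic variance).  If a pinned constrained fit fails to converge,
the model is automatically refit without constraints and flagged via
the `constrained` slot — the regime in which a pedigree component can
legitimately go negative.  Singular structures (the indicator
matrices, or a GRM with more individuals than SNPs) are handled by
bending: $10^{-6}$ of the phenotypic variance is added to the total
covariance diagonal only when its Cholesky factorisation fails.

Estimates are reported as fractions of the total phenotypic variance
(the sum of all components including the residual), with delta-method
standard errors from the inverse AI matrix.  Per-component hypothesis
tests are

* **Wald**: $(\hat\sigma^2_i/SE_i)^2$ against $\chi^2_1$, two-sided —
  the reporting convention of GREML software; the one-sided variant is
  not offered because the original convention is not documented;
* **likelihood ratio**: $2\Delta\ell$ against the 50:50 mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, the null distribution for a
  single variance component on the boundary.  A zero statistic
  therefore reports $p = 0.5$, the mixture's boundary mass.

**Backward stepwise selection** starts from the full G+K+F+C+S model.
At each round every component is tested by both tests (the LRT by
refitting without it); a component is removable if non-significant at
$\alpha = 0.05$ in *both*, and among removable components the one with
the largest Wald p is dropped.  The procedure stops when each
remaining component is significant in at least one test.  An empty
final model is legal.  The drop-one refits of one round seed the next
round, so the trace costs roughly one fit per (component, round) pair.

## Liability scale and power

For a 0/1 trait analysed by a linear model, estimates move from the
observed to the liability scale by the threshold-model multiplier
$c = K^2(1-K)^2/(P(1-P)z^2)$, where $K$ is the population prevalence,
$P$ the sample case fraction and $z$ the standard normal density at
the $K$-quantile; variances (heritabilities) are multiplied by $c$ and
regression coefficients by $\sqrt{c}$ (the first-order Taylor
conversion).  At $K=P=0.5$ the multiplier is exactly $\pi/2$, which
the suite uses as a closed-form anchor, alongside a quadrature oracle
at other prevalences.  The inverse transform divides by the same
multiplier, so round-trips are exact.

`gremlPower()` implements the non-centrality-parameter calculation:
$SE(\hat h^2)=\sqrt{2/(n^2\,\mathrm{var}_\pi)}$ with
$\mathrm{var}_\pi = 2\times10^{-5}$ for unrelated samples, NCP
$=(h^2/SE)^2$, and power as the non-central $\chi^2_1$ tail beyond the
$\alpha$ critical value.  For case-control designs the liability-scale
target is first moved to the observed scale.  The calculator exposes
the genotyped sample size separately from the case/control counts
because the two can differ (the case proportion is taken from the
phenotyped sample, the SE from the genotyped one); with 1506 cases,
7667 controls, 8734 genotyped and $K=0.162$ it returns 31.8% power for
$h^2_{liab}=0.12$ — the "roughly one in three" regime in which a
non-significant pedigree-genetic component is uninformative.

## Polygenic risk scores

Clumping is greedy by ascending discovery p-value: the most
significant unclaimed SNP indexes a clump and claims every unclaimed
SNP within ±250 kb (1-based, inclusive) whose genotypic $r^2$ in the
reference panel exceeds 0.1; ties in p break by (chromosome, position).
The suite checks the greedy result against an exhaustive oracle.
Scoring aligns alleles to the target coding (sign-flip when effect and
other allele are swapped; strand-ambiguous A/T and C/G SNPs are
dropped — the simulator only emits unambiguous pairs, so synthetic
tests are unaffected), mean-imputes missing dosages per SNP, and
accumulates $\sum_j \beta_j x_{ij}$ over the threshold grid
$p \le 0.01, 0.02, \dots, 1$ (endpoints inclusive; the grid is
cumulative, so the score at 1.0 uses every retained SNP).

Threshold selection measures, for each threshold, the incremental
variance explained by the standardised score over the covariate-only
mixed model with a pedigree random effect.  Incremental $r^2$ is
defined on the fixed-effect scale — the variance of the fitted fixed
part with the score minus without, over the phenotypic variance — and
variance components are estimated once on the covariate-only model and
held fixed across the 100 thresholds (refitting per threshold changes
third-decimal digits at the cost of two orders of magnitude more
computation).  The single reported association (`prsAssoc()`) does
refit the variance components with the score in the design, and tests
it by Wald's conditional F with $n-p$ denominator degrees of freedom.
On singleton-only pedigrees the machinery reduces exactly to ordinary
least squares, which the suite asserts to $10^{-8}$.

## GWAS and LD score regression

`mlmaLoco()` performs mixed-model association with a
leave-one-chromosome-out GRM: for each chromosome the variance
components are re-estimated with the GRM built from all other
chromosomes (proximal contamination is thereby excluded from the
random effect), and each SNP on the chromosome is tested as a fixed
effect given those components.  The per-chromosome model is solved in
the eigenbasis of the LOCO GRM, where the covariance is diagonal and
the REML profile over the heritability ratio is a one-dimensional
optimisation; the per-SNP statistics are then exact GLS quantities
(the suite verifies them against a direct dense-matrix fit).

LD scores are $\ell_j = 1 + \sum_k r^2_{jk,adj}$ over a ±1 Mb window
with the small-sample adjustment $r^2 - (1-r^2)/(n-2)$.  Heritability
regression uses $E[\chi^2_j] = 1 + N h^2 \ell_j/m$ with a free
intercept, canonical $1/\ell_j$ LD weights times the heteroskedasticity
weight $1/(2(1+Nh^2\ell_j/m)^2)$ updated in two steps, and a
delete-one-block jackknife over contiguous SNP blocks (200 by default,
reduced so blocks hold at least 10 SNPs, never fewer than 20 blocks).
The cross-trait regression of $z_{1j}z_{2j}$ on
$\sqrt{N_1N_2}\,\ell_j/m$ yields the genetic covariance;
$r_G = \mathrm{gencov}/\sqrt{h^2_1 h^2_2}$ is clamped to
$[-1.25, 1.25]$ with a warning outside $[-1,1]$, and its standard
error jackknifes the full ratio.  The cross-trait intercept absorbs
sample overlap and is reported; the expected-overlap term defaults to
zero, matching designs where discovery and target cohorts are
disjoint.  Both regressions refuse to run below 200 overlapping SNPs
or with a constant regressor, where the slope is unidentifiable.
`zDiff()` reports both one- and two-sided p-values for the comparison
of two correlations, since both conventions appear in applied
reporting; neither is privileged.

## The simulator: what it emulates and what it does not

`simulatePedigree()` generates founder couples with sibship sizes
drawn from a configurable distribution, plus unrelated singletons.
Couples are always founders — no remarriage, no half-siblings — which
keeps the C, S and F structures unambiguous.  The sibship-size
distribution is configuration, not a fixed constant, because real
cohorts differ; the suite demonstrates a distribution (40% two-child,
35% three-child, 25% four-child) under which 659 couples yield the
order of 1900 full-sib pairs.

`simulateGenotypes()` draws founder haplotypes at Hardy-Weinberg
equilibrium with uniform allele frequencies in a configurable range
and optional within-block linkage disequilibrium via an exchangeable
Gaussian copula among founder haplotypes; children receive one
parental allele per SNP, transmitted block-wise so within-block LD
survives transmission.  This emulates enough LD to exercise clumping
and LD scores without a coalescent simulator; it does **not** emulate
realistic LD decay with distance, allele-frequency spectra,
recombination maps, imputation dosages or the X chromosome.

`simulatePhenotypes()` composes the trait from standardised causal-SNP
effects (drawn i.i.d. normal, matching the infinitesimal assumption
GREML relies on), a pedigree-genetic draw with covariance
$\propto K$, one draw per family / couple / sibship, and noise.  Each
realised component is rescaled so its sample variance equals the
requested fraction exactly: the generating values are then conditions
of the experiment rather than expectations, which removes generative
noise from recovery studies while leaving estimation noise intact.
Binary traits threshold this liability at the $1-K$ quantile, making
the liability conversion exactly testable.  Assortative mating is
deliberately not simulated; with it, modelling the couple correlation
as purely environmental would inflate heritability, and the package
would have no way to tell.

Consequently, passing tests demonstrate correctness of the estimators
under the model's own assumptions — they do not certify behaviour
under model violations (assortative mating, G×E, non-Gaussian
liabilities, ascertainment) that real cohorts may exhibit.

## Numerical choices and problem sizes

* REML: tolerance $10^{-6}$, max 100 iterations, EM first step,
  AI with likelihood-guarded halving; pinning at $10^{-8}$ of the
  phenotypic variance; bending ridge $10^{-6}$ of it.
* Clumping ties: (chromosome, position) order; windows inclusive.
* Jackknife: 200 blocks, floored at 20, blocks of at least 10 SNPs.
* The recovery study behind the two-component (SNP + couple) result
  runs 20 replicates of 1000 four-person families (4000 individuals)
  with 10,000 SNPs and 1000 causal variants — sizes chosen so the
  study resolves 0.08/0.13 fractions with Monte-Carlo standard errors
  near 0.005 while a full run stays in the minutes range on a single
  core.  The estimator is unbiased in $n$, so these sizes trade only
  precision, not location.
* The stepwise-selection consistency studies use cohorts of roughly
  900–1000 individuals with 2000 SNPs and stronger generating
  fractions (0.25–0.40) than the headline analysis: exact-set
  recovery is a power-limited property, and these designs make it
  identifiable while staying small.

## Known limitations

* **GRM noise at small SNP counts.**  With a few hundred SNPs the
  sampling noise of GRM entries ($\mathrm{var} \approx 1/m$) rivals
  the relatedness signal, attenuating the fitted genetic variance, so
  a mixed model cannot fully absorb family covariance and association
  scans on such panels inflate.  The calibration test therefore places
  the polygenic background on the chromosomes inside the LOCO GRM and
  measures inflation on the truly null chromosome — the quantity the
  leave-one-chromosome-out design controls.  Real arrays (hundreds of
  thousands of SNPs) are far from this regime.
* **LD score regression needs discovery-scale inputs.**  The $h^2$
  slope is unidentifiable from a GWAS of a few hundred individuals;
  the pipeline's genetic-correlation stage therefore pairs
  discovery-scale summary statistics drawn from the polygenic
  expectation with the panel's LD scores, while the cohort GWAS
  contributes the inflation diagnostics.  This mirrors the applied
  design of pairing a family cohort with large external consortium
  statistics.
* The full five-component model can be near-singular; Table-style
  reporting should always accompany the stepwise-selected model.
* Half-siblings, X-linked variation, dominance and epistatic
  relationship matrices, bivariate REML and Bayesian/continuous-
  shrinkage scores are out of scope.
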