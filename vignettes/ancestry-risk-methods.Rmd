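---
title: "Methods: ancestry-risk analysis in admixed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-risk analysis in admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`admixrisk` estimates how continental genetic ancestry relates to disease
risk in a two-way admixed case-control cohort, with primary open-angle
glaucoma (POAG) in African Americans as the motivating application. This
vignette is the package's account of its models, the choices behind its
defaults, and what its validation does and does not establish.

## The two-way admixture model

Genotypes are additively coded counts of one designated allele. For
sample $i$ with admixture proportion $q_i$ (fraction of the genome from
population 1) and variant $l$ with ancestral allele frequencies
$f_{1l}, f_{2l}$, the model treats the two allele copies as independent
draws from the mixed frequency
$\theta_{il} = q_i f_{1l} + (1-q_i) f_{2l}$, giving the binomial
log-likelihood
$$\ell = \sum_{i,l}\; g_{il}\log\theta_{il} + (2-g_{il})\log(1-\theta_{il}).$$
`fit_admixture_k2()` maximizes $\ell$ jointly over $q$ and $f$ by EM:
each allele copy is probabilistically attributed to a population
(E-step), then $q$ and $f$ have closed-form refreshes (M-step). Missing
calls contribute nothing. The assumptions worth stating: two ancestral
populations, Hardy–Weinberg within each, independent variants given
ancestry (hence LD pruning first), and no inbreeding.

Plain EM is reliable but slow in its tail, so the iteration is wrapped in
a squared-extrapolation (SQUAREM-type) accelerator with an adaptive
steplength bound and a monotonicity safeguard: an extrapolated point is
accepted only if its likelihood is at least that of the plain double EM
step, so the per-cycle likelihood trace is non-decreasing — a property the
test suite asserts. Convergence is declared when the absolute likelihood
gain per cycle falls below `tol` (default 1e-6). Because the likelihood
surface for k = 2 occasionally has shallow local optima under random
starts, the fitter runs `restarts` (default 5) random initializations for
a short burn-in (25 iterations) and continues only the best — the standard
multi-start practice. With a fixed seed the whole fit is bit-reproducible.
Ancestral frequencies are clamped to [1e-6, 1-1e-6] to keep the
log-likelihood finite. The heavy inner step is compiled (Rcpp); a pure-R
reference implementation of the identical update is kept in the package
and the two are cross-checked to machine precision in the tests.

## Orientation and the sign conventions

The two EM components are exchangeable, and PC signs are arbitrary, so
both need a convention. The package fixes them as the tabulated analyses
of this literature do: each principal component of the genetic
relationship matrix is oriented so that AFR-labeled reference samples sit
at *negative* values (so cases, who carry more African ancestry, have
lower PC1 than controls), and `orient_q0()` swaps the admixture
components if needed so that corr(q0, PC1) > 0. The result: **low q0 =
high African ancestry**, quartile 1 of q0 is the most-African reference
group, and q0 behaves like a European-ancestry proportion. The source
literature is not internally consistent about this direction (a figure
caption implies the opposite of the tables); the package follows the
tables and documents the choice here rather than silently re-deriving it.
One consequence: the correlation between PC1 and genome-average African
ancestry is strongly *negative* under this convention; where an agreement
strength is reported, the magnitude is the meaningful quantity.

## Local ancestry and admixture mapping

`local_ancestry_posteriors()` runs, per chromosome, a diploid HMM that is
the product of two independent haploid chains with states {AFR, EUR}:
stationary probabilities $(q_i, 1-q_i)$, and between adjacent markers at
genetic distance $d$ morgans the chain keeps its state with probability
$e^{-\lambda d}$ (admixture age $\lambda$ in generations, default 8) and
otherwise redraws from the stationary distribution. Unphased genotype
emissions are the convolution of two Bernoulli draws at the marker's
AFR/EUR panel frequencies; missing genotypes emit likelihood 1.
Forward–backward posteriors over {0, 1, 2} African copies are collapsed
to an expected dose $d_{il} \in [0,2]$. The scan then fits, per marker, a
logistic model of case status on $d_{il}$ adjusted for age, sex and
global African ancestry, with a Bonferroni threshold of $0.05/M$. The
global-ancestry covariate is an explicit design addition: without it,
every marker simply re-detects the genome-wide ancestry effect, which is
exactly what admixture mapping must look beyond (a switch disables it).
Markers with separation are reported at p = 1 and flagged rather than
dropped, so the multiplicity correction stays honest. This
forward–backward + covariate-adjusted scan is a deterministic frequentist
analogue of the Bayesian MCMC machinery used historically for this
analysis, not a re-implementation of it.

The original analysis did not scan the replication cohort after a null
discovery scan; the pipeline mirrors that by treating the scan per run.

## Quality control

Filters run in a fixed order — sample missingness (≥ 3%, boundary
inclusive), heterozygosity (outside mean ± 3 SD, band computed once on
the pre-removal cohort; a zero-SD band removes nobody), relatedness, then
variant filters (missingness > 3%, Fisher-exact differential call rate at
α = 1e-5, exact Hardy–Weinberg test at p < 1e-5, MAF < 0.01). The
sample boundary is inclusive ("at least 3%") while the variant boundary
is strict ("more than 3%"); the asymmetry is preserved deliberately. The
differential call-rate α is a convention (the source states only
"statistically significant"); Fisher's exact test is used so small counts
behave. The HWE test is the conditional exact test given the minor-allele
count, computed in closed form over all heterozygote configurations; the
suite verifies it against an independent enumeration oracle for every
configuration with n ≤ 50.

Relatedness uses the classical method-of-moments IBD estimator (observed
IBS 0/1/2 counts against their expectations given cohort allele
frequencies; PI_HAT = P(IBD=2) + P(IBD=1)/2) and greedily removes, among
flagged pairs (PI_HAT ≥ 0.1875), the member with the higher missingness
(ties to the lexicographically larger id). Two honest caveats. First, the
estimator assumes a homogeneous population; in an admixed cohort, pairs of
similar extreme ancestry show positively biased PI_HAT (up to ~0.15 here).
With enough variants this bias stays below the 0.1875 threshold, which is
why the pairwise scan defaults to using up to 10,000 variants; thinning
far below that re-introduces false flags through sampling noise. Second,
which member of a related pair the original study removed is unstated;
the higher-missingness rule is this package's convention.

## The synthetic cohort: what it emulates and what it does not

The generator (`simulate_cohort()`) encodes the statistical structure the
analysis assumes, with defaults fixed once:

* **Differentiation**: Balding–Nichols draws around a shared ancestral
  frequency, FST = 0.15 — typical of African/European differentiation.
  AIMs are re-drawn until the frequency differential is ≥ 0.4.
* **Admixture proportions**: Beta(6, 1.6), mean African ancestry ≈ 0.79
  with heavy dispersion, matching the reported ~20% average European
  ancestry of African Americans and the wide individual variation.
* **Admixture age**: λ = 8 generations. The literature brackets African
  American admixture within the past ~20 generations, with 6–10 the
  commonly used range; 8 is the midpoint and is configurable.
* **Genetic map**: AIMs uniformly spaced on 22 autosomes of 1.5 morgans
  each (1 cM = 0.01 M = 1 Mb for synthetic coordinates).
* **Risk model**: case status is logistic in age/10 (OR 2.03), male sex
  (OR 1.57), standardized q0 (OR 0.90/SD) and the weighted risk score
  (OR 1.08/point) — the published discovery-cohort estimates — with the
  intercept solved numerically so mean prevalence equals 0.4656
  (1783/3830). Demographics: age ~ N(65, 12.3) truncated at 35 (study
  eligibility), 35% male.
* **Endophenotypes**: linear in standardized q0 with Gaussian noise at
  field-typical baselines (CCT 535 µm, σ = 30, coefficient 3.93 µm/SD of
  q0 by default; IOP/CDR/RNFL use the corresponding published
  coefficients as fixed defaults), plus missingness rates chosen so the
  analyzable case counts resemble the published tables.
* **Risk-score variants**: the packaged 23-SNP table's AFR/EUR
  risk-allele frequencies drive genotype generation, so the score's
  ancestry gradient is built in.

What it does **not** emulate: background linkage disequilibrium beyond
ancestry-induced correlation, genotype-intensity error models, sex
chromosomes, family structure beyond the planted duplicates, and any
social or environmental covariate. Passing parameter-recovery tests on
this cohort therefore shows the estimators are correct *under the model's
own assumptions* — it cannot show robustness to LD, batch effects, or
confounding in real data.

The generator gives no interpretation of the original study's raw data;
all distributional choices are stand-ins flagged as configuration.

## Numerical and design notes

* Positions are 1-based; merge identity is (chrom, pos) with allele sets
  matched after strand-ambiguous ({A,T}, {C,G}) removal; mismatched
  allele sets are dropped with a logged count.
* Additive coding counts `allele_b` (ALT in VCF, file-minor in PED);
  orientation is re-harmonized at merge and at risk scoring, so the
  internal choice is arbitrary but recorded per variant.
* Missing calls are `NA` and every consumer branches on them explicitly.
* The risk score weights are the published odds ratios themselves, not
  their logarithms — implemented exactly as described at the source; a
  `log_weights` switch exists but is off by default, and scores are
  therefore on an arbitrary "risk point" scale. Missing risk-SNP calls
  are mean-imputed at twice the cohort risk-allele frequency (a package
  convention; a skip mode exists).
* LD pruning window/step default to 50/5 variants — long-standing
  practical defaults, configurable.
* Logistic and linear fits go through `stats::glm`/`stats::lm` (IRLS /
  OLS) with Wald intervals; the tests pin them to closed-form 2×2 odds
  ratios and normal-equations solutions. Rank-deficient designs error
  naming the collinear terms; separation flags the fit and suppresses the
  CI.
* Suspects (neither case nor control) are excluded from all case-control
  models.

## Validation scales

The test suite and the acceptance script exercise the full chain at the
sizes the package's own validation conditions state: the
ancestry-agreement checks on one n = 2000 cohort with 5000 genome SNPs
and 2000 AIMs (the PCA and the admixture fit both use the LD-pruned
variant set) against a 200-sample AFR/EUR panel; model-recovery checks average 20–40
replicates of n = 3806 cohorts that carry only the covariate and
risk-score machinery the fitted model uses (the genome-SNP count is
reduced there because genome SNPs enter the risk model only through the
ancestry proportion, for which the generator's ground truth is used
directly — the targets measure effect-size recovery, not admixture
estimation error, which the dedicated ancestry checks cover). Oracle
suites (exact-test enumeration, closed-form odds ratios, brute-force GRM,
grid-search likelihood bounds, Mendelian IBD simulations) run at small n.

## Known limitations

* The admixture model is strictly two-way; cohorts with three or more
  ancestral components need different machinery.
* The IBD moment estimator's structural bias in admixed cohorts (above)
  makes very aggressive variant thinning inadvisable.
* Local-ancestry inference uses unphased genotypes and independent-marker
  emissions; with dense AIM panels in high-LD regions the posteriors
  would be overconfident.
* The risk-score construction (OR-weighted allele counts, no LD
  clumping or shrinkage) reproduces the published construction; it is not
  a state-of-the-art PRS.
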