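# admixrisk

Quantifying genetic ancestry as a risk factor for primary open-angle
glaucoma (POAG) in admixed African American cohorts — and, more generally,
an end-to-end, tested R implementation of the two-way ancestry-risk
analysis used in large admixed case-control studies.

POAG is the leading cause of irreversible blindness in people of African
descent, who carry a four- to five-fold higher risk than European
Americans. Within an African American cohort, individuals vary widely in
their proportion of African ancestry, and that proportion itself may carry
risk information beyond known susceptibility variants. `admixrisk`
implements the full analysis chain needed to ask that question:

1. **Genotype I/O and QC** — VCF / PLINK-text readers with additive
   coding; sample filters (missingness ≥ 3%, heterozygosity outside
   ±3 SD, PLINK-style method-of-moments identity-by-descent pruning at
   PI_HAT ≥ 0.1875) followed by variant filters (missingness > 3%,
   Fisher-exact differential call rate, exact Hardy–Weinberg test at
   p < 1e-5, MAF < 0.01), with an auditable removal report.
2. **Global ancestry** — LD pruning (r² ≤ 0.2), merge with a labeled
   AFR/EUR reference panel after strand-ambiguity removal, PCA of the
   genetic relationship matrix, and unsupervised two-way admixture
   estimation by maximum-likelihood EM: for sample *i* and variant *l*,
   the genotype is Binomial(2, θ_il) with θ_il = q_i f_1l + (1−q_i) f_2l.
   The two components (q0, q1), q0 + q1 = 1, are oriented against PC1 so
   that **low q0 = high African ancestry**, and q0 is cut into quartiles.
3. **Admixture mapping** — local African ancestry at ancestry-informative
   markers (AIMs) via a diploid hidden Markov model (haploid chains with
   stationary probabilities (q_afr, 1−q_afr) and stay probability
   e^(−λd) between markers at genetic distance d), then a per-AIM
   logistic scan for case-control ancestry skew, adjusted for age, sex
   and global ancestry, with Bonferroni control (0.05 / 2539 ≈ 1.96e-5
   for the published AIM panel).
4. **Polygenic risk score** — the packaged 23-variant POAG risk table
   (rsID, risk allele, published OR, AFR/EUR risk-allele frequencies);
   score = Σ (risk-allele count × published OR).
5. **Risk models** — standardized logistic models (OR per 1 SD of q0 or
   PC1), quartile models, linear endophenotype models among cases (IOP,
   CCT, cup-to-disc ratio, RNFL), and the joint multivariable model
   (age/10 y, male sex, PRS per point, q0 per SD).

Because the source cohort's genotypes are not public, the package ships a
first-class **synthetic cohort generator** (`simulate_cohort()`) that
encodes the statistical structure the analysis assumes — Balding–Nichols
ancestral differentiation (FST 0.15), Beta(6, 1.6) admixture proportions
(mean African ancestry ≈ 0.79), ancestry tracts from a λ = 8 generation
Markov model, and case status / endophenotypes generated from the
published effect sizes (age OR 2.03/10 y, male OR 1.57, q0 OR 0.90/SD,
PRS OR 1.08/point, CCT 3.93 µm/SD) — with exact ground truth for
parameter-recovery testing, plus planted QC contaminants.

## Worked example

```r
library(admixrisk)

cfg <- sim_config(n_samples = 500, n_snps = 2000, n_aims = 400,
                  n_chrom = 6, panel_afr = 80, panel_eur = 80, seed = 42)
cohort <- simulate_cohort(cfg)
panel  <- simulate_reference_panel(cfg)

qc <- run_qc(cohort$genotypes, cohort$records)
keep <- ld_prune(qc$genotypes)
pruned <- gm_subset(qc$genotypes, variants = match(keep, qc$genotypes$variants$variant_id))
merged <- merge_with_panel(pruned, panel, exclude_populations = "ASW")
afr <- merged$labels$sample_id[which(merged$labels$superpopulation == "AFR")]
pca <- grm_pca(grm(merged$genotypes), k = 10, afr_ids = afr)
fit <- orient_q0(fit_admixture_k2(pruned, seed = 777), pca$coords[, "PC1"])

cor(fit$estimates$q0, pca$coords[fit$estimates$sample_id, "PC1"])
#> [1] 0.9984
cor(1 - fit$estimates$q0, cohort$truth$q_afr_true[fit$estimates$sample_id])
#> [1] 0.9783

scores <- score_samples(qc$genotypes)
multivariable_model(fit$estimates, qc$records, scores)
#>            term estimate odds_ratio ci_low ci_high  p_value n_used flagged
#> 1   age_per_10y   0.6463       1.91  1.595    2.28 1.75e-12    492   FALSE
#> 2     q0_per_sd   0.0579       1.06  0.870    1.29 5.64e-01    492   FALSE
#> 3 prs_per_point   0.1255       1.13  1.070    1.20 1.97e-05    492   FALSE
#> 4          male   0.3913       1.48  0.977    2.24 6.45e-02    492   FALSE
```

The q0/PC1 correlation (0.998 here) says the panel-free admixture
estimate and the panel-anchored principal component measure the same
ancestry axis. The multivariable table reads as adjusted odds ratios:
age and the risk score are clear risk factors at this small n, while the
q0-per-SD CI (0.87–1.29) still covers its weak generating value of 0.90 —
an OR below 1 per SD of q0 means higher European ancestry is protective,
i.e. higher African ancestry carries higher POAG risk after adjusting for
age, sex and the known-variant score. The generating values
(2.03, 0.90, 1.08, 1.57) are recovered tightly at study scale (see the
acceptance script).

A single call runs the whole chain and writes every stage artifact plus a
reproducibility manifest:

```r
run_pipeline(default_config(seed = 1), out_dir = "run1")
```

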