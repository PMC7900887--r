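# shared fixture builders and independent oracles

# hand-built genotype matrix; calls given row-wise per sample
tiny_gm <- function(calls, chrom = NULL, pos = NULL,
                    allele_a = NULL, allele_b = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  nv <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", nv)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(allele_a)) allele_a <- rep("A", nv)
  if (is.null(allele_b)) allele_b <- rep("G", nv)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(nrow(calls)))
  genotype_matrix(calls,
                  data.frame(variant_id = sprintf("v%03d", seq_len(nv)),
                             chrom = chrom, pos = pos,
                             allele_a = allele_a, allele_b = allele_b,
                             stringsAsFactors = FALSE),
                  ids)
}

# minimal sample records for a genotype matrix
tiny_records <- function(ids, status = NULL, age = NULL, sex = NULL) {
  n <- length(ids)
  if (is.null(status)) status <- rep(c("case", "control"), length.out = n)
  if (is.null(age)) age <- rep(60, n)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  sample_records(data.frame(sample_id = ids, status = status, age = age,
                            sex = sex, cohort = "discovery",
                            stringsAsFactors = FALSE))
}

# independent HWE oracle: conditional distribution of the het count
# obtained numerically from the multinomial HWE law via dmultinom,
# conditioning on the minor-allele count by brute-force enumeration
hwe_oracle_dist <- function(n, r) {
  h <- seq.int(r %% 2, min(r, 2 * n - r), by = 2)
  p <- 0.3  # conditional law is free of p
  probs <- vapply(h, function(hh) {
    n_min_hom <- (r - hh) / 2
    n_maj_hom <- n - hh - n_min_hom
    stats::dmultinom(c(n_min_hom, hh, n_maj_hom),
                     prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
  }, numeric(1))
  list(h = h, prob = probs / sum(probs))
}

hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  r <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (r == 0) return(1)
  d <- hwe_oracle_dist(n, r)
  obs <- d$prob[d$h == n_ab]
  min(1, sum(d$prob[d$prob <= obs * (1 + 1e-12)]))
}

# memoised heavy fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# medium cohort for module-level parameter-recovery checks
medium_cohort <- function() memo("medium_cohort", function() {
  cfg <- sim_config(n_samples = 400, n_snps = 1200, n_aims = 500, n_chrom = 6,
                    panel_afr = 60, panel_eur = 60, seed = 2024)
  co <- simulate_cohort(cfg)
  pan <- simulate_reference_panel(cfg)
  list(cfg = cfg, co = co, pan = pan)
})

# study-scale run shared by the ancestry-agreement acceptance checks:
# n = 2000 cohort, 5000 genome SNPs (LD pruned), 2000 AIMs, FST 0.15,
# Beta(6, 1.6) ancestry, AFR/EUR panel
study_run <- function() memo("study_run", function() {
  cfg <- sim_config(seed = 777)
  co <- simulate_cohort(cfg)
  pan <- simulate_reference_panel(cfg)
  keep <- ld_prune(co$genotypes)
  mp <- gm_subset(co$genotypes, variants = match(keep, co$genotypes$variants$variant_id))
  mg <- merge_with_panel(mp, pan)
  afr <- mg$labels$sample_id[!is.na(mg$labels$superpopulation) &
                               mg$labels$superpopulation == "AFR"]
  pca <- grm_pca(grm(mg$genotypes), k = 10, afr_ids = afr)
  fit <- fit_admixture_k2(mp, seed = 777)   # cohort-only, LD-pruned variants
  fit <- orient_q0(fit, pca$coords[, "PC1"])
  m_aims <- gm_subset(co$genotypes,
                      variants = match(co$aim_panel$variant_id,
                                       co$genotypes$variants$variant_id))
  q_afr <- stats::setNames(1 - fit$estimates$q0, fit$estimates$sample_id)
  post <- local_ancestry_posteriors(m_aims, co$aim_panel, q_afr,
                                    lambda = cfg$generations)
  pc1 <- pca$coords[fit$estimates$sample_id, "PC1"]
  list(cfg = cfg, co = co, fit = fit, pca = pca, pc1 = pc1, post = post)
})

# model-recovery replicate: cohort at the discovery scale with only the
# machinery the risk model needs (small genome), fitted with truth q0
fit_discovery_replicate <- function(seed, n = 3806) {
  cfg <- sim_config(n_samples = n, n_snps = 50, n_aims = 10, n_chrom = 2,
                    seed = seed)
  co <- simulate_cohort(cfg)
  est <- data.frame(sample_id = co$records$sample_id,
                    q0 = 1 - co$truth$q_afr_true,
                    stringsAsFactors = FALSE)
  scores <- score_samples(co$genotypes)
  multivariable_model(est, co$records, scores)
}
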