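#' Simulation configuration for a two-way admixed cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults encode
#' the study conditions the rest of the package is validated against: an
#' African American-like cohort with mean African ancestry ~0.79 and heavy
#' dispersion (Beta(6, 1.6)), AFR/EUR differentiation FST = 0.15
#' (Balding-Nichols), admixture age 8 generations, and case status driven
#' by age (OR 2.03 per 10 y), male sex (OR 1.57), standardized European
#' ancestry q0 (OR 0.90 per SD) and the weighted polygenic risk score
#' (OR 1.08 per point), at baseline case prevalence 0.4656.
#'
#' @param n_samples,n_snps,n_aims cohort size, genome SNP count, count of
#'   ancestry informative markers.
#' @param fst Balding-Nichols differentiation of the two ancestral
#'   populations, in (0,1).
#' @param admix_alpha,admix_beta Beta shape parameters of the per-sample
#'   African ancestry proportion.
#' @param generations admixture age lambda, in generations; governs
#'   ancestry tract length along chromosomes.
#' @param n_chrom,chrom_length number of autosomes simulated and genetic
#'   length of each, in morgans.
#' @param effect_age_per_10y,effect_male,effect_q0_per_sd,effect_prs_per_point
#'   generating odds ratios of the case-status model.
#' @param cct_coef_per_sd generating central-corneal-thickness coefficient,
#'   microns per SD of q0.
#' @param baseline_prevalence target mean case probability; the model
#'   intercept is solved to hit it.
#' @param aim_min_diff minimum AFR/EUR allele-frequency differential
#'   enforced on AIMs by rejection.
#' @param male_frac,age_mean,age_sd demographics (age truncated at 35).
#' @param panel_afr,panel_eur,panel_asw reference-panel sizes (unadmixed
#'   AFR/EUR plus optionally an admixed "ASW"-like population).
#' @param panel_decoys named integer vector of decoy superpopulation sizes
#'   (names among EAS/AMR/SAS); drawn at their own differentiation
#'   `decoy_fst` from the shared ancestral frequencies.
#' @param decoy_fst differentiation of decoy populations.
#' @param seed integer seed; a fixed seed makes the generator
#'   byte-reproducible.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, n_snps = 5000, n_aims = 2000,
                       fst = 0.15, admix_alpha = 6, admix_beta = 1.6,
                       generations = 8, n_chrom = 22, chrom_length = 1.5,
                       effect_age_per_10y = 2.03, effect_male = 1.57,
                       effect_q0_per_sd = 0.90, effect_prs_per_point = 1.08,
                       cct_coef_per_sd = 3.93,
                       baseline_prevalence = 0.4656,
                       aim_min_diff = 0.4,
                       male_frac = 0.35, age_mean = 65, age_sd = 12.3,
                       panel_afr = 100, panel_eur = 100,
                       panel_asw = 0, panel_decoys = c(EAS = 0, AMR = 0, SAS = 0),
                       decoy_fst = 0.1, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_aims = as.integer(n_aims), fst = fst,
              admix_alpha = admix_alpha, admix_beta = admix_beta,
              generations = generations, n_chrom = as.integer(n_chrom),
              chrom_length = chrom_length,
              effect_age_per_10y = effect_age_per_10y,
              effect_male = effect_male, effect_q0_per_sd = effect_q0_per_sd,
              effect_prs_per_point = effect_prs_per_point,
              cct_coef_per_sd = cct_coef_per_sd,
              baseline_prevalence = baseline_prevalence,
              aim_min_diff = aim_min_diff, male_frac = male_frac,
              age_mean = age_mean, age_sd = age_sd,
              panel_afr = as.integer(panel_afr), panel_eur = as.integer(panel_eur),
              panel_asw = as.integer(panel_asw),
              panel_decoys = panel_decoys, decoy_fst = decoy_fst,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1, cfg$n_snps >= 1, cfg$n_aims >= 2,
            cfg$fst > 0, cfg$fst < 1,
            cfg$admix_alpha > 0, cfg$admix_beta > 0, cfg$generations > 0,
            cfg$n_chrom >= 1, cfg$chrom_length > 0,
            cfg$effect_age_per_10y > 0, cfg$effect_male > 0,
            cfg$effect_q0_per_sd > 0, cfg$effect_prs_per_point > 0,
            cfg$baseline_prevalence > 0, cfg$baseline_prevalence < 1,
            cfg$aim_min_diff >= 0, cfg$aim_min_diff < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw ancestral allele frequencies under the Balding-Nichols model
#'
#' Each SNP gets a common ancestral frequency p ~ Uniform(0.05, 0.95);
#' the two population frequencies are then independent
#' Beta(p(1-F)/F, (1-p)(1-F)/F) draws with F the differentiation
#' parameter. For AIM panels, SNPs are re-drawn until the AFR/EUR
#' frequency differential is at least `min_diff`.
#'
#' @param n_snps number of SNPs.
#' @param fst differentiation parameter in (0,1).
#' @param seed optional integer seed.
#' @param min_diff if > 0, enforce |freq_afr - freq_eur| >= min_diff by
#'   per-SNP rejection (used for AIM panels).
#' @return list with `freq_afr`, `freq_eur`, `p_anc`.
#' @export
simulate_ancestral_frequencies <- function(n_snps, fst, seed = NULL,
                                           min_diff = 0) {
  stopifnot(fst > 0, fst < 1, n_snps >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(k) {
    p <- stats::runif(k, 0.05, 0.95)
    sh <- (1 - fst) / fst
    fa <- stats::rbeta(k, p * sh, (1 - p) * sh)
    fe <- stats::rbeta(k, p * sh, (1 - p) * sh)
    list(p = p, fa = fa, fe = fe)
  }
  d <- draw(n_snps)
  if (min_diff > 0) {
    bad <- which(abs(d$fa - d$fe) < min_diff)
    guard <- 0L
    while (length(bad) > 0L) {
      r <- draw(length(bad))
      ok <- abs(r$fa - r$fe) >= min_diff
      d$p[bad[ok]] <- r$p[ok]; d$fa[bad[ok]] <- r$fa[ok]; d$fe[bad[ok]] <- r$fe[ok]
      bad <- bad[!ok]
      guard <- guard + 1L
      if (guard > 10000L) stop("AIM rejection sampling failed to converge")
    }
  }
  eps <- 1e-4   # keep frequencies off the boundary
  list(freq_afr = pmin(pmax(d$fa, eps), 1 - eps),
       freq_eur = pmin(pmax(d$fe, eps), 1 - eps),
       p_anc = d$p)
}

# Deterministic variant space shared by cohort and reference panel:
# genome SNPs + AIMs laid out on n_chrom autosomes, plus the 23 risk-score
# SNPs at their published coordinates and per-population frequencies.
# Consumes config$seed only; callers re-seed afterwards.
sim_variant_space <- function(config) {
  set.seed(config$seed)
  genome <- simulate_ancestral_frequencies(config$n_snps, config$fst)
  aims <- simulate_ancestral_frequencies(config$n_aims, config$fst,
                                         min_diff = config$aim_min_diff)
  risk <- load_risk_table()

  # AIMs: uniformly spaced genetic map per chromosome, 1 cM = 0.01 M = 1 Mb
  per_chrom <- diff(round(seq(0, config$n_aims, length.out = config$n_chrom + 1)))
  aim_chrom <- rep(seq_len(config$n_chrom), per_chrom)
  aim_gpos <- unlist(lapply(per_chrom, function(k)
    if (k > 0) seq(0.01, config$chrom_length, length.out = k) else numeric(0)))
  aim_bp <- as.integer(round(aim_gpos * 1e8 / 2) * 2)  # even positions

  aim_df <- data.frame(
    variant_id = sprintf("aim%05d", seq_len(config$n_aims)),
    chrom = as.character(aim_chrom), pos = aim_bp,
    allele_a = "A", allele_b = "G", genetic_pos = aim_gpos,
    freq_afr = aims$freq_afr, freq_eur = aims$freq_eur,
    stringsAsFactors = FALSE)

  # genome SNPs: random odd positions (disjoint from even AIM positions)
  g_chrom <- sample(seq_len(config$n_chrom), config$n_snps, replace = TRUE)
  g_bp <- sample.int(as.integer(config$chrom_length * 5e7), config$n_snps,
                     replace = TRUE) * 2L + 1L
  while (anyDuplicated(paste(g_chrom, g_bp))) {
    d <- duplicated(paste(g_chrom, g_bp))
    g_bp[d] <- sample.int(as.integer(config$chrom_length * 5e7), sum(d),
                          replace = TRUE) * 2L + 1L
  }
  genome_df <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(config$n_snps)),
    chrom = as.character(g_chrom), pos = g_bp,
    allele_a = "A", allele_b = "G", genetic_pos = NA_real_,
    freq_afr = genome$freq_afr, freq_eur = genome$freq_eur,
    stringsAsFactors = FALSE)

  # risk SNPs: published coordinates; allele_b is the risk allele, with a
  # non-complementary partner so strand filtering never removes them
  partner <- c(A = "G", C = "T", G = "A", T = "C")
  risk_df <- data.frame(
    variant_id = risk$rsid_norm, chrom = as.character(risk$chrom),
    pos = as.integer(risk$pos),
    allele_a = unname(partner[risk$risk_allele]), allele_b = risk$risk_allele,
    genetic_pos = NA_real_,
    freq_afr = risk$freq_afr, freq_eur = risk$freq_eur,
    stringsAsFactors = FALSE)

  all_df <- rbind(genome_df, aim_df, risk_df)
  ord <- variant_order(all_df$chrom, all_df$pos)
  all_df <- all_df[ord, ]
  rownames(all_df) <- NULL
  list(variants = all_df,
       aim_ids = aim_df$variant_id, genome_ids = genome_df$variant_id,
       risk_ids = risk_df$variant_id, risk = risk,
       p_anc = c(genome$p_anc, aims$p_anc))
}

#' Simulate a two-way admixed case-control cohort with ground truth
#'
#' Draws per-sample African ancestry proportions from
#' Beta(`admix_alpha`, `admix_beta`); genome SNP genotypes are
#' Binomial(2, q f_afr + (1-q) f_eur); AIM genotypes are emitted from true
#' local-ancestry tracts generated by a two-state haploid Markov chain
#' along each chromosome (stationary probabilities (q, 1-q); between
#' markers at genetic distance d the chain keeps its state with
#' probability exp(-lambda d), otherwise redraws from the stationary
#' distribution). The 23 risk-score SNPs use the packaged per-population
#' risk-allele frequencies. Case status follows a logistic model in
#' age/10, male sex, standardized q0 = 1 - q_afr and the weighted risk
#' score, with the intercept solved so the mean case probability equals
#' `baseline_prevalence`; the four glaucoma endophenotypes are linear in
#' standardized q0 with Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `genotypes`
#'   (`genotype_matrix`), `records` (`sample_records`), `aim_panel`
#'   (data.frame of AIM variants with panel frequencies), and `truth`
#'   (q_afr_true, per-AIM local ancestry, ancestral frequencies, risk
#'   score, and the linear-predictor components of the case model).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vs <- sim_variant_space(config)
  set.seed(config$seed + 2L)
  n <- config$n_samples

  q_afr <- stats::rbeta(n, config$admix_alpha, config$admix_beta)
  sex <- ifelse(stats::runif(n) < config$male_frac, "male", "female")
  age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
  age <- pmin(pmax(age, 35), 100)

  vt <- vs$variants
  calls <- matrix(NA_integer_, n, nrow(vt),
                  dimnames = list(NULL, vt$variant_id))

  # genome SNPs: binomial mixture of ancestral frequencies
  gi <- match(vs$genome_ids, vt$variant_id)
  fa <- vt$freq_afr[gi]; fe <- vt$freq_eur[gi]
  pmat <- outer(q_afr, fa - fe) + rep(fe, each = n)
  calls[, gi] <- stats::rbinom(n * length(gi), 2L, pmat)

  # AIMs: true tracts from the haploid Markov chain, then allele emission
  ai <- match(vs$aim_ids, vt$variant_id)
  aim_meta <- vt[ai, ]
  local <- matrix(0L, n, length(ai), dimnames = list(NULL, vs$aim_ids))
  aim_calls <- matrix(0L, n, length(ai))
  hap_switches <- numeric(n)   # observed haploid ancestry changes, both haps
  for (ch in unique(aim_meta$chrom)) {
    idx <- which(aim_meta$chrom == ch)
    gp <- aim_meta$genetic_pos[idx]
    L <- length(idx)
    for (hap in 1:2) {
      h <- matrix(0L, n, L)
      h[, 1] <- stats::rbinom(n, 1L, q_afr)
      if (L > 1) for (l in 2:L) {
        s <- exp(-config$generations * (gp[l] - gp[l - 1]))
        stay <- stats::runif(n) < s
        h[, l] <- ifelse(stay, h[, l - 1], stats::rbinom(n, 1L, q_afr))
      }
      if (L > 1)
        hap_switches <- hap_switches +
          rowSums(h[, -1, drop = FALSE] != h[, -L, drop = FALSE])
      f <- ifelse(h == 1L, rep(aim_meta$freq_afr[idx], each = n),
                  rep(aim_meta$freq_eur[idx], each = n))
      aim_calls[, idx] <- aim_calls[, idx] +
        matrix(stats::rbinom(n * L, 1L, f), n, L)
      local[, idx] <- local[, idx] + h
    }
  }
  calls[, ai] <- aim_calls

  # risk-score SNPs at published per-population frequencies
  ri <- match(vs$risk_ids, vt$variant_id)
  pr <- outer(q_afr, vt$freq_afr[ri] - vt$freq_eur[ri]) +
    rep(vt$freq_eur[ri], each = n)
  pr <- pmin(pmax(pr, 0), 1)
  calls[, ri] <- stats::rbinom(n * length(ri), 2L, pr)
  prs <- as.numeric(calls[, ri, drop = FALSE] %*%
                      vs$risk$odds_ratio[match(vt$variant_id[ri], vs$risk$rsid_norm)])

  # case-status model on q0 = 1 - q_afr (low q0 = high African ancestry)
  q0 <- 1 - q_afr
  zq0 <- as.numeric(scale(q0))
  lp0 <- log(config$effect_age_per_10y) * age / 10 +
    log(config$effect_male) * (sex == "male") +
    log(config$effect_q0_per_sd) * zq0 +
    log(config$effect_prs_per_point) * prs
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp0)) -
                         config$baseline_prevalence,
                       c(-60, 60), tol = 1e-10)$root
  status <- ifelse(stats::runif(n) < stats::plogis(b0 + lp0), "case", "control")

  # endophenotypes: baselines/noise at field-typical values, q0 effects
  # from the generating coefficients (CCT configurable, others fixed)
  iop <- 15.9 - 0.08 * zq0 + 0.02 * (age - 65) + stats::rnorm(n, 0, 4.3)
  cct <- 535 + config$cct_coef_per_sd * zq0 - 0.2 * (age - 65) +
    3 * (sex == "male") + stats::rnorm(n, 0, 30)
  cdr <- 0.65 - 0.004 * zq0 + 0.002 * (age - 65) + stats::rnorm(n, 0, 0.15)
  cdr <- pmin(pmax(cdr, 0), 1)
  rnfl <- 82 + 0.46 * zq0 - 0.2 * (age - 65) + stats::rnorm(n, 0, 13)
  # measurement availability mirrors observed endophenotype coverage
  blank <- function(x, frac) { x[stats::runif(n) < frac] <- NA_real_; x }
  iop <- blank(iop, 0.25); cct <- blank(cct, 0.16)
  cdr <- blank(cdr, 0.14); rnfl <- blank(rnfl, 0.36)

  ids <- sprintf("S%05d", seq_len(n))
  records <- sample_records(data.frame(
    sample_id = ids, status = status, age = age, sex = sex,
    cohort = "discovery", iop = iop, cct = cct, cdr = cdr, rnfl = rnfl,
    stringsAsFactors = FALSE))
  gm <- genotype_matrix(calls, vt[, c("variant_id", "chrom", "pos",
                                      "allele_a", "allele_b", "genetic_pos")],
                        ids)
  rownames(local) <- ids
  aim_panel <- aim_meta[, c("variant_id", "chrom", "pos", "genetic_pos",
                            "freq_afr", "freq_eur")]
  rownames(aim_panel) <- NULL

  truth <- list(q_afr_true = stats::setNames(q_afr, ids),
                local_ancestry_true = local,
                hap_switches = stats::setNames(hap_switches, ids),
                ancestral_freq_afr = stats::setNames(vt$freq_afr, vt$variant_id),
                ancestral_freq_eur = stats::setNames(vt$freq_eur, vt$variant_id),
                prs_true = stats::setNames(prs, ids),
                linear_predictor = data.frame(
                  sample_id = ids, intercept = b0, zq0 = zq0,
                  lp = b0 + lp0, p_case = stats::plogis(b0 + lp0),
                  stringsAsFactors = FALSE))
  structure(list(genotypes = gm, records = records, aim_panel = aim_panel,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' Simulate a labeled reference panel on the cohort's variant space
#'
#' Generates unadmixed AFR and EUR samples from the same ancestral
#' frequency draw as [simulate_cohort()] under the same `config` (so the
#' two share variants by construction), plus optional EAS/AMR/SAS decoy
#' populations drawn at their own Balding-Nichols differentiation and an
#' optional admixed "ASW"-labeled population inside the AFR
#' superpopulation.
#'
#' @param config a [sim_config()].
#' @return a [reference_panel()].
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vs <- sim_variant_space(config)
  set.seed(config$seed + 1L)
  vt <- vs$variants
  m <- nrow(vt)

  draw_pop <- function(k, freq) {
    matrix(stats::rbinom(k * m, 2L, rep(freq, each = k)), k, m)
  }
  blocks <- list(); pops <- character(); supers <- character()
  if (config$panel_afr > 0) {
    blocks <- c(blocks, list(draw_pop(config$panel_afr, vt$freq_afr)))
    pops <- c(pops, rep("AFR_SIM", config$panel_afr))
    supers <- c(supers, rep("AFR", config$panel_afr))
  }
  if (config$panel_eur > 0) {
    blocks <- c(blocks, list(draw_pop(config$panel_eur, vt$freq_eur)))
    pops <- c(pops, rep("EUR_SIM", config$panel_eur))
    supers <- c(supers, rep("EUR", config$panel_eur))
  }
  if (config$panel_asw > 0) {
    qa <- stats::rbeta(config$panel_asw, config$admix_alpha, config$admix_beta)
    p <- outer(qa, vt$freq_afr - vt$freq_eur) + rep(vt$freq_eur, each = config$panel_asw)
    blocks <- c(blocks, list(matrix(stats::rbinom(config$panel_asw * m, 2L, p),
                                    config$panel_asw, m)))
    pops <- c(pops, rep("ASW", config$panel_asw))
    supers <- c(supers, rep("AFR", config$panel_asw))
  }
  decoys <- config$panel_decoys[config$panel_decoys > 0]
  sh <- (1 - config$decoy_fst) / config$decoy_fst
  p_anc_full <- rep(0.5, m)
  p_anc_full[match(c(vs$genome_ids, vs$aim_ids), vt$variant_id)] <- vs$p_anc
  for (d in names(decoys)) {
    fd <- stats::rbeta(m, p_anc_full * sh, (1 - p_anc_full) * sh)
    fd <- pmin(pmax(fd, 1e-4), 1 - 1e-4)
    blocks <- c(blocks, list(draw_pop(decoys[[d]], fd)))
    pops <- c(pops, rep(paste0(d, "_SIM"), decoys[[d]]))
    supers <- c(supers, rep(d, decoys[[d]]))
  }
  calls <- do.call(rbind, blocks)
  ids <- sprintf("P%05d", seq_len(nrow(calls)))
  gm <- genotype_matrix(calls, vt[, c("variant_id", "chrom", "pos",
                                      "allele_a", "allele_b", "genetic_pos")],
                        ids)
  reference_panel(gm, pops, supers)
}

#' Contamination plan for QC validation
#'
#' Describes the contaminant classes [inject_qc_contaminants()] plants in
#' a clean simulated cohort, one class per QC rule.
#'
#' @param n_duplicate_pairs duplicated sample pairs (relatedness rule).
#' @param n_missing_samples samples given `sample_missing_rate` missing calls.
#' @param n_het_high,n_het_low samples with inflated / deflated
#'   heterozygosity.
#' @param n_missing_variants variants given `variant_missing_rate` missing
#'   calls.
#' @param n_dcr_variants variants made missing only in cases (rate
#'   `dcr_case_missing`).
#' @param n_hwe_variants variants redrawn from an inbreeding model with
#'   coefficient `hwe_f`.
#' @param n_rare_variants variants redrawn at minor allele frequency
#'   `rare_maf`.
#' @param sample_missing_rate,variant_missing_rate,dcr_case_missing,hwe_f,rare_maf
#'   class parameters.
#' @param seed optional integer seed for the injection draws.
#' @return list of class `contamination_spec`.
#' @export
contamination_spec <- function(n_duplicate_pairs = 5, n_missing_samples = 5,
                               n_het_high = 3, n_het_low = 3,
                               n_missing_variants = 20, n_dcr_variants = 10,
                               n_hwe_variants = 10, n_rare_variants = 10,
                               sample_missing_rate = 0.06,
                               variant_missing_rate = 0.06,
                               dcr_case_missing = 0.15, hwe_f = 0.5,
                               rare_maf = 0.002, seed = NULL) {
  spec <- as.list(environment())
  stopifnot(sample_missing_rate >= 0, sample_missing_rate <= 1,
            variant_missing_rate >= 0, variant_missing_rate <= 1,
            dcr_case_missing >= 0, dcr_case_missing <= 1,
            hwe_f >= 0, hwe_f <= 1, rare_maf >= 0, rare_maf <= 0.5)
  class(spec) <- "contamination_spec"
  spec
}

#' Plant QC contaminants in a simulated cohort
#'
#' Modifies a clean cohort in place according to a [contamination_spec()],
#' keeping exact truth labels of what was planted so QC sensitivity and
#' false-removal rates can be measured. Contaminated variants are chosen
#' among genome SNPs only (AIMs and risk SNPs are left intact). A
#' zero-count spec returns the inputs unchanged.
#'
#' @param m a `genotype_matrix`.
#' @param records matching `sample_records`.
#' @param spec a [contamination_spec()].
#' @return list with modified `genotypes`, `records` and `truth` (ids per
#'   contaminant class; `duplicate_pairs` is a two-column matrix).
#' @export
inject_qc_contaminants <- function(m, records, spec = contamination_spec()) {
  stopifnot(inherits(m, "genotype_matrix"), inherits(spec, "contamination_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  total <- spec$n_duplicate_pairs + spec$n_missing_samples +
    spec$n_het_high + spec$n_het_low
  if (total > n_samples(m)) stop("contaminant sample counts exceed cohort size")
  nv_needed <- spec$n_missing_variants + spec$n_dcr_variants +
    spec$n_hwe_variants + spec$n_rare_variants
  genome_ids <- grep("^snp", m$variants$variant_id, value = TRUE)
  if (nv_needed > length(genome_ids))
    stop("contaminant variant counts exceed available genome SNPs")
  truth <- list(duplicate_pairs = matrix(character(0), 0, 2),
                missing_samples = character(0), het_high = character(0),
                het_low = character(0), missing_variants = character(0),
                dcr_variants = character(0), hwe_variants = character(0),
                rare_variants = character(0))
  if (total == 0 && nv_needed == 0)
    return(list(genotypes = m, records = records, truth = truth))

  calls <- m$calls
  n <- nrow(calls)
  # disjoint sample draws per class
  pool <- sample(m$sample_ids, total)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  dup_src <- take(spec$n_duplicate_pairs)
  miss_s <- take(spec$n_missing_samples)
  het_hi <- take(spec$n_het_high)
  het_lo <- take(spec$n_het_low)

  vpool <- sample(genome_ids, nv_needed)
  vtake <- function(k) { out <- vpool[seq_len(k)]; vpool <<- vpool[-seq_len(k)]; out }
  miss_v <- vtake(spec$n_missing_variants)
  dcr_v <- vtake(spec$n_dcr_variants)
  hwe_v <- vtake(spec$n_hwe_variants)
  rare_v <- vtake(spec$n_rare_variants)

  for (v in miss_v) {
    j <- which(stats::runif(n) < spec$variant_missing_rate)
    calls[j, v] <- NA_integer_
  }
  case_rows <- which(records$status == "case")
  for (v in dcr_v) {
    j <- case_rows[stats::runif(length(case_rows)) < spec$dcr_case_missing]
    calls[j, v] <- NA_integer_
  }
  for (v in hwe_v) {
    p <- mean(calls[, v], na.rm = TRUE) / 2
    p <- min(max(p, 0.25), 0.75)       # keep the violation detectable
    f <- spec$hwe_f
    probs <- c(p^2 + f * p * (1 - p), 2 * p * (1 - p) * (1 - f),
               (1 - p)^2 + f * p * (1 - p))
    calls[, v] <- sample(2:0, n, replace = TRUE, prob = probs)
  }
  for (v in rare_v)
    calls[, v] <- stats::rbinom(n, 2L, spec$rare_maf)

  for (s in miss_s) {
    i <- match(s, m$sample_ids)
    j <- which(stats::runif(ncol(calls)) < spec$sample_missing_rate)
    calls[i, j] <- NA_integer_
  }
  for (s in het_hi) {   # resample to heterozygote with high probability
    i <- match(s, m$sample_ids)
    nm <- which(!is.na(calls[i, ]))
    flip <- nm[stats::runif(length(nm)) < 0.8]
    calls[i, flip] <- 1L
  }
  for (s in het_lo) {   # collapse heterozygotes to homozygotes
    i <- match(s, m$sample_ids)
    het <- which(!is.na(calls[i, ]) & calls[i, ] == 1L)
    calls[i, het] <- 2L * stats::rbinom(length(het), 1L, 0.5)
  }

  dup_ids <- paste0(dup_src, "_dup")
  if (length(dup_src) > 0) {
    calls <- rbind(calls, calls[match(dup_src, m$sample_ids), , drop = FALSE])
    dup_rec <- records[match(dup_src, records$sample_id), ]
    dup_rec$sample_id <- dup_ids
    records <- sample_records(rbind(as.data.frame(records), as.data.frame(dup_rec)))
  }
  gm <- genotype_matrix(calls, m$variants, c(m$sample_ids, dup_ids))
  truth$duplicate_pairs <- cbind(dup_src, dup_ids)
  truth$missing_samples <- miss_s
  truth$het_high <- het_hi
  truth$het_low <- het_lo
  truth$missing_variants <- miss_v
  truth$dcr_variants <- dcr_v
  truth$hwe_variants <- hwe_v
  truth$rare_variants <- rare_v
  list(genotypes = gm, records = records, truth = truth)
}
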