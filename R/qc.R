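#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the sample size and the minor-allele
#' count, the probability of each possible heterozygote count is computed
#' in closed form, and the p-value is the summed probability of all
#' configurations no more probable than the observed one (two-sided).
#' Monomorphic variants return p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (homozygous a, heterozygous,
#'   homozygous b).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype counts")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("no genotyped samples")
  r <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)   # minor allele count
  if (r == 0) return(1)
  h <- seq.int(r %% 2, r, by = 2)              # feasible het counts
  # log P(het = h | n, r), unnormalized
  lp <- h * log(2) - lgamma((r - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((2 * n - r - h) / 2 + 1)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- p[match(n_ab, h)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

removal_df <- function(ids, reason, value) {
  data.frame(sample_id = ids, reason = rep_len(reason, length(ids)),
             value = rep_len(value, length(ids)), stringsAsFactors = FALSE)
}

#' Per-sample missingness filter
#'
#' A sample fails when its fraction of missing calls is at least the
#' threshold (boundary inclusive).
#'
#' @param m a `genotype_matrix`.
#' @param threshold missing-call fraction, default 0.03.
#' @return list with `keep` (surviving sample ids) and `removed`
#'   (data.frame sample_id, reason, value).
#' @export
sample_missingness_filter <- function(m, threshold = 0.03) {
  rate <- sample_missing_rate(m)
  bad <- rate >= threshold
  list(keep = m$sample_ids[!bad],
       removed = removal_df(m$sample_ids[bad], "missingness", rate[bad]))
}

#' Heterozygosity outlier filter
#'
#' Per-sample heterozygous-call rate over non-missing autosomal calls;
#' samples outside mean +/- `sigma` * SD are removed. The band is computed
#' once on the full cohort before any removal; if the SD is zero the band
#' degenerates to a point and nobody is removed. Samples with no usable
#' calls are removed with reason `"no_calls"`.
#'
#' @param m a `genotype_matrix` with at least 2 samples.
#' @param sigma band half-width in cohort standard deviations, default 3.
#' @return list with `keep`, `removed` (sample_id, reason, value) and the
#'   band (`mean`, `sd`).
#' @export
heterozygosity_filter <- function(m, sigma = 3) {
  if (n_samples(m) < 2) stop("heterozygosity filter needs >= 2 samples")
  n_called <- rowSums(!is.na(m$calls))
  het <- rowSums(m$calls == 1L, na.rm = TRUE) / n_called
  no_calls <- n_called == 0L
  mu <- mean(het[!no_calls])
  sd_ <- stats::sd(het[!no_calls])
  out <- !no_calls & sd_ > 0 & (het < mu - sigma * sd_ | het > mu + sigma * sd_)
  removed <- rbind(
    removal_df(m$sample_ids[no_calls], "no_calls", NA_real_),
    removal_df(m$sample_ids[out], "heterozygosity", het[out]))
  list(keep = m$sample_ids[!no_calls & !out], removed = removed,
       mean = mu, sd = sd_)
}

# Pairwise IBS counts and the per-pair expected IBS-given-IBD sums needed
# by the method-of-moments estimator, computed with indicator-matrix
# products so the whole cohort is handled at once.
ibs_components <- function(calls, freqs) {
  A0 <- (!is.na(calls) & calls == 0L) * 1
  A1 <- (!is.na(calls) & calls == 1L) * 1
  A2 <- (!is.na(calls) & calls == 2L) * 1
  N <- (!is.na(calls)) * 1
  ibs2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  ibs0 <- tcrossprod(A0, A2); ibs0 <- ibs0 + t(ibs0)
  shared <- tcrossprod(N)
  ibs1 <- shared - ibs2 - ibs0
  p <- freqs; q <- 1 - p
  w <- cbind(e00 = 2 * p^2 * q^2,
             e10 = 4 * p^3 * q + 4 * p * q^3,
             e20 = p^4 + q^4 + 4 * p^2 * q^2,
             e11 = 2 * p^2 * q + 2 * p * q^2,
             e21 = p^3 + q^3 + p^2 * q + p * q^2)
  ew <- lapply(colnames(w), function(k) tcrossprod(sweep(N, 2, w[, k], "*"), N))
  names(ew) <- colnames(w)
  list(ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2, shared = shared, ew = ew)
}

pihat_from_components <- function(comp) {
  p0 <- comp$ibs0 / comp$ew$e00
  p1 <- (comp$ibs1 - p0 * comp$ew$e10) / comp$ew$e11
  p2 <- (comp$ibs2 - p0 * comp$ew$e20 - p1 * comp$ew$e21) / comp$shared
  p0 <- pmin(pmax(p0, 0), 1); p1 <- pmin(pmax(p1, 0), 1); p2 <- pmin(pmax(p2, 0), 1)
  pmin(pmax(p2 + p1 / 2, 0), 1)
}

#' Method-of-moments identity-by-descent estimate for one pair
#'
#' The standard moment estimator: observed identical-by-state 0/1/2 counts
#' are compared with their expectations under IBD states given cohort
#' allele frequencies, giving P(IBD=0,1,2); PI_HAT = P(IBD=2) +
#' P(IBD=1)/2, clamped to [0,1].
#'
#' @param m a `genotype_matrix`.
#' @param pair two sample ids (or indices).
#' @param min_shared minimum shared non-missing variants, default 100.
#' @return PI_HAT in [0, 1].
#' @export
ibd_estimate <- function(m, pair, min_shared = 100) {
  i <- resolve_index(pair, m$sample_ids, "sample")
  if (length(i) != 2L) stop("pair must name exactly two samples")
  calls <- m$calls[i, , drop = FALSE]
  ok <- !is.na(calls[1, ]) & !is.na(calls[2, ])
  if (sum(ok) < min_shared)
    stop("only ", sum(ok), " shared non-missing variants for the pair")
  freqs <- allele_freq(m)
  poly <- ok & freqs > 0 & freqs < 1
  comp <- ibs_components(calls[, poly, drop = FALSE], freqs[poly])
  unname(pihat_from_components(comp)[1, 2])
}

#' Pairwise PI_HAT matrix
#'
#' @param m a `genotype_matrix`.
#' @param max_snps cap on the number of variants used (evenly thinned)
#'   to keep the pairwise computation tractable; `Inf` disables thinning.
#' @return symmetric n x n matrix of PI_HAT values (diagonal NA).
#' @export
ibd_matrix <- function(m, max_snps = 10000) {
  freqs <- allele_freq(m)
  poly <- which(!is.nan(freqs) & freqs > 0 & freqs < 1)
  if (length(poly) > max_snps)
    poly <- poly[round(seq(1, length(poly), length.out = max_snps))]
  comp <- ibs_components(m$calls[, poly, drop = FALSE], freqs[poly])
  ph <- pihat_from_components(comp)
  diag(ph) <- NA_real_
  dimnames(ph) <- list(m$sample_ids, m$sample_ids)
  ph
}

#' Greedy relatedness pruning
#'
#' Among all pairs with PI_HAT at or above the threshold, repeatedly
#' removes the involved sample with the highest missingness (ties broken
#' towards the lexicographically larger sample id) until no flagged pair
#' remains.
#'
#' @param m a `genotype_matrix`.
#' @param threshold PI_HAT threshold, default 0.1875.
#' @param max_snps passed to [ibd_matrix()].
#' @return list with `keep`, `removed` (sample_id, reason, value =
#'   highest PI_HAT involving the sample at removal time) and `pairs`
#'   (the initially flagged pairs).
#' @export
relatedness_prune <- function(m, threshold = 0.1875, max_snps = 10000) {
  ph <- ibd_matrix(m, max_snps = max_snps)
  miss <- sample_missing_rate(m)
  names(miss) <- m$sample_ids
  flag <- which(upper.tri(ph) & ph >= threshold, arr.ind = TRUE)
  pairs <- data.frame(id1 = m$sample_ids[flag[, 1]],
                      id2 = m$sample_ids[flag[, 2]],
                      pi_hat = ph[flag], stringsAsFactors = FALSE)
  active <- pairs
  removed <- data.frame(sample_id = character(0), reason = character(0),
                        value = numeric(0), stringsAsFactors = FALSE)
  while (nrow(active) > 0) {
    cand <- unique(c(active$id1, active$id2))
    # highest missingness; ties -> lexicographically larger id
    top_miss <- miss[cand] == max(miss[cand])
    tied <- sort(cand[top_miss], decreasing = TRUE)
    pick <- tied[1]
    removed <- rbind(removed, data.frame(
      sample_id = pick, reason = "relatedness",
      value = max(active$pi_hat[active$id1 == pick | active$id2 == pick]),
      stringsAsFactors = FALSE))
    active <- active[active$id1 != pick & active$id2 != pick, , drop = FALSE]
  }
  list(keep = setdiff(m$sample_ids, removed$sample_id),
       removed = removed, pairs = pairs)
}

#' Variant-level QC filters
#'
#' Applied after sample QC: a variant is removed when its missing fraction
#' exceeds 0.03 (strictly), when a two-sided Fisher exact test of
#' missingness against case/control status has p below `dcr_alpha`, when
#' the Hardy-Weinberg exact test has p below `hwe_alpha`, or when its
#' minor allele frequency is below `maf_min`. Every triggering reason is
#' recorded; the first in the order above is canonical.
#'
#' @param m a `genotype_matrix` (sample QC already applied).
#' @param sample_status character vector aligned with samples, values
#'   case/control/suspect; suspects are excluded from the differential
#'   call-rate test.
#' @param missing_max,dcr_alpha,hwe_alpha,maf_min thresholds.
#' @param hwe_controls_only compute the HWE test on controls only (common
#'   practice) instead of all samples (default).
#' @return list with `keep` (variant ids) and `removed` (variant_id,
#'   reason = canonical, reasons = all, value of the canonical statistic).
#' @export
variant_filters <- function(m, sample_status, missing_max = 0.03,
                            dcr_alpha = 1e-5, hwe_alpha = 1e-5,
                            maf_min = 0.01, hwe_controls_only = FALSE) {
  stopifnot(length(sample_status) == n_samples(m))
  calls <- m$calls
  nv <- n_variants(m)
  miss_frac <- colMeans(is.na(calls))
  maf <- minor_allele_freq(m)
  maf[is.nan(maf)] <- 0

  is_case <- sample_status == "case"
  is_ctrl <- sample_status == "control"
  do_dcr <- any(is_case) && any(is_ctrl)
  if (!do_dcr) warning("no cases or no controls: differential call-rate test skipped")
  dcr_p <- rep(NA_real_, nv)
  if (do_dcr) {
    miss_case <- colSums(is.na(calls[is_case, , drop = FALSE]))
    miss_ctrl <- colSums(is.na(calls[is_ctrl, , drop = FALSE]))
    n_case <- sum(is_case); n_ctrl <- sum(is_ctrl)
    for (l in seq_len(nv)) {
      if (miss_case[l] + miss_ctrl[l] == 0L) { dcr_p[l] <- 1; next }
      tab <- matrix(c(miss_case[l], n_case - miss_case[l],
                      miss_ctrl[l], n_ctrl - miss_ctrl[l]), 2, 2)
      dcr_p[l] <- stats::fisher.test(tab)$p.value
    }
  }

  hwe_rows <- if (hwe_controls_only) is_ctrl else rep(TRUE, n_samples(m))
  hc <- calls[hwe_rows, , drop = FALSE]
  hwe_p <- vapply(seq_len(nv), function(l) {
    g <- hc[, l]; g <- g[!is.na(g)]
    if (length(g) == 0L) return(1)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))

  fail <- cbind(missingness = miss_frac > missing_max,
                differential_call_rate = !is.na(dcr_p) & dcr_p < dcr_alpha,
                hwe = hwe_p < hwe_alpha,
                maf = maf < maf_min)
  any_fail <- rowSums(fail) > 0
  canonical <- apply(fail, 1, function(z) if (any(z)) colnames(fail)[which(z)[1]] else NA)
  all_reasons <- apply(fail, 1, function(z) paste(colnames(fail)[z], collapse = ";"))
  stat <- ifelse(canonical == "missingness", miss_frac,
                 ifelse(canonical == "differential_call_rate", dcr_p,
                        ifelse(canonical == "hwe", hwe_p, maf)))
  list(keep = m$variants$variant_id[!any_fail],
       removed = data.frame(variant_id = m$variants$variant_id[any_fail],
                            reason = canonical[any_fail],
                            reasons = all_reasons[any_fail],
                            value = stat[any_fail], stringsAsFactors = FALSE),
       stats = data.frame(variant_id = m$variants$variant_id,
                          missing = miss_frac, dcr_p = dcr_p, hwe_p = hwe_p,
                          maf = maf, stringsAsFactors = FALSE))
}

#' Run the full QC cascade
#'
#' Sample filters in fixed order (missingness, heterozygosity,
#' relatedness) followed by variant filters, with an auditable report of
#' every removal and before/after counts.
#'
#' @param m a `genotype_matrix`.
#' @param records matching `sample_records` (used for case/control status
#'   in the differential call-rate test).
#' @param sample_missing,het_sigma,ibd_threshold,variant_missing,dcr_alpha,hwe_alpha,maf_min
#'   thresholds (documented at the individual filters).
#' @param ibd_max_snps SNP cap for the pairwise relatedness scan.
#' @return list of class `qc_result`: `genotypes` (filtered matrix),
#'   `records` (filtered), and `report` (a `qc_report`).
#' @export
run_qc <- function(m, records, sample_missing = 0.03, het_sigma = 3,
                   ibd_threshold = 0.1875, variant_missing = 0.03,
                   dcr_alpha = 1e-5, hwe_alpha = 1e-5, maf_min = 0.01,
                   ibd_max_snps = 10000) {
  stopifnot(inherits(m, "genotype_matrix"))
  records <- sample_records(records)
  if (!setequal(records$sample_id, m$sample_ids))
    stop("records and genotype matrix disagree on sample ids")
  n0 <- n_samples(m); v0 <- n_variants(m)

  removed_samples <- data.frame(sample_id = character(0), reason = character(0),
                                value = numeric(0), stringsAsFactors = FALSE)
  note <- function(prev, res) {
    new <- res$removed[!res$removed$sample_id %in% prev$sample_id, , drop = FALSE]
    rbind(prev, new)
  }
  f1 <- sample_missingness_filter(m, sample_missing)
  removed_samples <- note(removed_samples, f1)
  m1 <- gm_subset(m, samples = f1$keep)

  f2 <- heterozygosity_filter(m1, het_sigma)
  removed_samples <- note(removed_samples, f2)
  m2 <- gm_subset(m1, samples = f2$keep)

  f3 <- relatedness_prune(m2, ibd_threshold, max_snps = ibd_max_snps)
  removed_samples <- note(removed_samples, f3)
  m3 <- gm_subset(m2, samples = f3$keep)

  rec3 <- records[match(m3$sample_ids, records$sample_id), , drop = FALSE]
  f4 <- variant_filters(m3, rec3$status, missing_max = variant_missing,
                        dcr_alpha = dcr_alpha, hwe_alpha = hwe_alpha,
                        maf_min = maf_min)
  m4 <- gm_subset(m3, variants = match(f4$keep, m3$variants$variant_id))

  report <- structure(list(
    removed_samples = removed_samples,
    removed_variants = f4$removed,
    thresholds = list(sample_missing = sample_missing, het_sigma = het_sigma,
                      ibd_threshold = ibd_threshold,
                      variant_missing = variant_missing, dcr_alpha = dcr_alpha,
                      hwe_alpha = hwe_alpha, maf_min = maf_min),
    counts = data.frame(
      stage = c("input", "sample_missingness", "heterozygosity",
                "relatedness", "variant_filters"),
      samples = c(n0, n_samples(m1), n_samples(m2), n_samples(m3), n_samples(m4)),
      variants = c(v0, v0, v0, v0, n_variants(m4)))),
    class = "qc_report")

  rec4 <- sample_records(rec3)
  structure(list(genotypes = m4, records = rec4, report = report),
            class = "qc_result")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$removed_samples) > 0) {
    cat("sample removals by reason:\n")
    print(table(x$removed_samples$reason))
  }
  if (nrow(x$removed_variants) > 0) {
    cat("variant removals by canonical reason:\n")
    print(table(x$removed_variants$reason))
  }
  invisible(x)
}

#' Write a QC report as TSV + JSON summary
#'
#' @param report a `qc_report`.
#' @param tsv_path,json_path output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_qc_report <- function(report, tsv_path, json_path = NULL) {
  rs <- report$removed_samples
  rv <- report$removed_variants
  ent <- rbind(
    if (nrow(rs) > 0) data.frame(entity = rs$sample_id, type = "sample",
                                 reason = rs$reason, value = rs$value),
    if (nrow(rv) > 0) data.frame(entity = rv$variant_id, type = "variant",
                                 reason = rv$reason, value = rv$value))
  if (is.null(ent)) ent <- data.frame(entity = character(0), type = character(0),
                                      reason = character(0), value = numeric(0))
  utils::write.table(ent, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(thresholds = report$thresholds,
                              counts = report$counts),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
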