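test_that("sample missingness boundary is inclusive ('at least 3%')", {
  calls <- matrix(0L, 3, 100)
  calls[1, 1:3] <- NA          # exactly 3%
  calls[2, 1:2] <- NA          # 2%
  m <- tiny_gm(calls)
  res <- sample_missingness_filter(m)
  expect_equal(res$removed$sample_id, "S01")
  expect_setequal(res$keep, c("S02", "S03"))
})

test_that("heterozygosity filter: degenerate band keeps everyone, forced outlier removed", {
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), each = 6), 6, 4)
  m <- tiny_gm(calls)                 # identical het rate for all
  res <- heterozygosity_filter(m)
  expect_equal(res$sd, 0)
  expect_length(res$removed$sample_id, 0)

  set.seed(1)
  calls2 <- matrix(rbinom(40 * 200, 2, 0.5), 40, 200)
  calls2[1, ] <- 0L                  # het rate 0 against a cohort near 0.5
  m2 <- tiny_gm(calls2)
  res2 <- heterozygosity_filter(m2)
  expect_true("S01" %in% res2$removed$sample_id)
})

test_that("exact HWE test: monomorphic p = 1, modal configuration p = 1, oracle agreement", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_equal(hwe_exact_test(20, 40, 40), hwe_oracle(20, 40, 40),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 3), "negative")
})

test_that("exact HWE test matches the enumeration oracle for every configuration with n <= 50", {
  worst <- 0
  for (n in c(1:20, 25, 30, 40, 50)) {
    for (r in 0:n) {
      d <- hwe_oracle_dist(max(n, 1), max(r, 1))
      for (h in seq.int(r %% 2, r, by = 2)) {
        n_aa <- (r - h) / 2
        n_bb <- n - h - n_aa
        worst <- max(worst, abs(hwe_exact_test(n_aa, h, n_bb) -
                                  hwe_oracle(n_aa, h, n_bb)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("PI_HAT is ~1 for duplicates, ~0.5 for parent-offspring, ~0 for unrelateds", {
  set.seed(21)
  nv <- 10000
  f <- runif(nv, 0.1, 0.9)
  pop <- matrix(rbinom(60 * nv, 2, rep(f, each = 60)), 60, nv)
  # parent-offspring: child gets one allele from each of two parents
  p1 <- pop[1, ]; p2 <- pop[2, ]
  child <- rbinom(nv, 1, p1 / 2) + rbinom(nv, 1, p2 / 2)
  calls <- rbind(pop, dup = pop[3, ], child = child)
  m <- tiny_gm(calls, pos = seq_len(nv) * 10L)
  ids <- m$sample_ids
  expect_gte(ibd_estimate(m, c(ids[3], ids[61])), 0.95)   # duplicate
  expect_equal(ibd_estimate(m, c(ids[1], ids[62])), 0.5, tolerance = 0.05)
  expect_lte(ibd_estimate(m, c(ids[4], ids[5])), 0.05)    # unrelated
  expect_error(ibd_estimate(m, c(ids[1], ids[2]), min_shared = 1e6), "shared")
})

test_that("relatedness pruning removes one member per duplicate pair and resolves chains", {
  set.seed(22)
  nv <- 3000
  f <- runif(nv, 0.2, 0.8)
  base <- matrix(rbinom(10 * nv, 2, rep(f, each = 10)), 10, nv)
  A <- base[1, ]; C <- base[2, ]
  B <- A; B[1501:nv] <- C[1501:nv]       # mosaic: related to both A and C
  calls <- rbind(base, A2 = A, B = B, C2 = C)
  calls[12, sample(nv, 150)] <- NA       # B has the highest missingness
  m <- tiny_gm(calls, pos = seq_len(nv) * 10L,
               ids = c(sprintf("U%02d", 1:10), "A", "B", "C"))
  res <- relatedness_prune(m)
  expect_true("B" %in% res$removed$sample_id)
  expect_true(all(c("A", "C") %in% res$keep))
  # pairs A~B and B~C flagged, A~C not
  key <- paste(res$pairs$id1, res$pairs$id2)
  expect_false(any(grepl("^A C$|^C A$", key)))

  # single duplicated pair: exactly one member goes
  m2 <- tiny_gm(rbind(base, dup = base[1, ]), pos = seq_len(nv) * 10L)
  res2 <- relatedness_prune(m2)
  expect_equal(nrow(res2$removed), 1)
  expect_true(res2$removed$sample_id %in% c("S01", "S11"))

  # nothing above threshold: identity
  m3 <- tiny_gm(base, pos = seq_len(nv) * 10L)
  res3 <- relatedness_prune(m3)
  expect_equal(nrow(res3$removed), 0)
  expect_setequal(res3$keep, m3$sample_ids)
})

test_that("variant filters: missingness boundary, differential call rate, MAF", {
  set.seed(23)
  n <- 400
  status <- rep(c("case", "control"), each = n / 2)
  calls <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  calls[sample(n, 0.04 * n), 1] <- NA                     # 4% missing -> out
  calls[sample(n, 0.02 * n), 2] <- NA                     # 2% -> stays
  case_rows <- which(status == "case")
  calls[case_rows[1:60], 3] <- NA                         # case-only missing
  calls[, 4] <- rbinom(n, 2, 0.004)                       # MAF < 0.01
  m <- tiny_gm(calls)
  res <- variant_filters(m, status)
  removed <- res$removed$variant_id
  expect_true(all(c("v001", "v003", "v004") %in% removed))
  expect_false("v002" %in% removed)
  expect_equal(res$removed$reason[res$removed$variant_id == "v001"], "missingness")
  # v003 trips both the missingness and the differential-call-rate rules
  expect_match(res$removed$reasons[res$removed$variant_id == "v003"],
               "differential_call_rate")
  # Fisher oracle for the differential call-rate p-value
  p_oracle <- stats::fisher.test(matrix(c(60, 140, 0, 200), 2))$p.value
  expect_equal(res$stats$dcr_p[res$stats$variant_id == "v003"], p_oracle,
               tolerance = 1e-12)
  expect_warning(variant_filters(m, rep("case", n)), "skipped")
})

test_that("on clean data nearly all common variants survive and QC is idempotent", {
  run <- medium_cohort()
  co <- run$co
  vf <- variant_filters(co$genotypes, co$records$status)
  common <- co$genotypes$variants$variant_id[minor_allele_freq(co$genotypes) >= 0.05]
  expect_gte(mean(common %in% vf$keep), 0.99)

  # full cascade idempotence on a clean homogeneous cohort
  cfg <- sim_config(n_samples = 10, n_snps = 2000, n_aims = 50, n_chrom = 4,
                    panel_afr = 250, panel_eur = 5, seed = 272)
  pan <- simulate_reference_panel(cfg)
  hom <- gm_subset(pan$genotypes, samples = pan$superpopulation == "AFR")
  rec <- tiny_records(hom$sample_ids)
  qc1 <- run_qc(hom, rec)
  qc2 <- run_qc(qc1$genotypes, qc1$records)
  expect_equal(n_variants(qc2$genotypes), n_variants(qc1$genotypes))
  expect_gte(n_samples(qc2$genotypes) / n_samples(qc1$genotypes), 0.99)
})

test_that("every planted contaminant class is removed with high sensitivity and low false-removal", {
  run <- study_run()
  co <- run$co
  spec <- contamination_spec(seed = 314)
  inj <- inject_qc_contaminants(co$genotypes, co$records, spec)
  qc <- run_qc(inj$genotypes, inj$records)
  tr <- inj$truth
  removed_s <- qc$report$removed_samples$sample_id
  removed_v <- qc$report$removed_variants$variant_id

  planted_s <- c(tr$missing_samples, tr$het_high, tr$het_low)
  expect_gte(mean(planted_s %in% removed_s), 0.95)
  # exactly one member of each duplicate pair is gone
  dup_removed <- apply(tr$duplicate_pairs, 1, function(p) sum(p %in% removed_s))
  expect_true(all(dup_removed >= 1))
  planted_v <- c(tr$missing_variants, tr$dcr_variants, tr$hwe_variants,
                 tr$rare_variants)
  expect_gte(mean(planted_v %in% removed_v), 0.95)

  clean_s <- setdiff(inj$genotypes$sample_ids,
                     c(planted_s, as.vector(tr$duplicate_pairs)))
  expect_lte(mean(clean_s %in% removed_s), 0.01)
  clean_common <- setdiff(
    inj$genotypes$variants$variant_id[minor_allele_freq(inj$genotypes) >= 0.05],
    planted_v)
  expect_lte(mean(clean_common %in% removed_v), 0.01)

  # report bookkeeping: counts consistent, no entity listed twice
  expect_false(anyDuplicated(removed_s) > 0)
  cnt <- qc$report$counts
  expect_equal(cnt$samples[1] - length(removed_s), cnt$samples[5])
  expect_equal(cnt$variants[1] - length(removed_v), cnt$variants[5])
})
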