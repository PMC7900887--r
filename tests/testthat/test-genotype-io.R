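test_that("VCF round trip reproduces additive coding, including missing calls", {
  calls <- rbind(c(0L, 2L), c(1L, NA), c(2L, 0L))
  m <- tiny_gm(calls, allele_a = c("A", "C"), allele_b = c("G", "T"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(m, path)
  m2 <- read_vcf(path)
  expect_identical(m2$calls, m$calls)
  expect_identical(m2$variants$allele_b, m$variants$allele_b)
})

test_that("VCF GT values map to ALT-allele counts and ./. to missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "I1", "I2", "I3", "I4", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1|1", "0|0", "0/1", "1/0", sep = "\t")), path)
  m <- read_vcf(path)
  expect_equal(unname(m$calls[, "rs1"]), c(0L, 1L, 2L, NA))
  expect_equal(unname(m$calls[, "rs2"]), c(2L, 0L, 1L, 1L))
})

test_that("multiallelic, indel and sex-chromosome records are dropped with counts", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "I1", sep = "\t"),
    paste("1", "100", "rs1", "A", "G,T", ".", ".", ".", "GT", "0/1", sep = "\t"),
    paste("1", "200", "rs2", "AT", "A", ".", ".", ".", "GT", "0/1", sep = "\t"),
    paste("X", "300", "rs3", "A", "G", ".", ".", ".", "GT", "0/1", sep = "\t"),
    paste("2", "400", "rs4", "A", "G", ".", ".", ".", "GT", "0/1", sep = "\t")), path)
  expect_message(m <- read_vcf(path), "dropped 3")
  expect_equal(n_variants(m), 1L)
  expect_equal(unname(attr(m, "dropped")),
               c(1L, 1L, 1L))
})

test_that("duplicate variant ids in a VCF raise an error naming the id", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "I1", sep = "\t"),
    paste("1", "100", "rsX", "A", "G", ".", ".", ".", "GT", "0/1", sep = "\t"),
    paste("1", "200", "rsX", "C", "T", ".", ".", ".", "GT", "0/1", sep = "\t")), path)
  expect_error(read_vcf(path), "rsX")
})

test_that("PED coding counts the file-minor allele and 0 0 is missing", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  # at v1 allele A appears 3 times, G 5 times -> minor = A; "A A" counts 2
  writeLines(c("F1 S1 0 0 0 -9 A A G G",
               "F2 S2 0 0 0 -9 A G 0 0",
               "F3 S3 0 0 0 -9 G G G T",
               "F4 S4 0 0 0 -9 G G T T"), ped)
  writeLines(c("1\tv1\t0\t100", "1\tv2\t0\t200"), map)
  m <- read_plink_text(ped, map)
  expect_equal(m$variants$allele_b, c("A", "T"))
  expect_equal(unname(m$calls[, "v1"]), c(2L, 1L, 0L, 0L))
  expect_equal(unname(m$calls[, "v2"]), c(0L, NA, 1L, 2L))
})

test_that("PED/MAP round trip reproduces calls when allele_b is the minor allele", {
  set.seed(11)
  calls <- matrix(rbinom(5 * 10, 2, 0.25), 5, 10)  # allele_b minor in expectation
  calls[calls == 2 & col(calls) == 1] <- 1          # guard column 1
  m <- tiny_gm(calls)
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_plink_text(m, ped, map)
  m2 <- read_plink_text(ped, map)
  # orientation-free comparison: calls equal or flipped per variant
  same <- vapply(seq_len(10), function(l)
    all(m2$calls[, l] == m$calls[, l]) || all(m2$calls[, l] == 2L - m$calls[, l]),
    logical(1))
  expect_true(all(same))
  # where minor-allele orientation is preserved, calls are identical
  minor <- colMeans(m$calls) / 2 < 0.5
  expect_identical(m2$calls[, minor], m$calls[, minor])
})

test_that("column-count mismatch between PED and MAP errors", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("F1 S1 0 0 0 -9 A A", ped)
  writeLines(c("1\tv1\t0\t100", "1\tv2\t0\t200"), map)
  expect_error(read_plink_text(ped, map), "columns")
})

test_that("strand-ambiguous filtering removes exactly {A,T}/{C,G} pairs and is idempotent", {
  m <- tiny_gm(matrix(0L, 2, 3),
               allele_a = c("A", "C", "A"), allele_b = c("T", "G", "G"))
  f <- drop_strand_ambiguous(m)
  expect_equal(f$variants$variant_id, "v003")
  expect_equal(attr(f, "n_dropped"), 2L)
  # identity on unambiguous input, and idempotence
  f2 <- drop_strand_ambiguous(f)
  expect_identical(f2$calls, f$calls)
  expect_equal(attr(f2, "n_dropped"), 0L)

  set.seed(3)
  pairs <- rbind(matrix(rep(c("A", "G"), 80), 80, 2, byrow = TRUE),
                 matrix(rep(c("C", "G"), 20), 20, 2, byrow = TRUE))
  shuf <- sample(100)
  m100 <- tiny_gm(matrix(0L, 2, 100), allele_a = pairs[shuf, 1],
                  allele_b = pairs[shuf, 2])
  expect_equal(n_variants(drop_strand_ambiguous(m100)), 80L)
})

test_that("panel merge harmonizes allele orientation and preserves panel frequencies", {
  set.seed(5)
  n <- 30; nv <- 50
  f <- runif(nv, 0.2, 0.8)
  cohort <- tiny_gm(matrix(rbinom(n * nv, 2, rep(f, each = n)), n, nv))
  # panel with the same variants but swapped allele labels at half of them
  pc <- matrix(rbinom(20 * nv, 2, rep(f, each = 20)), 20, nv)
  swap <- seq_len(nv) %% 2 == 0
  pv <- cohort$variants
  pv$allele_a[swap] <- "G"; pv$allele_b[swap] <- "A"
  pcalls <- pc
  pcalls[, swap] <- 2L - pcalls[, swap]   # panel codes the other allele
  pg <- genotype_matrix(pcalls, pv, sprintf("P%02d", 1:20))
  panel <- reference_panel(pg, rep(c("AFR_SIM", "EUR_SIM"), each = 10),
                           rep(c("AFR", "EUR"), each = 10))
  mg <- merge_with_panel(cohort, panel)
  expect_equal(n_samples(mg$genotypes), 50)
  expect_equal(n_variants(mg$genotypes), nv)
  # after harmonization the panel samples' calls equal the pre-swap draws
  merged_panel <- mg$genotypes$calls[31:50, , drop = FALSE]
  expect_equal(unname(colMeans(merged_panel)), unname(colMeans(pc)))
})

test_that("panel populations can be excluded and disjoint variant sets error", {
  run <- medium_cohort()
  cfg_asw <- sim_config(n_samples = 10, n_snps = 100, n_aims = 20, n_chrom = 2,
                        panel_afr = 10, panel_eur = 10, panel_asw = 5, seed = 9)
  co <- simulate_cohort(cfg_asw)
  pan <- simulate_reference_panel(cfg_asw)
  expect_true("ASW" %in% pan$population)
  mg <- merge_with_panel(co$genotypes, pan, exclude_populations = "ASW")
  expect_false(any(mg$labels$population %in% "ASW"))

  other <- tiny_gm(matrix(0L, 2, 3), chrom = rep("21", 3), pos = c(5L, 15L, 25L))
  panel2 <- reference_panel(other, c("AFR_SIM", "EUR_SIM"), c("AFR", "EUR"))
  expect_error(merge_with_panel(run$co$genotypes, panel2), "no shared variants")
})
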