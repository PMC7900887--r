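#' Read a VCF into a genotype matrix
#'
#' Parses GT fields of a VCF 4.x file (plain or gzipped) into additive
#' coding: the call counts copies of the ALT allele, so `allele_b` is ALT.
#' Only biallelic autosomal SNP records are kept; multiallelic records,
#' indels, non-ACGT alleles and sex/mitochondrial chromosomes are dropped
#' and the drop counts are reported via `attr(, "dropped")` and a message.
#' `./.` (and `.`) genotypes map to missing.
#'
#' @param path path to a VCF file.
#' @return a `genotype_matrix` with attribute `dropped`, a named integer
#'   vector of counts of records removed per reason.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  snp[multi] <- FALSE
  auto <- !toupper(sub("^chr", "", fix$CHROM)) %in% c("X", "Y", "MT", "M", "XY")
  keep <- !multi & snp & auto
  dropped <- c(multiallelic = sum(multi),
               non_snp = sum(!snp & !multi),
               non_autosomal = sum(snp & !multi & !auto))
  if (any(dropped > 0L))
    message("read_vcf: dropped ", sum(dropped), " record(s) [",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), "]")
  if (!any(keep)) stop("no biallelic autosomal SNP records in ", path)

  ids_all <- fix$ID
  anon <- is.na(ids_all) | ids_all == "."
  ids_all[anon] <- paste0(fix$CHROM[anon], ":", fix$POS[anon], ":",
                          fix$REF[anon], ":", fix$ALT[anon])
  dup <- ids_all[keep][duplicated(ids_all[keep])]
  if (length(dup) > 0L) stop("duplicate variant_id in VCF: ", dup[1L])
  vcf@fix[, "ID"] <- make.unique(ids_all)   # keep extract.gt happy on drops

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ids_all[keep]

  code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  gt_chr <- sub(":.*$", "", as.character(gt))     # tolerate GT:extra
  calls <- code[gt_chr]
  missing_gt <- gt_chr %in% c("./.", ".|.", ".") | is.na(gt_chr)
  malformed <- is.na(calls) & !missing_gt
  if (any(malformed))
    stop("malformed GT value in VCF: '", gt_chr[malformed][1L], "'")
  calls <- matrix(calls, nrow = nrow(gt), ncol = ncol(gt))

  variants <- data.frame(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         allele_a = fix$REF, allele_b = fix$ALT,
                         stringsAsFactors = FALSE)
  m <- genotype_matrix(t(calls), variants, colnames(gt))
  attr(m, "dropped") <- dropped
  m
}

#' Write a genotype matrix as an uncompressed VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype fields; `allele_a` is
#' written as REF and `allele_b` as ALT, so reading the file back
#' reproduces the calls exactly.
#'
#' @param m a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", m$sample_ids), collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (l in seq_len(n_variants(m))) {
    g <- m$calls[, l]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    v <- m$variants[l, ]
    writeLines(paste(c(v$chrom, v$pos, v$variant_id, v$allele_a, v$allele_b,
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write PLINK text PED + MAP
#'
#' The PED dialect has six leading columns (family, individual, paternal,
#' maternal, sex, phenotype) followed by two allele columns per variant;
#' `0 0` marks a missing genotype. The MAP file carries chromosome, id,
#' genetic position (morgans) and physical position. On reading,
#' `allele_b` is the minor allele within the file (ties broken towards the
#' alphabetically later allele), so a write/read round trip reproduces
#' calls up to allele-label orientation.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return a `genotype_matrix`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "variant_id", "genetic_pos", "pos"))
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  nvar <- nrow(map)
  if (ncol(ped) != 6L + 2L * nvar)
    stop("PED has ", ncol(ped), " columns but MAP implies ", 6L + 2L * nvar)
  sample_ids <- ped[[2L]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(nvar) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(nvar), drop = FALSE])
  ok <- c("A", "C", "G", "T", "0")
  if (!all(a1 %in% ok) || !all(a2 %in% ok))
    stop("allele symbol outside {A,C,G,T,0} in PED")
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing)) stop("half-missing genotype ('0 X') in PED")

  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, nvar)
  allele_a <- allele_b <- character(nvar)
  for (l in seq_len(nvar)) {
    al <- c(a1[, l], a2[, l])
    al <- al[al != "0"]
    lev <- sort(unique(al), decreasing = TRUE)  # alphabetically later first
    if (length(lev) > 2L)
      stop("more than two alleles at ", map$variant_id[l])
    if (length(lev) == 0L) lev <- c("A", "C")   # all-missing column: arbitrary labels
    if (length(lev) == 1L) lev <- c(lev, setdiff(c("A", "C", "G", "T"), lev)[1L])
    counts <- c(sum(al == lev[1L]), sum(al == lev[2L]))
    b <- if (counts[1L] <= counts[2L]) lev[1L] else lev[2L]  # minor allele
    aa <- setdiff(lev, b)[1L]
    g <- (a1[, l] == b) + (a2[, l] == b)
    g[a1[, l] == "0"] <- NA_integer_
    calls[, l] <- as.integer(g)
    allele_a[l] <- aa
    allele_b[l] <- b
  }
  variants <- data.frame(variant_id = map$variant_id, chrom = as.character(map$chrom),
                         pos = as.integer(map$pos), allele_a = allele_a,
                         allele_b = allele_b, genetic_pos = as.numeric(map$genetic_pos),
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, sample_ids)
}

#' @rdname read_plink_text
#' @param m a `genotype_matrix`.
#' @export
write_plink_text <- function(m, ped_path, map_path) {
  v <- m$variants
  gp <- ifelse(is.na(v$genetic_pos), 0, v$genetic_pos)
  utils::write.table(data.frame(v$chrom, v$variant_id, gp, v$pos),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- n_samples(m)
  nvar <- n_variants(m)
  out <- matrix("0", n, 2L * nvar)
  for (l in seq_len(nvar)) {
    g <- m$calls[, l]
    a <- v$allele_a[l]; b <- v$allele_b[l]
    out[, 2L * l - 1L] <- ifelse(is.na(g), "0", ifelse(g >= 1L, b, a))
    out[, 2L * l] <- ifelse(is.na(g), "0", ifelse(g == 2L, b, a))
  }
  lead <- cbind(m$sample_ids, m$sample_ids, "0", "0", "0", "-9")
  utils::write.table(cbind(lead, out), ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}

#' Remove strand-ambiguous variants
#'
#' Drops variants whose allele pair is {A,T} or {C,G}: these cannot be
#' strand-aligned when merging genotype sets from different sources.
#' Idempotent; surviving variant order is preserved.
#'
#' @param m a `genotype_matrix`.
#' @return the filtered `genotype_matrix` with attribute `n_dropped`.
#' @export
drop_strand_ambiguous <- function(m) {
  pair <- paste(pmin(m$variants$allele_a, m$variants$allele_b),
                pmax(m$variants$allele_a, m$variants$allele_b))
  keep <- !(pair %in% c("A T", "C G"))
  out <- gm_subset(m, variants = keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Reference panel with population labels
#'
#' @param genotypes a `genotype_matrix` of panel samples.
#' @param population per-sample population label (e.g. "YRI", "CEU", "ASW").
#' @param superpopulation per-sample superpopulation, one of
#'   AFR/AMR/EAS/EUR/SAS.
#' @return an object of class `reference_panel`.
#' @export
reference_panel <- function(genotypes, population, superpopulation) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- n_samples(genotypes)
  if (length(population) != n || length(superpopulation) != n)
    stop("panel labels must match sample count")
  if (!all(superpopulation %in% c("AFR", "AMR", "EAS", "EUR", "SAS")))
    stop("unknown superpopulation label")
  if (!any(superpopulation == "AFR") || !any(superpopulation == "EUR"))
    stop("panel must contain AFR and EUR samples")
  structure(list(genotypes = genotypes,
                 population = as.character(population),
                 superpopulation = as.character(superpopulation)),
            class = "reference_panel")
}

#' @exportS3Method base::print
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", n_samples(x$genotypes), "samples,",
      n_variants(x$genotypes), "variants\n")
  print(table(x$superpopulation))
  invisible(x)
}

#' Merge a cohort with a labeled reference panel
#'
#' Intersects variants by (chrom, pos) after strand-ambiguous removal on
#' both sides, harmonizes the panel's allele orientation to the cohort's
#' `allele_b` (flipping panel calls g -> 2 - g where the allele labels are
#' swapped), drops shared positions whose allele sets disagree (with a
#' logged count), and stacks cohort and panel samples.
#'
#' @param cohort a `genotype_matrix`.
#' @param panel a `reference_panel`.
#' @param exclude_populations population labels to drop from the panel
#'   before merging (e.g. `"ASW"` to remove admixed African Americans).
#' @return list with `genotypes` (merged `genotype_matrix`), `labels`
#'   (data.frame sample_id, source, population, superpopulation) and
#'   `n_allele_mismatch` (count of shared positions dropped).
#' @export
merge_with_panel <- function(cohort, panel, exclude_populations = character()) {
  keep_s <- !(panel$population %in% exclude_populations)
  if (!any(keep_s)) stop("exclude_populations removes every panel sample")
  pg <- gm_subset(panel$genotypes, samples = keep_s)

  cohort <- drop_strand_ambiguous(cohort)
  pg <- drop_strand_ambiguous(pg)

  ckey <- paste(cohort$variants$chrom, cohort$variants$pos, sep = ":")
  pkey <- paste(pg$variants$chrom, pg$variants$pos, sep = ":")
  shared <- intersect(ckey, pkey)
  if (length(shared) == 0L) stop("no shared variants between cohort and panel")
  ci <- match(shared, ckey)
  pi <- match(shared, pkey)

  cv <- cohort$variants[ci, ]
  pv <- pg$variants[pi, ]
  same <- cv$allele_a == pv$allele_a & cv$allele_b == pv$allele_b
  swapped <- cv$allele_a == pv$allele_b & cv$allele_b == pv$allele_a
  ok <- same | swapped
  n_mismatch <- sum(!ok)
  if (n_mismatch > 0L)
    message("merge_with_panel: dropped ", n_mismatch,
            " shared position(s) with mismatched allele sets")
  if (!any(ok)) stop("no shared variants with compatible alleles")
  ci <- ci[ok]; pi <- pi[ok]; swapped <- swapped[ok]

  cc <- cohort$calls[, ci, drop = FALSE]
  pc <- pg$calls[, pi, drop = FALSE]
  if (any(swapped))
    pc[, swapped] <- 2L - pc[, swapped]

  clash <- intersect(cohort$sample_ids, pg$sample_ids)
  if (length(clash) > 0L) stop("sample id present in both cohort and panel: ", clash[1L])
  merged <- genotype_matrix(rbind(cc, pc), cohort$variants[ci, ],
                            c(cohort$sample_ids, pg$sample_ids))
  labels <- data.frame(
    sample_id = c(cohort$sample_ids, pg$sample_ids),
    source = rep(c("cohort", "panel"), c(n_samples(cohort), n_samples(pg))),
    population = c(rep(NA_character_, n_samples(cohort)), panel$population[keep_s]),
    superpopulation = c(rep(NA_character_, n_samples(cohort)),
                        panel$superpopulation[keep_s]),
    stringsAsFactors = FALSE)
  list(genotypes = merged, labels = labels, n_allele_mismatch = n_mismatch)
}
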