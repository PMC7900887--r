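#' Load the packaged glaucoma risk-variant table
#'
#' The packaged default is a 23-row table of previously published
#' POAG-associated SNPs (NHGRI-EBI GWAS catalog selection): rsID, risk
#' allele, whether it was directly genotyped, genomic coordinates,
#' reported gene(s), published odds ratio, and African / European
#' risk-allele frequencies. rsIDs with platform prefixes ("exm-", "seq-")
#' are kept verbatim; a normalized `rsid_norm` column (prefix stripped) is
#' added for matching.
#'
#' @param path optional path to an alternative TSV with the same header;
#'   default is the packaged resource.
#' @return validated data.frame of class `risk_table`.
#' @export
load_risk_table <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged)
    path <- system.file("extdata", "poag_risk_snps.tsv", package = "admixrisk",
                        mustWork = TRUE)
  tb <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer", chrom = "character"))
  req <- c("rsid", "risk_allele", "genotyped_directly", "chrom", "pos",
           "reported_genes", "odds_ratio", "freq_afr", "freq_eur")
  miss <- setdiff(req, names(tb))
  if (length(miss) > 0L) stop("risk table lacks column(s): ", paste(miss, collapse = ", "))
  if (packaged && nrow(tb) != 23L)
    stop("packaged risk table must have exactly 23 rows, found ", nrow(tb))
  if (anyDuplicated(tb$rsid)) stop("duplicate rsid in risk table: ",
                                   tb$rsid[duplicated(tb$rsid)][1L])
  stopifnot(all(tb$risk_allele %in% c("A", "C", "G", "T")),
            all(tb$odds_ratio > 0),
            all(tb$freq_afr >= 0 & tb$freq_afr <= 1),
            all(tb$freq_eur >= 0 & tb$freq_eur <= 1))
  tb$rsid_norm <- sub("^(exm-|seq-)", "", tb$rsid)
  if (anyDuplicated(tb$rsid_norm)) stop("duplicate normalized rsid in risk table")
  class(tb) <- c("risk_table", "data.frame")
  tb
}

#' Weighted polygenic risk score
#'
#' For each sample, the score is the sum over risk variants of the
#' risk-allele count times the variant's published odds ratio. Variants
#' are matched by rsID (verbatim or normalized) and then by chrom:pos;
#' when the matrix's counted allele (`allele_b`) is the non-risk allele,
#' counts are flipped (c -> 2 - c). Missing calls are imputed as twice the
#' cohort risk-allele frequency by default, or the variant can be skipped
#' for that sample.
#'
#' @param m a `genotype_matrix`.
#' @param table a `risk_table` (default: the packaged 23-SNP table).
#' @param cohort_freqs optional named vector of risk-allele frequencies
#'   (names = normalized rsIDs) used for imputation; computed from the
#'   matrix when absent.
#' @param missing `"impute"` (default) or `"skip"`.
#' @param log_weights if TRUE weight by ln(OR) instead of the odds ratio
#'   itself (the published construction uses the OR directly).
#' @return data.frame of class `prs_result` with `sample_id`, `score`,
#'   `n_snps_used`, `n_missing_imputed`.
#' @export
score_samples <- function(m, table = load_risk_table(), cohort_freqs = NULL,
                          missing = c("impute", "skip"), log_weights = FALSE) {
  missing <- match.arg(missing)
  stopifnot(inherits(m, "genotype_matrix"))
  v <- m$variants
  vkey <- paste(v$chrom, v$pos, sep = ":")
  n <- n_samples(m)
  score <- numeric(n)
  n_used <- 0L
  n_imputed <- integer(n)
  for (r in seq_len(nrow(table))) {
    j <- match(table$rsid[r], v$variant_id)
    if (is.na(j)) j <- match(table$rsid_norm[r], v$variant_id)
    if (is.na(j)) j <- match(paste(table$chrom[r], table$pos[r], sep = ":"), vkey)
    if (is.na(j)) {
      warning("risk SNP ", table$rsid[r], " absent from genotype matrix; excluded")
      next
    }
    risk <- table$risk_allele[r]
    if (v$allele_b[j] == risk) {
      cnt <- m$calls[, j]
    } else if (v$allele_a[j] == risk) {
      cnt <- 2L - m$calls[, j]
    } else {
      warning("risk allele ", risk, " not among alleles of ", table$rsid[r],
              "; excluded")
      next
    }
    w <- if (log_weights) log(table$odds_ratio[r]) else table$odds_ratio[r]
    miss_i <- is.na(cnt)
    cnt <- as.numeric(cnt)
    if (any(miss_i)) {
      if (missing == "impute") {
        f <- if (!is.null(cohort_freqs) && table$rsid_norm[r] %in% names(cohort_freqs))
          cohort_freqs[[table$rsid_norm[r]]]
        else mean(cnt[!miss_i]) / 2
        if (is.nan(f)) f <- 0
        cnt[miss_i] <- 2 * f
        n_imputed <- n_imputed + miss_i
      } else {
        cnt[miss_i] <- 0
      }
    }
    score <- score + w * cnt
    n_used <- n_used + 1L
  }
  out <- data.frame(sample_id = m$sample_ids, score = score,
                    n_snps_used = n_used, n_missing_imputed = n_imputed,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("prs_result", "data.frame")
  out
}
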