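#' Genotype matrix container
#'
#' The substrate of every pipeline stage: an integer matrix of additive
#' genotype calls (rows = samples, columns = variants) together with a
#' variant table and sample identifiers. Calls count copies of `allele_b`
#' and take values 0, 1, 2 or `NA` (missing). Variants are kept strictly
#' sorted by (chromosome, position).
#'
#' @param calls integer matrix, samples x variants, values in {0,1,2,NA}.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b` and optionally `genetic_pos` (morgans).
#' @param sample_ids character vector, one id per row of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, sample_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  sample_ids <- as.character(sample_ids)

  req <- c("variant_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L)
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"genetic_pos" %in% names(variants)) variants$genetic_pos <- NA_real_
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)

  if (nrow(calls) != length(sample_ids))
    stop("calls has ", nrow(calls), " rows but ", length(sample_ids), " sample ids")
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " columns but ", nrow(variants), " variants")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  dup <- variants$variant_id[duplicated(variants$variant_id)]
  if (length(dup) > 0L) stop("duplicate variant_id: ", dup[1L])

  bad <- calls[!is.na(calls)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must lie in {0, 1, 2, NA}")
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  ok_allele <- c("A", "C", "G", "T")
  if (!all(variants$allele_a %in% ok_allele) || !all(variants$allele_b %in% ok_allele))
    stop("alleles must be single nucleotides in {A,C,G,T}")
  if (any(variants$allele_a == variants$allele_b))
    stop("allele_a and allele_b must differ for every variant")

  ord <- variant_order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  dimnames(calls) <- list(sample_ids, variants$variant_id)

  structure(
    list(calls = calls, variants = variants, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

# numeric-aware (chrom, pos) ordering; "2" sorts before "10"
variant_order <- function(chrom, pos) {
  chrom_num <- suppressWarnings(as.numeric(chrom))
  order(is.na(chrom_num), chrom_num, chrom, pos)
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_variants(x), "variants\n")
  mr <- mean(is.na(x$calls))
  cat(sprintf("  chromosomes: %s\n  missing call fraction: %.4f\n",
              paste(unique(x$variants$chrom), collapse = ","), mr))
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param m a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(m) length(m$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(m) nrow(m$variants)

#' Subset a genotype matrix
#'
#' @param m a `genotype_matrix`.
#' @param samples sample ids, logical mask or integer indices (default: all).
#' @param variants variant ids, logical mask or integer indices (default: all).
#' @return the subset `genotype_matrix` (variant order preserved).
#' @export
gm_subset <- function(m, samples = NULL, variants = NULL) {
  si <- resolve_index(samples, m$sample_ids, "sample")
  vi <- resolve_index(variants, m$variants$variant_id, "variant")
  genotype_matrix(m$calls[si, vi, drop = FALSE],
                  m$variants[vi, , drop = FALSE],
                  m$sample_ids[si])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.logical(idx)) {
    if (length(idx) != length(ids)) stop("logical ", what, " mask has wrong length")
    return(which(idx))
  }
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ", what, " id: ", idx[is.na(pos)][1L])
    return(pos)
  }
  as.integer(idx)
}

#' Per-variant allele frequency of allele_b
#' @param m a `genotype_matrix`.
#' @return numeric vector (NaN for variants with no calls).
#' @export
allele_freq <- function(m) colMeans(m$calls, na.rm = TRUE) / 2

#' Per-variant minor allele frequency
#' @param m a `genotype_matrix`.
#' @return numeric vector in [0, 0.5].
#' @export
minor_allele_freq <- function(m) {
  f <- allele_freq(m)
  pmin(f, 1 - f)
}

#' Per-sample and per-variant missing-call fractions
#' @param m a `genotype_matrix`.
#' @return numeric vector of missing fractions.
#' @export
sample_missing_rate <- function(m) rowMeans(is.na(m$calls))

#' @rdname sample_missing_rate
#' @export
variant_missing_rate <- function(m) colMeans(is.na(m$calls))

#' Sample metadata records
#'
#' Validates a phenotype/covariate table: one row per sample with case
#' status, age, sex, cohort, and the four optional glaucoma endophenotypes
#' (intraocular pressure, central corneal thickness, cup-to-disc ratio,
#' retinal nerve fiber layer thickness).
#'
#' @param df data.frame with columns sample_id, status, age, sex, cohort and
#'   optionally iop, cct, cdr, rnfl. Empty/NA entries mark absent values.
#' @return validated data.frame of class `sample_records`.
#' @export
sample_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "status", "age", "sex", "cohort")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("sample records lack column(s): ", paste(miss, collapse = ", "))
  for (col in c("iop", "cct", "cdr", "rnfl"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in records")
  if (!all(df$status %in% c("case", "control", "suspect")))
    stop("status must be case/control/suspect")
  if (!all(df$sex %in% c("male", "female"))) stop("sex must be male/female")
  if (!all(df$cohort %in% c("discovery", "replication")))
    stop("cohort must be discovery/replication")
  if (any(df$age < 0, na.rm = TRUE)) stop("negative age")
  if (any(df$cdr < 0 | df$cdr > 1, na.rm = TRUE)) stop("cdr outside [0,1]")
  df <- df[, c(req, "iop", "cct", "cdr", "rnfl")]
  class(df) <- c("sample_records", "data.frame")
  df
}

#' Read / write sample metadata TSV
#'
#' Tab-separated with header
#' `sample_id status age sex cohort iop cct cdr rnfl`; empty fields are
#' absent values.
#'
#' @param path file path.
#' @return `read_sample_records`: a `sample_records` data.frame.
#' @export
read_sample_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  sample_records(df)
}

#' @rdname read_sample_records
#' @param records a `sample_records` data.frame.
#' @export
write_sample_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
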