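#' Local African ancestry posteriors at AIMs (diploid HMM)
#'
#' Per chromosome, a diploid hidden Markov model formed as the product of
#' two independent haploid chains with states {AFR, EUR}: stationary
#' probabilities (q_afr, 1 - q_afr) per sample, and between adjacent AIMs
#' at genetic distance d the haploid chain keeps its state with
#' probability exp(-lambda d), otherwise redraws from the stationary
#' distribution. Emission of an unphased genotype given the diploid
#' ancestry state is the convolution of two Bernoulli allele draws with
#' success probability f_afr or f_eur per haplotype; missing genotypes
#' emit likelihood 1. Forward-backward posteriors over the three diploid
#' states (0/1/2 African copies) are collapsed to the expected number of
#' African-derived alleles d_il in [0, 2].
#'
#' All samples are processed simultaneously (the marker loop is the only
#' loop), so the cost is linear in markers.
#'
#' @param m_aims `genotype_matrix` restricted to the AIM panel.
#' @param aim_panel data.frame with `variant_id`, `chrom`, `genetic_pos`
#'   (strictly increasing within chromosome), `freq_afr`, `freq_eur`.
#' @param q_afr named per-sample global African ancestry proportions,
#'   clamped to [0.01, 0.99].
#' @param lambda admixture age in generations (default 8).
#' @return list of class `local_ancestry`: `expected_afr` (n x M matrix
#'   d_il), `genome_average` (named vector, mean(d)/2),
#'   `log_likelihood_forward` and `log_likelihood_backward` (per-sample),
#'   `state_posterior_check` (max |1 - sum of state posteriors|).
#' @export
local_ancestry_posteriors <- function(m_aims, aim_panel, q_afr, lambda = 8) {
  stopifnot(inherits(m_aims, "genotype_matrix"))
  ord <- match(m_aims$variants$variant_id, aim_panel$variant_id)
  if (anyNA(ord)) stop("AIM panel lacks frequencies for some variants")
  panel <- aim_panel[ord, ]
  if (nrow(panel) == 0) stop("empty AIM panel")
  if (anyNA(panel$genetic_pos)) stop("AIMs need genetic positions")
  ids <- m_aims$sample_ids
  if (!all(ids %in% names(q_afr))) stop("q_afr lacks values for some samples")
  qa <- pmin(pmax(q_afr[ids], 0.01), 0.99)
  n <- length(ids)
  M <- nrow(panel)

  # stationary diploid prior per sample: P(j African copies)
  prior <- cbind((1 - qa)^2, 2 * qa * (1 - qa), qa^2)

  # emission lookup per marker: rows g = 0,1,2; cols j = 0,1,2 copies
  emis_tab <- function(fa, fe) {
    cbind(`0` = c((1 - fe)^2, (1 - fa) * (1 - fe), (1 - fa)^2),
          `1` = c(2 * fe * (1 - fe), fa * (1 - fe) + (1 - fa) * fe,
                  2 * fa * (1 - fa)),
          `2` = c(fe^2, fa * fe, fa^2))
  }

  d_exp <- matrix(NA_real_, n, M, dimnames = list(ids, panel$variant_id))
  ll_f <- stats::setNames(numeric(n), ids)
  ll_b <- stats::setNames(numeric(n), ids)
  max_dev <- 0

  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    gp <- panel$genetic_pos[idx]
    if (any(diff(gp) <= 0)) stop("genetic positions not strictly increasing on chrom ", ch)
    L <- length(idx)
    g <- m_aims$calls[, idx, drop = FALSE]

    # per-marker n x 3 emission matrices (missing -> 1)
    emis <- vector("list", L)
    for (l in seq_len(L)) {
      et <- emis_tab(panel$freq_afr[idx[l]], panel$freq_eur[idx[l]])
      e <- matrix(1, n, 3)
      gi <- g[, l]
      ok <- !is.na(gi)
      e[ok, ] <- t(et[, gi[ok] + 1L, drop = FALSE])
      emis[[l]] <- e
    }

    # haploid transition entries per interval, vectorized over samples
    trans <- function(s) {
      tAA <- s + (1 - s) * qa; tAE <- (1 - s) * (1 - qa)
      tEA <- (1 - s) * qa;     tEE <- s + (1 - s) * (1 - qa)
      # diploid 3x3 as nine n-vectors, [from j][to k], j,k in 0..2 copies
      list(
        t00 = tEE^2,        t01 = 2 * tEA * tEE,            t02 = tEA^2,
        t10 = tAE * tEE,    t11 = tAA * tEE + tAE * tEA,    t12 = tAA * tEA,
        t20 = tAE^2,        t21 = 2 * tAA * tAE,            t22 = tAA^2)
    }
    s_int <- exp(-lambda * diff(gp))

    # forward with per-step scaling
    alpha <- prior * emis[[1]]
    sc <- rowSums(alpha)
    alpha <- alpha / sc
    logc <- log(sc)
    alphas <- vector("list", L)
    alphas[[1]] <- alpha
    for (l in seq_len(L - 1)) {
      tr <- trans(s_int[l])
      a0 <- alpha[, 1] * tr$t00 + alpha[, 2] * tr$t10 + alpha[, 3] * tr$t20
      a1 <- alpha[, 1] * tr$t01 + alpha[, 2] * tr$t11 + alpha[, 3] * tr$t21
      a2 <- alpha[, 1] * tr$t02 + alpha[, 2] * tr$t12 + alpha[, 3] * tr$t22
      alpha <- cbind(a0, a1, a2) * emis[[l + 1]]
      sc <- rowSums(alpha)
      alpha <- alpha / sc
      logc <- logc + log(sc)
      alphas[[l + 1]] <- alpha
    }
    ll_f <- ll_f + logc

    # backward, same scaling structure
    beta <- matrix(1, n, 3)
    logd <- numeric(n)
    for (l in seq(L - 1, 1, length.out = max(L - 1, 0))) {
      tr <- trans(s_int[l])
      eb <- emis[[l + 1]] * beta
      b0 <- eb[, 1] * tr$t00 + eb[, 2] * tr$t01 + eb[, 3] * tr$t02
      b1 <- eb[, 1] * tr$t10 + eb[, 2] * tr$t11 + eb[, 3] * tr$t12
      b2 <- eb[, 1] * tr$t20 + eb[, 2] * tr$t21 + eb[, 3] * tr$t22
      beta <- cbind(b0, b1, b2)
      sc <- rowSums(beta)
      beta <- beta / sc
      logd <- logd + log(sc)
      gamma <- alphas[[l]] * beta
      gamma <- gamma / rowSums(gamma)
      d_exp[, idx[l]] <- gamma[, 2] + 2 * gamma[, 3]
      max_dev <- max(max_dev, abs(rowSums(gamma) - 1))
    }
    # last marker: beta = 1 there
    gammaL <- alphas[[L]]
    d_exp[, idx[L]] <- gammaL[, 2] + 2 * gammaL[, 3]
    # backward log-likelihood: sum_j prior_j e_1(j) beta_1(j)
    ll_b <- ll_b + log(rowSums(prior * emis[[1]] * beta)) + logd
  }

  structure(list(expected_afr = d_exp,
                 genome_average = rowMeans(d_exp) / 2,
                 log_likelihood_forward = ll_f,
                 log_likelihood_backward = ll_b,
                 state_posterior_check = max_dev),
            class = "local_ancestry")
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tested markers.
#' @param alpha family-wise error rate, default 0.05.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Admixture-mapping scan for case-control ancestry skew
#'
#' At each AIM, logistic regression of case status on the expected local
#' African allele count, adjusted for age, sex and (by default) global
#' African ancestry; the global adjustment keeps the genome-wide ancestry
#' effect from masquerading as local signal at every marker. Two-sided
#' Wald p-values; the family-wise threshold is Bonferroni 0.05/M.
#' Markers with separation or a failed fit are reported with p = 1 and
#' flagged.
#'
#' @param posteriors a `local_ancestry` object.
#' @param records `sample_records` with case/control status and
#'   non-missing age and sex (suspects are excluded).
#' @param global_q named per-sample global African ancestry proportions.
#' @param adjust_global include the global-ancestry covariate (default
#'   TRUE).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return data.frame of class `scan_result`: per AIM beta, se, p,
#'   `flagged`, `significant`; `attr(,"bonferroni_threshold")`.
#' @export
ancestry_scan <- function(posteriors, records, global_q, adjust_global = TRUE,
                          alpha = 0.05) {
  stopifnot(inherits(posteriors, "local_ancestry"))
  d <- posteriors$expected_afr
  use <- records$status %in% c("case", "control") & !is.na(records$age)
  rec <- records[use, , drop = FALSE]
  if (!any(rec$status == "case") || !any(rec$status == "control"))
    stop("scan needs both cases and controls")
  rows <- match(rec$sample_id, rownames(d))
  if (anyNA(rows)) stop("posteriors missing for some samples")
  d <- d[rows, , drop = FALSE]
  y <- as.integer(rec$status == "case")
  X0 <- cbind(1, age = rec$age, male = as.integer(rec$sex == "male"))
  if (adjust_global) {
    gq <- global_q[rec$sample_id]
    if (anyNA(gq)) stop("global_q missing for some samples")
    X0 <- cbind(X0, global_q = gq)
  }
  M <- ncol(d)
  beta <- se <- p <- rep(NA_real_, M)
  flagged <- logical(M)
  for (l in seq_len(M)) {
    X <- cbind(X0, local = d[, l])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
      error = function(e) NULL)
    bad <- is.null(fit) || !fit$converged ||
      any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
    if (!bad) {
      cf <- fit$coefficients
      # Wald from the IRLS weighted cross-product
      W <- fit$weights
      XtWX <- crossprod(X * sqrt(W))
      cov <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (is.null(cov) || anyNA(cf)) bad <- TRUE
      else {
        k <- ncol(X)
        beta[l] <- cf[k]
        se[l] <- sqrt(cov[k, k])
        p[l] <- 2 * stats::pnorm(-abs(beta[l] / se[l]))
      }
    }
    if (bad) { p[l] <- 1; flagged[l] <- TRUE }
  }
  thr <- bonferroni_threshold(M, alpha)
  out <- data.frame(variant_id = colnames(d), beta = beta, se = se, p = p,
                    flagged = flagged, significant = p < thr,
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni_threshold") <- thr
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Plot-ready Manhattan table for a scan
#'
#' @param scan a `scan_result`.
#' @param variants variant table carrying `variant_id`, `chrom`, `pos`.
#' @return data.frame chrom, pos, variant_id, neglog10p, significant,
#'   ordered by (chrom, pos).
#' @export
manhattan_table <- function(scan, variants) {
  i <- match(scan$variant_id, variants$variant_id)
  if (anyNA(i)) stop("variant table lacks some scanned AIMs")
  tb <- data.frame(chrom = variants$chrom[i], pos = variants$pos[i],
                   variant_id = scan$variant_id,
                   neglog10p = -log10(scan$p),
                   significant = scan$significant, stringsAsFactors = FALSE)
  tb[variant_order(tb$chrom, tb$pos), , drop = FALSE]
}
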