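#' LD pruning by pairwise genotype correlation
#'
#' Sliding window of `window` variants advancing by `step`. Within each
#' window, while any pair of surviving variants has squared Pearson
#' correlation of genotype vectors above `r2_max`, the member of the worst
#' pair with the lower minor allele frequency is removed (ties towards the
#' later position). Monomorphic variants have undefined correlation and
#' are treated as r2 = 0.
#'
#' @param m a `genotype_matrix` with at least 2 variants.
#' @param r2_max squared-correlation ceiling, default 0.2.
#' @param window,step window size and advance, in variants.
#' @return character vector of surviving variant ids (original order).
#' @export
ld_prune <- function(m, r2_max = 0.2, window = 50, step = 5) {
  nv <- n_variants(m)
  if (nv < 2) stop("ld_prune needs >= 2 variants")
  maf <- minor_allele_freq(m)
  maf[is.nan(maf)] <- 0
  keep <- rep(TRUE, nv)
  cor_use <- if (anyNA(m$calls)) "pairwise.complete.obs" else "everything"
  starts <- seq(1, max(1, nv - 1), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1, nv)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(m$calls[, idx, drop = FALSE],
                                      use = cor_use))
    cc[is.na(cc)] <- 0
    r2 <- cc^2
    diag(r2) <- 0
    while (max(r2) > r2_max) {
      w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      i <- idx[w[1]]; j <- idx[w[2]]
      drop_var <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
      keep[drop_var] <- FALSE
      k <- which(idx == drop_var)
      r2[k, ] <- 0; r2[, k] <- 0
    }
  }
  m$variants$variant_id[keep]
}

#' Genetic relationship matrix
#'
#' Entry (i, j) is the average over variants, non-missing for both
#' samples, of (g_i - 2p)(g_j - 2p) / (2p(1-p)) with p the allele
#' frequency computed across all samples in the matrix. Variants that are
#' monomorphic (or entirely missing) are excluded with a message.
#'
#' @param m a `genotype_matrix` (typically LD pruned).
#' @return symmetric n x n matrix with sample ids as dimnames.
#' @export
grm <- function(m) {
  p <- allele_freq(m)
  usable <- !is.nan(p) & p > 0 & p < 1
  if (!all(usable))
    message("grm: excluding ", sum(!usable), " monomorphic/all-missing variant(s)")
  if (!any(usable)) stop("no polymorphic variants for GRM")
  calls <- m$calls[, usable, drop = FALSE]
  p <- p[usable]
  z <- sweep(calls, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  miss <- is.na(z)
  z[miss] <- 0
  num <- tcrossprod(z)
  cnt <- tcrossprod((!miss) * 1)
  if (any(cnt == 0)) stop("a sample pair shares no non-missing variants")
  g <- num / cnt
  dimnames(g) <- list(m$sample_ids, m$sample_ids)
  g
}

#' Principal components of a genetic relationship matrix
#'
#' Top-k eigenvectors, each scaled by the square root of its eigenvalue.
#' Sign convention: when AFR-labeled panel samples are supplied, each
#' component is oriented so their mean coordinate is negative, placing
#' African ancestry at low values (the convention under which cases sit
#' lower on PC1 than controls); otherwise the first sample's coordinate is
#' made non-negative.
#'
#' @param g symmetric relationship matrix from [grm()].
#' @param k number of components.
#' @param afr_ids sample ids of AFR reference-panel samples, used only for
#'   the deterministic sign convention.
#' @return list with `coords` (n x k matrix, columns PC1..PCk) and
#'   `eigenvalues` (length k, non-increasing).
#' @export
grm_pca <- function(g, k = 10, afr_ids = NULL) {
  stopifnot(is.matrix(g), nrow(g) == ncol(g))
  if (max(abs(g - t(g))) > 1e-8) stop("relationship matrix is not symmetric")
  e <- eigen(g, symmetric = TRUE)
  pos <- sum(e$values > 1e-10)
  if (k > pos) {
    warning("k = ", k, " exceeds matrix rank ", pos, "; truncated")
    k <- pos
  }
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  val <- e$values[seq_len(k)]
  coords <- sweep(vec, 2, sqrt(val), "*")
  rownames(coords) <- rownames(g)
  for (j in seq_len(k)) {
    s <- if (!is.null(afr_ids) && length(afr_ids) > 0) {
      afr <- intersect(afr_ids, rownames(g))
      if (length(afr) == 0) stop("none of afr_ids found in the matrix")
      -sign(mean(coords[afr, j]))
    } else {
      s0 <- sign(coords[1, j]); if (s0 == 0) 1 else s0
    }
    if (s < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, eigenvalues = val)
}

# one EM pass; returns updated parameters and the log-likelihood of the
# *incoming* parameters. The compiled step is used for fitting; this pure
# R version is retained as the reference implementation and cross-checked
# against the compiled one in the test suite.
admix_em_step_r <- function(Gm, Hm, q, f1, f2) {
  theta <- outer(q, f1 - f2) + rep(f2, each = length(q))
  ll <- sum(Gm * log(theta) + Hm * log1p(-theta))
  P1 <- outer(q, f1) / theta
  Q1 <- outer(q, 1 - f1) / (1 - theta)
  A1 <- Gm * P1; B1 <- Hm * Q1
  A2 <- Gm - A1; B2 <- Hm - B1
  ra1 <- rowSums(A1); rb1 <- rowSums(B1)
  q_new <- (ra1 + rb1) / (ra1 + rb1 + rowSums(A2) + rowSums(B2))
  q_new[!is.finite(q_new)] <- 0.5   # sample with no usable calls
  c1 <- colSums(A1); c2 <- colSums(B1)
  c3 <- colSums(A2); c4 <- colSums(B2)
  eps <- 1e-6
  f1_new <- pmin(pmax(c1 / (c1 + c2), eps), 1 - eps)
  f2_new <- pmin(pmax(c3 / (c3 + c4), eps), 1 - eps)
  q_new <- pmin(pmax(q_new, 0), 1)
  list(q = q_new, f1 = f1_new, f2 = f2_new, ll = ll)
}

#' Unsupervised two-way admixture estimation by EM
#'
#' Maximizes the binomial genotype log-likelihood
#' sum_il [ g_il log(theta_il) + (2 - g_il) log(1 - theta_il) ] with
#' theta_il = q_i f_1l + (1 - q_i) f_2l over per-sample proportions q and
#' two ancestral allele-frequency vectors, using the standard EM block
#' updates (posterior attribution of each allele copy to a population,
#' then closed-form refresh of q and f). Missing calls contribute
#' nothing. Multiple seeded initializations are run for a short burn-in
#' and the best is continued to convergence (log-likelihood gain below
#' `tol`, with a parameter-stall guard). Frequencies are clamped to
#' [1e-6, 1 - 1e-6].
#'
#' The two components are arbitrary until [orient_q0()] fixes their
#' labels against PC1.
#'
#' @param m cohort-only `genotype_matrix` (QC'd and LD pruned).
#' @param seed integer seed for the initializations.
#' @param tol absolute log-likelihood gain at which to stop.
#' @param max_iter iteration cap; hitting it flags non-convergence.
#' @param restarts number of random initializations.
#' @param burn_iter burn-in iterations per restart before the best is
#'   selected.
#' @return list of class `admixture_fit`: `estimates` (data.frame
#'   sample_id, q0, q1), `ancestral_freq` (2 x variants), `log_likelihood`,
#'   `n_iterations`, `converged`, `ll_trace`.
#' @export
fit_admixture_k2 <- function(m, seed = 777, tol = 1e-6, max_iter = 2000,
                             restarts = 5, burn_iter = 25) {
  stopifnot(inherits(m, "genotype_matrix"))
  calls <- m$calls
  em_step <- function(q, f1, f2) .admix_em_step_cpp(calls, q, f1, f2)
  n <- nrow(calls)
  phat <- colMeans(calls, na.rm = TRUE) / 2
  phat[is.nan(phat)] <- 0.5
  eps <- 1e-6

  set.seed(seed)
  starts <- lapply(seq_len(restarts), function(r) {
    delta <- stats::runif(ncol(calls), 0.05, 0.3)
    list(q = stats::runif(n, 0.1, 0.9),
         f1 = pmin(pmax(phat + delta / 2, eps), 1 - eps),
         f2 = pmin(pmax(phat - delta / 2, eps), 1 - eps))
  })
  burn <- lapply(starts, function(st) {
    for (it in seq_len(burn_iter)) {
      st2 <- em_step(st$q, st$f1, st$f2)
      st <- list(q = st2$q, f1 = st2$f1, f2 = st2$f2, ll = st2$ll)
    }
    st
  })
  best <- burn[[which.max(vapply(burn, `[[`, numeric(1), "ll"))]]

  # SQUAREM-accelerated EM cycles (Varadhan & Roland steplength SqS3),
  # with a monotonicity safeguard: an extrapolated point is accepted only
  # when its likelihood is no worse than the plain double EM step, so the
  # per-cycle log-likelihood trace is non-decreasing.
  nq <- length(best$q)
  pack <- function(st) c(st$q, st$f1, st$f2)
  clampv <- function(x) {
    q <- pmin(pmax(x[seq_len(nq)], 0), 1)
    f <- pmin(pmax(x[-seq_len(nq)], eps), 1 - eps)
    c(q, f)
  }
  unpack <- function(x) {
    nf <- (length(x) - nq) / 2
    list(q = x[seq_len(nq)], f1 = x[nq + seq_len(nf)],
         f2 = x[nq + nf + seq_len(nf)])
  }
  step_at <- function(x) {
    p <- unpack(x)
    em_step(p$q, p$f1, p$f2)
  }
  x0 <- pack(best)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  step_max <- 4   # adaptive steplength bound (grows on boundary hits)
  while (it < max_iter) {
    s1 <- step_at(x0); x1 <- pack(s1); it <- it + 1L
    ll_trace <- c(ll_trace, s1$ll)
    if (is.finite(ll_prev) && (s1$ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- s1$ll
    if (it >= max_iter) break
    s2 <- step_at(x1); x2 <- pack(s2); it <- it + 1L
    r <- x1 - x0
    v <- (x2 - x1) - r
    alpha <- -sqrt(sum(r^2)) / sqrt(sum(v^2))
    if (!is.finite(alpha)) { x0 <- x2; next }
    at_bound <- alpha < -step_max
    alpha <- max(min(alpha, -1), -step_max)
    xe <- clampv(x0 - 2 * alpha * r + alpha^2 * v)
    if (it >= max_iter) { x0 <- x2; break }
    s3 <- step_at(xe); it <- it + 1L
    if (s3$ll >= s2$ll) {
      x0 <- pack(s3)
      if (at_bound) step_max <- step_max * 4
    } else {
      x0 <- x2
      step_max <- max(4, step_max / 4)
    }
  }
  if (!converged)
    warning("admixture EM did not converge in ", max_iter, " iterations")
  pf <- unpack(x0)
  q <- pf$q; f1 <- pf$f1; f2 <- pf$f2
  final <- em_step(q, f1, f2)  # ll at the returned parameters

  estimates <- data.frame(sample_id = m$sample_ids, q0 = q, q1 = 1 - q,
                          stringsAsFactors = FALSE)
  freq <- rbind(q0 = f1, q1 = f2)
  colnames(freq) <- m$variants$variant_id
  structure(list(estimates = estimates, ancestral_freq = freq,
                 log_likelihood = final$ll, n_iterations = it,
                 converged = converged, ll_trace = ll_trace),
            class = "admixture_fit")
}

#' Orient the admixture components against PC1
#'
#' Relabels the two components (q0 <-> q1, with the ancestral frequency
#' rows swapped) if needed so that corr(q0, PC1) is positive. Under the
#' package's PC sign convention (African ancestry at low PC1), the
#' resulting q0 is the European-like proportion: low q0 means high
#' African ancestry, the convention of the tabulated quartile analyses.
#'
#' @param fit an `admixture_fit`.
#' @param pc1 named numeric vector of PC1 coordinates covering the fit's
#'   samples.
#' @return the fit, possibly with components swapped; `attr(,"swapped")`
#'   records the decision.
#' @export
orient_q0 <- function(fit, pc1) {
  ids <- fit$estimates$sample_id
  if (!all(ids %in% names(pc1))) stop("pc1 lacks coordinates for some samples")
  r <- stats::cor(fit$estimates$q0, pc1[ids])
  if (!is.finite(r) || abs(r) < 0.2)
    stop("ancestry axis not identified: |corr(q0, PC1)| = ",
         formatC(abs(r), digits = 3))
  swapped <- r < 0
  if (swapped) {
    fit$estimates[, c("q0", "q1")] <- fit$estimates[, c("q1", "q0")]
    fit$ancestral_freq <- fit$ancestral_freq[c(2, 1), , drop = FALSE]
    rownames(fit$ancestral_freq) <- c("q0", "q1")
  }
  attr(fit, "swapped") <- swapped
  fit
}

#' Assign ancestry quartiles of q0
#'
#' Cut points at the empirical 25/50/75 percentiles of q0; intervals are
#' half-open (low, high] with the lowest closed at 0. Quartile 1 (lowest
#' q0) carries the highest degree of African ancestry and is the
#' reference group of the quartile risk model.
#'
#' @param estimates data.frame with `sample_id` and `q0` (cohort samples
#'   only; call per cohort).
#' @return the data.frame with an integer `quartile` column, plus
#'   `attr(,"cut_points")`.
#' @export
assign_quartiles <- function(estimates) {
  q0 <- estimates$q0
  if (length(unique(q0)) < 4) stop("fewer than 4 distinct q0 values")
  cuts <- stats::quantile(q0, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  quart <- findInterval(q0, cuts, left.open = TRUE) + 1L
  estimates$quartile <- quart
  attr(estimates, "cut_points") <- cuts
  estimates
}
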