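test_that("LD pruning removes duplicated columns, keeps independent ones, and meets its ceiling", {
  set.seed(31)
  n <- 300
  base <- matrix(rbinom(n * 20, 2, 0.5), n, 20)
  base[, 8] <- base[, 7]                       # perfect duplicate pair
  m <- tiny_gm(base)
  keep <- ld_prune(m)
  expect_equal(sum(c("v007", "v008") %in% keep), 1L)

  indep <- tiny_gm(matrix(rbinom(2000 * 30, 2, 0.5), 2000, 30))
  expect_length(ld_prune(indep), 30)

  # postcondition replay on correlated data
  q <- runif(n)
  corr <- sapply(1:40, function(l) rbinom(n, 2, 0.2 + 0.6 * q))
  mc <- tiny_gm(corr)
  keep2 <- ld_prune(mc, r2_max = 0.2, window = 10, step = 2)
  mk <- gm_subset(mc, variants = match(keep2, mc$variants$variant_id))
  for (s in seq(1, max(1, n_variants(mk) - 1), by = 2)) {
    idx <- s:min(s + 9, n_variants(mk))
    if (length(idx) < 2) next
    r2 <- suppressWarnings(stats::cor(mk$calls[, idx]))^2
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), 0.2 + 1e-12)
  }
})

test_that("GRM matches the double-loop oracle, is symmetric, and centers exact matches to zero", {
  set.seed(32)
  n <- 20; nv <- 50
  calls <- matrix(rbinom(n * nv, 2, runif(nv, 0.2, 0.8)[rep(1:nv, each = n)]), n, nv)
  calls[sample(n * nv, 30)] <- NA
  m <- tiny_gm(calls)
  g <- grm(m)
  expect_equal(max(abs(g - t(g))), 0)

  p <- allele_freq(m)
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    z <- 0; cnt <- 0
    for (l in 1:nv) {
      if (is.na(calls[i, l]) || is.na(calls[j, l])) next
      if (p[l] <= 0 || p[l] >= 1) next
      z <- z + (calls[i, l] - 2 * p[l]) * (calls[j, l] - 2 * p[l]) /
        (2 * p[l] * (1 - p[l]))
      cnt <- cnt + 1
    }
    oracle[i, j] <- z / cnt
  }
  expect_lt(max(abs(g - oracle)), 1e-10)

  # sample whose calls all equal 2p has a zero diagonal entry
  m2 <- tiny_gm(matrix(rep(c(0L, 1L, 2L, 1L), each = 4), 4, 4))
  g2 <- grm(m2)   # every sample identical -> calls == 2p everywhere
  expect_equal(max(abs(diag(g2))), 0)
})

test_that("PCA separates simulated populations, orders eigenvalues, and orients AFR low", {
  set.seed(33)
  nv <- 400
  fr <- simulate_ancestral_frequencies(nv, 0.2, seed = 33)
  ca <- matrix(rbinom(40 * nv, 2, rep(fr$freq_afr, each = 40)), 40, nv)
  ce <- matrix(rbinom(40 * nv, 2, rep(fr$freq_eur, each = 40)), 40, nv)
  m <- tiny_gm(rbind(ca, ce))
  afr_ids <- m$sample_ids[1:40]
  res <- grm_pca(grm(m), k = 5, afr_ids = afr_ids)
  pc1 <- res$coords[, "PC1"]
  expect_lt(max(pc1[1:40]), min(pc1[41:80]))   # zero overlap, AFR below EUR
  expect_true(all(diff(res$eigenvalues) <= 1e-10))
  expect_warning(grm_pca(grm(m), k = 100, afr_ids = afr_ids), "rank")
})

test_that("admixture EM: seed-reproducible, monotone likelihood, restarts keep the best", {
  run <- medium_cohort()
  sub <- gm_subset(run$co$genotypes, samples = 1:120,
                   variants = grep("^snp", run$co$genotypes$variants$variant_id)[1:300])
  f1 <- fit_admixture_k2(sub, seed = 5, restarts = 2, burn_iter = 10)
  f2 <- fit_admixture_k2(sub, seed = 5, restarts = 2, burn_iter = 10)
  expect_identical(f1$estimates$q0, f2$estimates$q0)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_true(all(diff(f1$ll_trace) > -1e-6))
  expect_true(all(abs(f1$estimates$q0 + f1$estimates$q1 - 1) < 1e-9))
})

test_that("EM attains at least the likelihood of a dense grid search with true frequencies", {
  run <- medium_cohort()
  co <- run$co
  ids <- co$genotypes$variants$variant_id[grep("^snp", co$genotypes$variants$variant_id)][1:8]
  sub <- gm_subset(co$genotypes, samples = 1:5, variants = ids)
  fit <- fit_admixture_k2(sub, seed = 3, restarts = 4, burn_iter = 20)
  fa <- co$truth$ancestral_freq_afr[ids]
  fe <- co$truth$ancestral_freq_eur[ids]
  grid <- seq(0, 1, by = 0.01)
  ll_i <- function(g, q) {
    th <- pmin(pmax(q * fa + (1 - q) * fe, 1e-6), 1 - 1e-6)
    sum(g * log(th) + (2 - g) * log1p(-th))
  }
  grid_ll <- sum(vapply(1:5, function(i)
    max(vapply(grid, function(q) ll_i(sub$calls[i, ], q), numeric(1))),
    numeric(1)))
  expect_gte(fit$log_likelihood, grid_ll)
})

test_that("two unadmixed populations are recovered at the boundary", {
  cfg <- sim_config(n_samples = 10, n_snps = 2500, n_aims = 50, n_chrom = 2,
                    panel_afr = 60, panel_eur = 60, seed = 44)
  pan <- simulate_reference_panel(cfg)
  fit <- fit_admixture_k2(pan$genotypes, seed = 2, restarts = 4, burn_iter = 20)
  q <- fit$estimates$q0
  truth <- as.integer(pan$superpopulation == "AFR")
  if (stats::cor(q, truth) < 0) q <- 1 - q
  # boundary recovery up to the estimator's own sampling error
  expect_lt(mean(abs(q - truth)), 0.02)
  expect_lt(max(q[truth == 0]), min(q[truth == 1]))  # complete separation
})

test_that("orientation against PC1 flips once, is idempotent, and fails without signal", {
  run <- medium_cohort()
  sub <- gm_subset(run$co$genotypes,
                   variants = grep("^snp", run$co$genotypes$variants$variant_id))
  fit <- fit_admixture_k2(sub, seed = 7, restarts = 2, burn_iter = 15)
  qt <- run$co$truth$q_afr_true
  # a stand-in PC1 pointing along European ancestry (low = African)
  pc1 <- stats::setNames(-qt + rnorm(length(qt), 0, 0.02), names(qt))
  fit1 <- orient_q0(fit, pc1)
  expect_gt(stats::cor(fit1$estimates$q0, pc1[fit1$estimates$sample_id]), 0.2)
  fit2 <- orient_q0(fit1, pc1)
  expect_false(attr(fit2, "swapped"))
  expect_identical(fit2$estimates$q0, fit1$estimates$q0)
  # pre-swapped input gets swapped back
  fit_sw <- fit1
  fit_sw$estimates[, c("q0", "q1")] <- fit_sw$estimates[, c("q1", "q0")]
  fit3 <- orient_q0(fit_sw, pc1)
  expect_true(attr(fit3, "swapped"))
  expect_equal(fit3$estimates$q0, fit1$estimates$q0)

  noise <- stats::setNames(rnorm(length(qt)), names(qt))
  expect_error(orient_q0(fit, noise), "not identified")
})

test_that("quartiles: uniform grid cut points, balanced groups, quartile 1 most African", {
  est <- data.frame(sample_id = sprintf("S%03d", 1:101),
                    q0 = seq(0, 1, length.out = 101))
  qq <- assign_quartiles(est)
  expect_equal(unname(attr(qq, "cut_points")), c(0.25, 0.5, 0.75))
  expect_true(max(table(qq$quartile)) - min(table(qq$quartile)) <= 1)
  expect_true(all(qq$q0[qq$quartile == 1] <= min(qq$q0[qq$quartile == 2])))
  expect_error(assign_quartiles(data.frame(sample_id = c("a", "b", "c"),
                                           q0 = c(0.1, 0.1, 0.1))),
               "distinct")
})
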