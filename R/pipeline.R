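#' Default end-to-end pipeline configuration
#'
#' Nested list covering every stage; unknown keys are rejected by
#' [run_pipeline()]. The `simulate` block configures the synthetic cohort
#' (see [sim_config()]); set `input$vcf` / `input$metadata` instead to run
#' on real data.
#'
#' @param seed global seed (propagated to the simulation block).
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_samples = 500, n_snps = 1500, n_aims = 400,
                    fst = 0.15, panel_afr = 80, panel_eur = 80),
    input = list(vcf = NULL, metadata = NULL),
    qc = list(enabled = TRUE, sample_missing = 0.03, het_sigma = 3,
              ibd_threshold = 0.1875, variant_missing = 0.03,
              dcr_alpha = 1e-5, hwe_alpha = 1e-5, maf_min = 0.01,
              ibd_max_snps = 10000),
    ancestry = list(r2_max = 0.2, window = 50, step = 5, k_pcs = 10,
                    tol = 1e-6, max_iter = 2000, restarts = 5, seed = 777,
                    exclude_populations = "ASW"),
    mapping = list(lambda = NULL, adjust_global = TRUE, alpha = 0.05),
    prs = list(missing = "impute", log_weights = FALSE),
    models = list(ci_level = 0.95, age_scale = 10)
  )
}

check_config <- function(config) {
  template <- default_config()
  bad <- setdiff(names(config), names(template))
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), names(template))) {
    if (is.list(template[[blk]]) && !is.null(config[[blk]])) {
      extra <- setdiff(names(config[[blk]]),
                       unique(c(names(template[[blk]]),
                                names(formals(sim_config)))))
      if (length(extra) > 0)
        stop("unknown config key(s) in '", blk, "': ", paste(extra, collapse = ", "))
    }
  }
  out <- template
  for (blk in names(config)) {
    if (is.list(template[[blk]]) && is.list(config[[blk]])) {
      for (k in names(config[[blk]])) out[[blk]][[k]] <- config[[blk]][[k]]
    } else out[[blk]] <- config[[blk]]
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full ancestry-risk pipeline
#'
#' Stage order: simulate (or load) genotypes and metadata; sample- and
#' variant-level QC; LD pruning, reference-panel merge, GRM-PCA, k = 2
#' admixture with orientation and quartiles; local-ancestry HMM and
#' admixture-mapping scan; polygenic risk score; association models
#' (ancestry metrics, quartiles, endophenotypes, multivariable risk
#' model). Each stage writes its TSV artifacts into `out_dir` and the run
#' closes with a YAML manifest (config echo, seed, stage timings, counts,
#' output checksums). A stage failure halts the run with a diagnostic
#' naming the stage.
#'
#' @param config nested list as from [default_config()]; partial lists are
#'   filled with defaults, unknown keys rejected.
#' @param out_dir output directory (created if needed).
#' @return list of in-memory stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  cfg <- check_config(config)
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, stages = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    res
  }

  # --- data stage ------------------------------------------------------
  simulated <- is.null(cfg$input$vcf)
  dat <- t_stage("data", {
    if (simulated) {
      sc_args <- cfg$simulate
      sc_args$seed <- cfg$seed
      scfg <- do.call(sim_config, sc_args)
      cohort <- simulate_cohort(scfg)
      panel <- simulate_reference_panel(scfg)
      write_vcf(cohort$genotypes, file.path(out_dir, "cohort.vcf"))
      write_sample_records(cohort$records, file.path(out_dir, "metadata.tsv"))
      write_tsv(data.frame(sample_id = names(cohort$truth$q_afr_true),
                           q_afr_true = cohort$truth$q_afr_true),
                file.path(out_dir, "truth_q.tsv"))
      list(genotypes = cohort$genotypes, records = cohort$records,
           panel = panel, aim_panel = cohort$aim_panel,
           generations = scfg$generations)
    } else {
      list(genotypes = read_vcf(cfg$input$vcf),
           records = read_sample_records(cfg$input$metadata),
           panel = NULL, aim_panel = NULL, generations = NULL)
    }
  })

  # --- QC --------------------------------------------------------------
  qcres <- t_stage("qc", {
    if (isTRUE(cfg$qc$enabled)) {
      r <- run_qc(dat$genotypes, dat$records,
                  sample_missing = cfg$qc$sample_missing,
                  het_sigma = cfg$qc$het_sigma,
                  ibd_threshold = cfg$qc$ibd_threshold,
                  variant_missing = cfg$qc$variant_missing,
                  dcr_alpha = cfg$qc$dcr_alpha, hwe_alpha = cfg$qc$hwe_alpha,
                  maf_min = cfg$qc$maf_min, ibd_max_snps = cfg$qc$ibd_max_snps)
      write_qc_report(r$report, file.path(out_dir, "qc_report.tsv"),
                      file.path(out_dir, "qc_summary.json"))
      r
    } else {
      list(genotypes = dat$genotypes,
           records = sample_records(dat$records), report = NULL)
    }
  })
  if (is.null(qcres$report)) manifest$qc_skipped <- TRUE
  m <- qcres$genotypes
  records <- qcres$records

  # --- global ancestry -------------------------------------------------
  anc <- t_stage("ancestry", {
    pruned_ids <- ld_prune(m, r2_max = cfg$ancestry$r2_max,
                           window = cfg$ancestry$window, step = cfg$ancestry$step)
    mp <- gm_subset(m, variants = match(pruned_ids, m$variants$variant_id))
    if (!is.null(dat$panel)) {
      mg <- merge_with_panel(mp, dat$panel,
                             exclude_populations = cfg$ancestry$exclude_populations)
      afr_ids <- mg$labels$sample_id[!is.na(mg$labels$superpopulation) &
                                       mg$labels$superpopulation == "AFR"]
      pca <- grm_pca(grm(mg$genotypes), k = cfg$ancestry$k_pcs, afr_ids = afr_ids)
    } else {
      pca <- grm_pca(grm(mp), k = cfg$ancestry$k_pcs)
    }
    fit <- fit_admixture_k2(mp, seed = cfg$ancestry$seed, tol = cfg$ancestry$tol,
                            max_iter = cfg$ancestry$max_iter,
                            restarts = cfg$ancestry$restarts)
    pc1 <- pca$coords[, "PC1"]
    fit <- orient_q0(fit, pc1)
    est <- fit$estimates
    cohort_pcs <- pca$coords[match(est$sample_id, rownames(pca$coords)), ,
                             drop = FALSE]
    est <- cbind(est, as.data.frame(cohort_pcs))
    est <- assign_quartiles(est)
    write_tsv(est, file.path(out_dir, "ancestry.tsv"))
    write_tsv(data.frame(component = seq_along(pca$eigenvalues),
                         eigenvalue = pca$eigenvalues),
              file.path(out_dir, "eigenvalues.tsv"))
    list(estimates = est, pca = pca, fit = fit)
  })

  # --- admixture mapping ----------------------------------------------
  mapres <- t_stage("mapping", {
    if (is.null(dat$aim_panel)) return(NULL)
    aim_ids <- intersect(dat$aim_panel$variant_id, m$variants$variant_id)
    if (length(aim_ids) < 2) return(NULL)
    m_aims <- gm_subset(m, variants = match(aim_ids, m$variants$variant_id))
    q_afr <- stats::setNames(1 - anc$estimates$q0, anc$estimates$sample_id)
    lambda <- if (!is.null(cfg$mapping$lambda)) cfg$mapping$lambda
              else if (!is.null(dat$generations)) dat$generations else 8
    post <- local_ancestry_posteriors(m_aims, dat$aim_panel, q_afr, lambda)
    scan <- ancestry_scan(post, records, q_afr,
                          adjust_global = cfg$mapping$adjust_global,
                          alpha = cfg$mapping$alpha)
    write_tsv(manhattan_table(scan, m_aims$variants),
              file.path(out_dir, "scan.tsv"))
    list(posteriors = post, scan = scan)
  })

  # --- PRS -------------------------------------------------------------
  prsres <- t_stage("prs", {
    s <- score_samples(m, missing = cfg$prs$missing,
                       log_weights = cfg$prs$log_weights)
    write_tsv(s, file.path(out_dir, "prs.tsv"))
    s
  })

  # --- association models ---------------------------------------------
  models <- t_stage("models", {
    est <- anc$estimates
    t1 <- rbind(ancestry_association(est, records, "q0"),
                ancestry_association(est, records, "PC1"))
    qa <- quartile_association(est, records)
    t3 <- endophenotype_models(est, records, ci_level = cfg$models$ci_level)
    t5 <- multivariable_model(est, records, prsres)
    write_tsv(t1, file.path(out_dir, "table1.tsv"))
    write_tsv(cbind(qa$table,
                    odds_ratio = c(NA, qa$model$odds_ratio),
                    ci_low = c(NA, qa$model$ci_low),
                    ci_high = c(NA, qa$model$ci_high)),
              file.path(out_dir, "table2.tsv"))
    write_tsv(t3, file.path(out_dir, "table3.tsv"))
    write_tsv(t5, file.path(out_dir, "table5.tsv"))
    list(ancestry = t1, quartiles = qa, endophenotypes = t3,
         multivariable = t5)
  })

  tsvs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$seed <- cfg$seed
  manifest$simulated <- simulated
  manifest$counts <- list(samples = n_samples(m), variants = n_variants(m))
  manifest$checksums <- as.list(tools::md5sum(tsvs))
  names(manifest$checksums) <- basename(tsvs)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(data = dat, qc = qcres, ancestry = anc, mapping = mapres,
                 prs = prsres, models = models, manifest = manifest))
}
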