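#' Logistic regression with Wald reporting
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' `stats::glm`), reported per term as odds ratio with Wald 95% CI
#' (exponentiated log-odds scale) and two-sided p. The design is checked
#' for full rank first (rank deficiency errors, naming the collinear
#' terms); separated fits are flagged and reported without CIs.
#'
#' @param outcome binary vector (0/1 or logical) with both classes present.
#' @param design data.frame or matrix of predictors (no intercept column;
#'   one is added).
#' @param ci_level confidence level, default 0.95.
#' @return data.frame of class `association_result`: term, estimate
#'   (log-odds), odds_ratio, ci_low, ci_high, p_value, n_used, flagged.
#' @export
fit_logistic <- function(outcome, design, ci_level = 0.95) {
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary")
  if (length(unique(y)) < 2) stop("outcome has a single class")
  X <- as.data.frame(design)
  if (nrow(X) != length(y)) stop("design and outcome lengths differ")
  cc <- stats::complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]; y <- y[cc]
  mm <- stats::model.matrix(~ ., data = X)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(mm, y, family = stats::binomial(),
                                         control = stats::glm.control(epsilon = 1e-10,
                                                                      maxit = 100)))
  sep <- !fit$converged || any(fit$fitted.values < 1e-9) ||
    any(fit$fitted.values > 1 - 1e-9)
  cf <- fit$coefficients
  W <- fit$weights
  cov <- solve(crossprod(mm * sqrt(W)))
  se <- sqrt(diag(cov))
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  keep <- colnames(mm) != "(Intercept)"
  out <- data.frame(term = colnames(mm)[keep], estimate = cf[keep],
                    odds_ratio = exp(cf[keep]),
                    ci_low = if (sep) NA_real_ else exp(cf[keep] - zc * se[keep]),
                    ci_high = if (sep) NA_real_ else exp(cf[keep] + zc * se[keep]),
                    p_value = 2 * stats::pnorm(-abs(cf[keep] / se[keep])),
                    n_used = length(y), flagged = sep,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("association_result", "data.frame")
  out
}

# z-score a vector by its own mean/SD; errors on zero variance
standardize <- function(x, what = "predictor") {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop(what, " has zero variance; cannot standardize")
  (x - mean(x, na.rm = TRUE)) / s
}

# case/control analysis frame: suspects excluded, estimates joined
model_frame <- function(estimates, records, extra = NULL) {
  df <- merge(as.data.frame(records), as.data.frame(estimates),
              by = "sample_id")
  if (!is.null(extra)) df <- merge(df, as.data.frame(extra), by = "sample_id")
  df <- df[df$status %in% c("case", "control"), , drop = FALSE]
  df$case <- as.integer(df$status == "case")
  df$male <- as.integer(df$sex == "male")
  df
}

#' Ancestry-metric association with case status
#'
#' Logistic model of case status on the standardized ancestry metric (q0
#' or PC1; z-scored with the analysis cohort's own mean/SD) adjusting for
#' age and sex; the reported OR is per 1-SD increase in the metric, which
#' makes the two metrics directly comparable. Also tabulates mean (SD) of
#' the raw metric in cases and controls.
#'
#' @param estimates data.frame with `sample_id` and the metric column.
#' @param records `sample_records`.
#' @param metric `"q0"` or `"PC1"`.
#' @return `association_result` row for the metric term, with
#'   `attr(,"group_summary")`.
#' @export
ancestry_association <- function(estimates, records, metric = c("q0", "PC1")) {
  metric <- match.arg(metric)
  df <- model_frame(estimates, records)
  df <- df[!is.na(df[[metric]]), , drop = FALSE]
  z <- standardize(df[[metric]], metric)
  res <- fit_logistic(df$case, data.frame(metric_sd = z, age = df$age,
                                          male = df$male))
  out <- res[res$term == "metric_sd", , drop = FALSE]
  out$term <- paste0(metric, "_per_sd")
  gs <- do.call(rbind, lapply(split(df[[metric]], df$status), function(x)
    data.frame(mean = mean(x), sd = stats::sd(x), n = length(x))))
  gs$status <- rownames(gs)
  attr(out, "group_summary") <- gs
  class(out) <- c("association_result", "data.frame")
  out
}

#' Quartile risk model of q0
#'
#' Quartile 1 (lowest q0, highest African ancestry) is the reference;
#' indicator terms for quartiles 2-4 give adjusted ORs for case status
#' (age and sex as covariates), alongside per-quartile counts, percent
#' male, mean age and percent cases.
#'
#' @param estimates output of [assign_quartiles()].
#' @param records `sample_records`.
#' @return list with `model` (`association_result` for quartiles 2-4) and
#'   `table` (4-row per-quartile summary; reference row marked).
#' @export
quartile_association <- function(estimates, records) {
  if (!"quartile" %in% names(estimates)) stop("assign_quartiles first")
  df <- model_frame(estimates, records)
  if (!all(1:4 %in% df$quartile)) stop("empty quartile among cases/controls")
  qf <- factor(df$quartile, levels = 1:4)
  design <- data.frame(q2 = as.integer(qf == 2), q3 = as.integer(qf == 3),
                       q4 = as.integer(qf == 4), age = df$age, male = df$male)
  model <- fit_logistic(df$case, design)
  model <- model[model$term %in% c("q2", "q3", "q4"), , drop = FALSE]
  model$term <- paste0("quartile_", 2:4)
  class(model) <- c("association_result", "data.frame")
  tab <- do.call(rbind, lapply(1:4, function(k) {
    dd <- df[df$quartile == k, ]
    data.frame(quartile = k, n = nrow(dd),
               males = sum(dd$male), pct_male = round(100 * mean(dd$male)),
               mean_age = mean(dd$age), sd_age = stats::sd(dd$age),
               cases = sum(dd$case), pct_case = round(100 * mean(dd$case)),
               reference = k == 1L)
  }))
  list(model = model, table = tab)
}

#' Linear endophenotype models among cases
#'
#' Among POAG cases only, ordinary least squares of each quantitative
#' trait (IOP, CCT, CDR, RNFL, in that order) on standardized q0, age and
#' sex; the coefficient of interest is microns (or trait units) per 1 SD
#' of q0, with Wald 95% CI and two-sided p. Traits with fewer than 10
#' usable cases are skipped with a warning.
#'
#' @param estimates data.frame with `sample_id`, `q0`.
#' @param records `sample_records` (cases are selected internally).
#' @param ci_level confidence level.
#' @return data.frame: trait, n_used, beta, ci_low, ci_high, p_value.
#' @export
endophenotype_models <- function(estimates, records, ci_level = 0.95) {
  df <- model_frame(estimates, records)
  df <- df[df$status == "case" & !is.na(df$q0), , drop = FALSE]
  traits <- c("iop", "cct", "cdr", "rnfl")
  rows <- lapply(traits, function(tr) {
    dd <- df[!is.na(df[[tr]]), , drop = FALSE]
    if (nrow(dd) < 10) {
      warning("trait ", tr, ": only ", nrow(dd), " usable cases; skipped")
      return(data.frame(trait = tr, n_used = nrow(dd), beta = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_))
    }
    z <- standardize(dd$q0, "q0")
    fit <- stats::lm(dd[[tr]] ~ z + dd$age + dd$male)
    sm <- summary(fit)$coefficients
    est <- sm["z", "Estimate"]; se <- sm["z", "Std. Error"]
    tc <- stats::qt(1 - (1 - ci_level) / 2, df = fit$df.residual)
    data.frame(trait = tr, n_used = nrow(dd), beta = est,
               ci_low = est - tc * se, ci_high = est + tc * se,
               p_value = sm["z", "Pr(>|t|)"])
  })
  do.call(rbind, rows)
}

#' Multivariable risk model
#'
#' Logistic regression of case status on age (per 10 years), standardized
#' q0 (per SD), the weighted polygenic risk score (per point) and male
#' sex, reported as ORs with 95% CIs — the joint model separating the
#' genome-wide ancestry effect from the known-variant polygenic effect.
#'
#' @param estimates data.frame with `sample_id`, `q0`.
#' @param records `sample_records`.
#' @param scores `prs_result` from [score_samples()] (or data.frame with
#'   `sample_id`, `score`).
#' @return `association_result` with terms `age_per_10y`, `q0_per_sd`,
#'   `prs_per_point`, `male`.
#' @export
multivariable_model <- function(estimates, records, scores) {
  df <- model_frame(estimates, records, extra = scores[, c("sample_id", "score")])
  df <- df[!is.na(df$q0) & !is.na(df$score), , drop = FALSE]
  design <- data.frame(age_per_10y = df$age / 10,
                       q0_per_sd = standardize(df$q0, "q0"),
                       prs_per_point = df$score,
                       male = df$male)
  fit_logistic(df$case, design)
}
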