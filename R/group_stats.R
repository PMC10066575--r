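#' Simple standardized associations with FDR correction
#'
#' One simple regression per covariate against the outcome, on
#' standardized variables so the coefficient is the correlation; markedly
#' skewed covariates (by default TMT-B style reaction-time scores) use
#' Spearman's rho instead. Benjamini-Hochberg FDR correction is applied
#' across the whole association family.
#'
#' @param data data.frame holding the outcome and covariates.
#' @param outcome Outcome column name (e.g. the NFQ).
#' @param covariates Covariate column names.
#' @param methods Named character vector overriding the per-covariate
#'   method (`"pearson"` or `"spearman"`); unnamed covariates default to
#'   Pearson.
#' @param minN Minimum complete-case rows per association (default 10).
#' @return data.frame: `predictor`, `method`, `coefficient` (standardized
#'   beta or rho), `t`, `p`, `p_fdr`, `adj_r2`, `ci_lo`, `ci_hi`, `n`.
#' @export
simpleAssociations <- function(data, outcome, covariates,
                               methods = NULL, minN = 10) {
  rows <- lapply(covariates, function(cv) {
    meth <- if (!is.null(methods) && cv %in% names(methods))
      methods[[cv]] else "pearson"
    cc <- stats::complete.cases(data[[outcome]], data[[cv]])
    y <- data[[outcome]][cc]; x <- data[[cv]][cc]
    n <- length(y)
    if (n < minN)
      stop("fewer than ", minN, " complete cases for ", cv, call. = FALSE)
    if (stats::sd(x) == 0) {
      warning("skipping zero-variance covariate: ", cv)
      return(NULL)
    }
    if (meth == "pearson") {
      zy <- as.numeric(scale(y)); zx <- as.numeric(scale(x))
      fit <- stats::lm(zy ~ zx)
      sm <- summary(fit)
      ci <- stats::confint(fit)["zx", ]
      data.frame(predictor = cv, method = "pearson",
                 coefficient = unname(stats::coef(fit)["zx"]),
                 t = sm$coefficients["zx", "t value"],
                 p = sm$coefficients["zx", "Pr(>|t|)"],
                 adj_r2 = sm$adj.r.squared,
                 ci_lo = ci[1], ci_hi = ci[2], n = n)
    } else {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      rho <- unname(ct$estimate)
      # approximate CI via Fisher transform with SE 1/sqrt(n - 3)
      fz <- atanh(rho); se <- 1 / sqrt(n - 3)
      data.frame(predictor = cv, method = "spearman",
                 coefficient = rho, t = NA_real_, p = ct$p.value,
                 adj_r2 = NA_real_,
                 ci_lo = tanh(fz - 1.96 * se),
                 ci_hi = tanh(fz + 1.96 * se), n = n)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("predictor", "method", "coefficient", "t", "p", "p_fdr",
          "adj_r2", "ci_lo", "ci_hi", "n")]
}

#' Multivariate regression of the outcome on all predictors
#'
#' @param data data.frame.
#' @param outcome Outcome column.
#' @param predictors Predictor columns, all entered jointly.
#' @return List: `fit` (the `lm`), `F`, `df` (c(num, den)), `p`, `r2`,
#'   `adj_r2`, `coefficients` (per-predictor t and p table).
#' @export
multivariateRegression <- function(data, outcome, predictors) {
  dat <- data[stats::complete.cases(data[, c(outcome, predictors)]),
              c(outcome, predictors)]
  .stopIfNot(nrow(dat) > length(predictors) + 1,
             "need n > p + 1 complete cases")
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; aliased column(s): ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(fit = fit, F = unname(fs[1]), df = unname(fs[2:3]),
       p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
       coefficients = sm$coefficients)
}

#' One-way ANOVA with Tukey HSD post hoc tests
#'
#' Tukey-Kramer honest significant differences handle unequal group
#' sizes; singleton groups are excluded from the post hoc comparisons
#' with a warning.
#'
#' @param values Numeric response (e.g. age-adjusted Z-scores).
#' @param groups Group labels.
#' @return List: `F`, `df`, `p`, `tukey` (data.frame comparison, diff,
#'   lwr, upr, p_adj), `fit`.
#' @export
anovaTukey <- function(values, groups) {
  groups <- factor(groups)
  .stopIfNot(nlevels(groups) >= 2, "need at least 2 groups")
  sizes <- table(groups)
  .stopIfNot(all(sizes >= 2) || sum(sizes >= 2) >= 2,
             "need at least two groups with n >= 2")
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  singles <- names(sizes)[sizes < 2]
  tukGroups <- groups
  if (length(singles)) {
    warning("excluding singleton group(s) from Tukey tests: ",
            paste(singles, collapse = ", "))
    keep <- !groups %in% singles
    tukGroups <- droplevels(groups[keep])
    tukFit <- stats::aov(values[keep] ~ tukGroups)
  } else tukFit <- fit
  tk <- stats::TukeyHSD(tukFit)[[1]]
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = sm[["F value"]][1], df = c(sm[["Df"]][1], sm[["Df"]][2]),
       p = sm[["Pr(>F)"]][1], tukey = tukey, fit = fit)
}

#' Cohen's D with confidence interval
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, pooled SD weighted by degrees of
#' freedom. The CI is based on the noncentral t distribution by default,
#' with a bootstrap option. Magnitude labels follow the small/medium/
#' large thresholds 0.3 / 0.5 / 0.8.
#'
#' @param a,b Numeric samples; the sign convention is a-minus-b.
#' @param ci `"noncentral"` (default) or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param nBoot Bootstrap resamples when `ci = "bootstrap"`.
#' @return List: `d`, `ci_lo`, `ci_hi`, `magnitude`, `n`.
#' @export
cohensD <- function(a, b, ci = c("noncentral", "bootstrap"),
                    level = 0.95, nBoot = 2000) {
  ci <- match.arg(ci)
  na <- length(a); nb <- length(b)
  .stopIfNot(na >= 2 && nb >= 2, "need n >= 2 per group")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("zero pooled SD: Cohen's D undefined", call. = FALSE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  alpha <- 1 - level
  if (ci == "noncentral") {
    # invert the noncentral t CDF for the noncentrality parameter
    scl <- sqrt(1 / na + 1 / nb)
    tobs <- d / scl
    df <- na + nb - 2
    ncpFor <- function(target) {
      f <- function(ncp) stats::pt(tobs, df, ncp) - target
      lim <- max(10, abs(tobs) * 3 + 10)
      if (f(-lim) * f(lim) > 0) return(sign(tobs) * lim)
      stats::uniroot(f, c(-lim, lim))$root
    }
    lo <- ncpFor(1 - alpha / 2) * scl
    hi <- ncpFor(alpha / 2) * scl
  } else {
    ds <- replicate(nBoot, {
      aa <- sample(a, na, replace = TRUE)
      bb <- sample(b, nb, replace = TRUE)
      s2 <- ((na - 1) * stats::var(aa) + (nb - 1) * stats::var(bb)) /
        (na + nb - 2)
      if (s2 == 0) NA_real_ else (mean(aa) - mean(bb)) / sqrt(s2)
    })
    qs <- stats::quantile(ds, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
    lo <- qs[1]; hi <- qs[2]
  }
  mag <- cut(abs(d), c(-Inf, 0.3, 0.5, 0.8, Inf),
             labels = c("negligible", "small", "medium", "large"),
             right = FALSE)
  list(d = d, ci_lo = unname(lo), ci_hi = unname(hi),
       magnitude = as.character(mag), n = c(na, nb))
}

#' ROC AUC with confidence interval
#'
#' AUC via the rank (Mann-Whitney) statistic with half credit for ties;
#' the CI uses DeLong's method by default or a stratified bootstrap.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels; cases are `TRUE`/1/second factor level.
#' @param ci `"delong"` (default) or `"bootstrap"`.
#' @param level Confidence level.
#' @return List: `auc`, `ci_lo`, `ci_hi`, `nCases`, `nControls`.
#' @export
rocAuc <- function(scores, labels, ci = c("delong", "bootstrap"),
                   level = 0.95) {
  ci <- match.arg(ci)
  lab <- if (is.logical(labels)) labels
         else if (is.factor(labels)) labels == levels(labels)[2]
         else labels == max(labels)
  if (length(unique(lab)) < 2)
    stop("need at least one case and one control", call. = FALSE)
  r <- suppressMessages(pROC::roc(response = lab, predictor = scores,
                                  direction = "<", quiet = TRUE))
  auc <- as.numeric(pROC::auc(r))
  cc <- suppressWarnings(pROC::ci.auc(
    r, conf.level = level,
    method = if (ci == "delong") "delong" else "bootstrap",
    boot.n = 2000, progress = "none"))
  list(auc = auc, ci_lo = as.numeric(cc[1]), ci_hi = as.numeric(cc[3]),
       nCases = sum(lab), nControls = sum(!lab))
}

#' Centile-threshold patient counts
#'
#' Counts, per biomarker and group, subjects whose 2-decimal-rounded
#' centile rank passes a threshold rule. "Above the c-th centile" uses
#' `>=` on the rounded rank (so a printed 0.90 counts as above the 90th
#' centile); "c-th centile or lower" uses `<=`.
#'
#' @param ztable Long Z-score table with columns `biomarker`, `group`,
#'   `centile` (rounded to 2 decimals).
#' @param rules data.frame with columns `biomarker`, `group`, `direction`
#'   (`"above"` or `"below"`), `cutoff` (proportion, e.g. 0.90).
#' @return `rules` with added `count` and `n` columns.
#' @export
centileThresholdCounts <- function(ztable, rules) {
  if (nrow(rules) == 0)
    return(cbind(rules, count = integer(0), n = integer(0)))
  res <- lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    sel <- ztable$biomarker == r$biomarker & ztable$group == r$group
    if (!any(sel))
      stop("no rows for biomarker '", r$biomarker, "' in group '",
           r$group, "'", call. = FALSE)
    cen <- ztable$centile[sel]
    hit <- if (r$direction == "above") cen >= r$cutoff else cen <= r$cutoff
    data.frame(count = sum(hit), n = length(cen))
  })
  cbind(rules, do.call(rbind, res))
}

#' Amyloid / tau positivity classification
#'
#' A+ iff the amyloid SUVR strictly exceeds 1.42; T+ iff the tau SUVR
#' strictly exceeds 1.23.
#'
#' @param amyloidSUVR,tauSUVR Meta-ROI SUVRs.
#' @param aThreshold,tThreshold Positivity cut-points (defaults 1.42,
#'   1.23; strict `>`).
#' @return data.frame with logical `A` and `T` columns and an `status`
#'   string such as `"A+/T-"`.
#' @export
atClassify <- function(amyloidSUVR, tauSUVR,
                       aThreshold = 1.42, tThreshold = 1.23) {
  .stopIfNot(all(is.finite(amyloidSUVR)) && all(is.finite(tauSUVR)),
             "SUVRs must be finite")
  A <- amyloidSUVR > aThreshold
  T <- tauSUVR > tThreshold
  data.frame(A = A, T = T,
             status = paste0("A", ifelse(A, "+", "-"),
                             "/T", ifelse(T, "+", "-")))
}

#' Chi-squared test on a categorical distribution across groups
#'
#' Utility for demographic tables (e.g. sex by group); Yates correction
#' off by default.
#'
#' @param x,g Category and group labels.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return `htest` from [stats::chisq.test()].
#' @export
chisqGroups <- function(x, g, correct = FALSE) {
  stats::chisq.test(table(x, g), correct = correct)
}
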