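#' Quasi-Bayesian causal mediation analysis
#'
#' Estimates the average causal mediation effect (ACME), average direct
#' effect (ADE), total effect and proportion mediated for a linear,
#' no-interaction mediation model. The mediator model `M ~ X (+ cov)` and
#' outcome model `Y ~ X + M (+ cov)` are fitted by OLS; `nSims` parameter
#' vectors are drawn from the asymptotic multivariate normal of each fit
#' (the quasi-Bayesian Monte Carlo approximation), and per draw
#' `ACME = a * b`, `ADE = c'`, `total = ACME + ADE`,
#' `proportion = ACME / total`. Point estimates are medians of the draws
#' (mean available), CIs are percentile intervals, and p-values are
#' two-sided simulation tail probabilities. A nonparametric
#' case-resampling bootstrap is available as an option.
#'
#' @param data data.frame with the analysis columns.
#' @param outcome,treatment,mediator Column names for Y, X and M
#'   (distinct).
#' @param covariates Optional covariate column names added to both models.
#' @param nSims Simulation draws (default 10000, minimum 100).
#' @param ciLevel Confidence level (default 0.95).
#' @param seed Optional RNG seed for reproducible draws.
#' @param method `"quasi-bayesian"` (default) or `"bootstrap"`.
#' @param point `"median"` (default) or `"mean"` point estimate.
#' @return A [MediationResult-class].
#' @export
fitMediation <- function(data, outcome, treatment, mediator,
                         covariates = NULL, nSims = 10000,
                         ciLevel = 0.95, seed = NULL,
                         method = c("quasi-bayesian", "bootstrap"),
                         point = c("median", "mean")) {
  method <- match.arg(method)
  point <- match.arg(point)
  .stopIfNot(length(unique(c(outcome, treatment, mediator))) == 3,
             "outcome, treatment and mediator must be distinct columns")
  .stopIfNot(nSims >= 100, "nSims must be at least 100")
  cols <- c(outcome, treatment, mediator, covariates)
  dat <- data[stats::complete.cases(data[, cols]), cols]
  .stopIfNot(nrow(dat) >= 20, "need at least 20 complete cases")
  if (!is.null(seed)) set.seed(seed)
  covTerm <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""
  fM <- stats::as.formula(paste(mediator, "~", treatment, covTerm))
  fY <- stats::as.formula(paste(outcome, "~", treatment, "+", mediator,
                                covTerm))
  mFit <- stats::lm(fM, data = dat)
  yFit <- stats::lm(fY, data = dat)
  if (anyNA(stats::coef(mFit)) || anyNA(stats::coef(yFit)))
    stop("non-invertible design in mediator or outcome model", call. = FALSE)

  if (method == "quasi-bayesian") {
    aDraw <- MASS::mvrnorm(nSims, stats::coef(mFit),
                           stats::vcov(mFit))[, treatment]
    yDraws <- MASS::mvrnorm(nSims, stats::coef(yFit), stats::vcov(yFit))
    bDraw <- yDraws[, mediator]
    cDraw <- yDraws[, treatment]
  } else {
    n <- nrow(dat)
    draws <- vapply(seq_len(nSims), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mB <- stats::lm(fM, data = dat[idx, ])
      yB <- stats::lm(fY, data = dat[idx, ])
      c(stats::coef(mB)[treatment], stats::coef(yB)[mediator],
        stats::coef(yB)[treatment])
    }, numeric(3))
    aDraw <- draws[1, ]; bDraw <- draws[2, ]; cDraw <- draws[3, ]
  }
  acme <- aDraw * bDraw
  ade <- cDraw
  total <- acme + ade
  flagged <- abs(total) < .Machine$double.eps^0.5
  prop <- ifelse(flagged, NA_real_, acme / total)

  est <- if (point == "median") function(x) stats::median(x, na.rm = TRUE)
         else function(x) mean(x, na.rm = TRUE)
  alpha <- 1 - ciLevel
  summarise <- function(x) {
    qs <- stats::quantile(x, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
    pv <- 2 * min(mean(x < 0, na.rm = TRUE), mean(x > 0, na.rm = TRUE))
    c(estimate = est(x), ci_lo = unname(qs[1]), ci_hi = unname(qs[2]),
      p = max(pv, 2 / nSims))
  }
  tab <- rbind(acme = summarise(acme), ade = summarise(ade),
               total = summarise(total),
               proportion_mediated = summarise(prop))
  new("MediationResult",
      estimates = data.frame(effect = rownames(tab), tab, row.names = NULL),
      nSims = as.integer(nSims), flaggedFraction = mean(flagged),
      models = list(mediator = mFit, outcome = yFit),
      spec = list(outcome = outcome, treatment = treatment,
                  mediator = mediator, covariates = covariates,
                  method = method, point = point, ciLevel = ciLevel,
                  seed = seed))
}

#' Human-readable mediation summary
#'
#' @param result A [MediationResult-class].
#' @return data.frame report (effect, estimate, CI bounds, p, and the
#'   proportion mediated formatted as a percentage), printed on request
#'   with [writeTSV()].
#' @export
summarizeMediation <- function(result) {
  es <- mediationEstimates(result)
  fmtP <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  rep <- data.frame(
    effect = es$effect,
    estimate = sprintf("%.4g", es$estimate),
    ci = sprintf("(%.4g, %.4g)", es$ci_lo, es$ci_hi),
    p = fmtP(es$p), stringsAsFactors = FALSE)
  propRow <- es$effect == "proportion_mediated"
  rep$estimate[propRow] <- sprintf("%.1f%%", 100 * es$estimate[propRow])
  attr(rep, "flaggedFraction") <- result@flaggedFraction
  rep
}
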