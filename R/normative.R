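#' Fit age-conditional location-scale quantile curves
#'
#' Fits, for one biomarker on the normative cohort, smooth location
#' mu(age) and scale sigma(age) curves under a normal family by penalized
#' maximum likelihood: both curves are penalized B-splines of age, the
#' scale is modelled on a log-type (positivity-preserving) link, and
#' smoothing is chosen by REML within each candidate basis dimension. Each
#' candidate is scored with the global deviance (-2 log L), AIC and the
#' Schwarz Bayesian criterion, and the winner is selected by SBC
#' (configurable). Quantile-residual diagnostics are computed on the
#' winner.
#'
#' @param values Biomarker values, one per subject.
#' @param ages Ages in years, same length.
#' @param kGrid Candidate basis dimensions for the two spline curves
#'   (default `c(4, 6, 9)`, spanning roughly 2-8 effective df).
#' @param select Selection score: `"sbc"` (default), `"aic"` or `"gd"`.
#' @param biomarker Name stored in the model.
#' @param sp Optional fixed smoothing parameters (length 2) passed to the
#'   engine; large values force the linear limit.
#' @return A [NormativeModel-class].
#' @export
fitNormative <- function(values, ages, kGrid = c(4, 6, 9),
                         select = c("sbc", "aic", "gd"),
                         biomarker = "biomarker", sp = NULL) {
  select <- match.arg(select)
  keep <- is.finite(values) & is.finite(ages)
  values <- values[keep]; ages <- ages[keep]
  n <- length(values)
  if (n < 50) warning("fewer than 50 normative subjects (n = ", n, ")")
  if (length(unique(ages)) < max(kGrid))
    stop("fewer distinct ages (", length(unique(ages)),
         ") than spline degrees of freedom (", max(kGrid), ")", call. = FALSE)
  dat <- data.frame(y = values, age = ages)
  cand <- data.frame(k = kGrid, edf = NA_real_, global_deviance = NA_real_,
                     aic = NA_real_, sbc = NA_real_, converged = FALSE)
  fits <- vector("list", length(kGrid))
  for (i in seq_along(kGrid)) {
    k <- kGrid[i]
    # location: order-2 penalty (shrinks to a linear trend); scale:
    # order-1 penalty (shrinks to homoscedasticity), so the infinite-
    # smoothing limit is the ordinary least-squares fit
    fit <- tryCatch(
      mgcv::gam(list(y ~ s(age, bs = "ps", k = k),
                     ~ s(age, bs = "ps", k = k, m = c(2, 1))),
                family = mgcv::gaulss(), data = dat, method = "REML",
                sp = sp),
      error = function(e) e)
    if (inherits(fit, "error")) next
    edf <- sum(fit$edf)
    gd <- -2 * as.numeric(stats::logLik(fit))
    cand$edf[i] <- edf
    cand$global_deviance[i] <- gd
    cand$aic[i] <- gd + 2 * edf
    cand$sbc[i] <- gd + log(n) * edf
    cand$converged[i] <- fit$converged %||% TRUE
    fits[[i]] <- fit
  }
  if (!any(cand$converged))
    stop("no candidate location-scale fit converged", call. = FALSE)
  score <- switch(select, sbc = cand$sbc, aic = cand$aic,
                  gd = cand$global_deviance)
  best <- which.min(ifelse(cand$converged, score, Inf))
  model <- new("NormativeModel", biomarker = biomarker,
               engine = fits[[best]], backend = "gam",
               support = range(ages),
               scores = list(global_deviance = cand$global_deviance[best],
                             aic = cand$aic[best], sbc = cand$sbc[best],
                             edf = cand$edf[best], k = cand$k[best],
                             n = n, selected_by = select),
               candidates = cand, diagnostics = list())
  model@diagnostics <- wormDiagnostics(model, values, ages)[
    c("mean", "sd", "skewness", "kurtosis", "flags")]
  model
}

#' Evaluate the location and scale curves
#'
#' @param model A [NormativeModel-class].
#' @param ages Ages (years) at which to evaluate.
#' @return data.frame with `age`, `mu`, `sigma`, `extrapolated` (TRUE for
#'   ages outside the fitted support; values are still returned).
#' @export
predictNormative <- function(model, ages) {
  if (model@backend == "gam") {
    pr <- stats::predict(model@engine, newdata = data.frame(age = ages),
                         type = "response")
    mu <- pr[, 1]
    sigma <- 1 / pr[, 2]        # second response column is 1/sigma
  } else {
    mu <- model@engine$muFun(ages)
    sigma <- exp(model@engine$logSigmaFun(ages))
  }
  data.frame(age = ages, mu = as.numeric(mu), sigma = as.numeric(sigma),
             extrapolated = ages < model@support[1] |
                            ages > model@support[2])
}

#' Centile curves over an age grid
#'
#' `curve_c(age) = mu(age) + qnorm(c) * sigma(age)` for each requested
#' centile under the normal family. The default centile set is
#' 0.4, 2, 10, 25, 50, 75, 90, 99 and 99.6 per cent.
#'
#' @param model A [NormativeModel-class].
#' @param centiles Centiles as proportions in (0, 1).
#' @param ageGrid Ages at which to evaluate (default 101 points over the
#'   support).
#' @return data.frame: `age`, `extrapolated`, one column per centile
#'   (named `c0.004` etc.).
#' @export
centileCurves <- function(model,
                          centiles = c(0.004, 0.02, 0.10, 0.25, 0.50,
                                       0.75, 0.90, 0.99, 0.996),
                          ageGrid = NULL) {
  .stopIfNot(all(centiles > 0 & centiles < 1),
             "centiles must be proportions in (0, 1)")
  if (is.null(ageGrid))
    ageGrid <- seq(model@support[1], model@support[2], length.out = 101)
  p <- predictNormative(model, ageGrid)
  out <- data.frame(age = p$age, extrapolated = p$extrapolated)
  for (cc in centiles)
    out[[paste0("c", cc)]] <- p$mu + stats::qnorm(cc) * p$sigma
  out
}

#' Age-adjusted Z-scores and centile ranks
#'
#' `z = (value - mu(age)) / sigma(age)`; the centile rank is `pnorm(z)`
#' rounded to 2 decimals (the rounding convention used for reported
#' patient tables and for centile-threshold counting), with the unrounded
#' value kept alongside.
#'
#' @param model A [NormativeModel-class].
#' @param values Biomarker values.
#' @param ages Ages (years), same length.
#' @param subjects Optional subject ids.
#' @param group Optional group labels.
#' @return data.frame: `subject`, `group`, `biomarker`, `z`, `centile`
#'   (2-decimal), `centile_raw`, `extrapolated`.
#' @export
scoreSubjects <- function(model, values, ages, subjects = NULL,
                          group = NULL) {
  p <- predictNormative(model, ages)
  z <- (values - p$mu) / p$sigma
  raw <- stats::pnorm(z)
  data.frame(
    subject = subjects %||% seq_along(values),
    group = group %||% NA_character_,
    biomarker = model@biomarker,
    z = z, centile = round(raw, 2), centile_raw = raw,
    extrapolated = p$extrapolated,
    stringsAsFactors = FALSE)
}

#' Quantile-residual (worm) diagnostics
#'
#' Quantile residuals `r_i = qnorm(F(value_i | age_i))`, which for the
#' normal family equal the age-adjusted Z-scores; a well-specified model
#' yields residuals close to standard normal. Returns moments, worm-plot
#' (detrended Q-Q) coordinates and a pointwise 95% band.
#'
#' @param model A [NormativeModel-class].
#' @param values,ages Data to diagnose.
#' @return List: `mean`, `sd`, `skewness`, `kurtosis`, `flags`
#'   (character; non-empty when residual moments leave the healthy range),
#'   `worm` (data.frame `theoretical`, `deviation`, `band`).
#' @export
wormDiagnostics <- function(model, values, ages) {
  p <- predictNormative(model, ages)
  r <- (values - p$mu) / p$sigma
  n <- length(r)
  probs <- stats::ppoints(n)
  theo <- stats::qnorm(probs)
  dev <- sort(r) - theo
  band <- 1.96 * sqrt(probs * (1 - probs) / n) / stats::dnorm(theo)
  kur <- .momentKurtosis(r)
  ske <- .momentSkewness(r)
  flags <- character()
  if (abs(mean(r)) > 0.1) flags <- c(flags, "residual mean away from 0")
  if (abs(ske) >= 1) flags <- c(flags, "|skewness| >= 1")
  if (kur > 4 || kur < 2) flags <- c(flags, "kurtosis outside 3 +/- 1")
  list(mean = mean(r), sd = stats::sd(r), skewness = ske, kurtosis = kur,
       flags = flags,
       worm = data.frame(theoretical = theo, deviation = dev, band = band))
}

#' Serialize a normative model to JSON
#'
#' The curves are stored as a dense age grid (mu, log sigma) plus scores
#' and support; [readNormativeModel()] rebuilds an evaluable model from
#' it. The grid representation round-trips scoring to interpolation
#' accuracy and needs no fitted engine object.
#'
#' @param model A [NormativeModel-class].
#' @param path Output JSON path.
#' @param nGrid Grid density (default 201).
#' @return `path`, invisibly.
#' @export
writeNormativeModel <- function(model, path, nGrid = 201) {
  grid <- seq(model@support[1], model@support[2], length.out = nGrid)
  p <- predictNormative(model, grid)
  obj <- list(biomarker = model@biomarker, support = model@support,
              age = grid, mu = p$mu, log_sigma = log(p$sigma),
              scores = model@scores,
              diagnostics = model@diagnostics[
                c("mean", "sd", "skewness", "kurtosis")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a normative model from JSON
#'
#' @param path JSON file written by [writeNormativeModel()].
#' @return A [NormativeModel-class] with a grid backend.
#' @export
readNormativeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  engine <- list(
    muFun = stats::splinefun(obj$age, obj$mu, method = "natural"),
    logSigmaFun = stats::splinefun(obj$age, obj$log_sigma,
                                   method = "natural"))
  new("NormativeModel", biomarker = obj$biomarker, engine = engine,
      backend = "grid", support = as.numeric(obj$support),
      scores = as.list(obj$scores),
      candidates = data.frame(),
      diagnostics = as.list(obj$diagnostics))
}

#' Fit normative models for a set of biomarkers
#'
#' @param data data.frame of normative subjects with an `age` column.
#' @param biomarkers Column names to model.
#' @param ... Passed to [fitNormative()].
#' @return Named list of [NormativeModel-class] objects.
#' @export
fitNormativeSet <- function(data, biomarkers, ...) {
  stats::setNames(lapply(biomarkers, function(b)
    fitNormative(data[[b]], data$age, biomarker = b, ...)), biomarkers)
}
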