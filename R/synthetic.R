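# ---- study-condition defaults -------------------------------------------
# Biomarkers modelled throughout: the NFQ plus four structural markers.
nfqBiomarkers <- function() {
  c("nfq", "meta_roi", "left_hipp", "right_hipp", "inf_parietal")
}

# True age curves: mu as quadratic in (age - 35), sigma linear in
# (age - 35). Units: NFQ unitless; thickness mm; volumes mm^3 (already
# ICV-adjusted scale).
.defaultCurves <- function() list(
  nfq          = list(mu = c(1.05, 0.012, 0.00002), sigma = c(0.45, 0.001)),
  meta_roi     = list(mu = c(3.05, -0.0045, 0),     sigma = c(0.12, 0)),
  left_hipp    = list(mu = c(4400, -13, 0),         sigma = c(350, 0)),
  right_hipp   = list(mu = c(4450, -13, 0),         sigma = c(350, 0)),
  inf_parietal = list(mu = c(4.95, -0.007, 0),      sigma = c(0.22, 0)))

# Patient effects in normative-SD units at the subject's age. Values are
# the group-mean Z-shifts of the case-study phenotypes: the dysexecutive
# phenotype is dominated by inferior parietal thinning, the amnestic one
# by hippocampal and global cortical loss; both share a raised NFQ.
.defaultEffects <- function() {
  m <- rbind(
    dAD     = c(nfq = 2.21, meta_roi = -1.62, left_hipp = -1.06,
                right_hipp = -0.24, inf_parietal = -3.20),
    AD      = c(nfq = 1.76, meta_roi = -2.56, left_hipp = -1.54,
                right_hipp = -1.41, inf_parietal = -1.40),
    control = c(nfq = 0, meta_roi = 0, left_hipp = 0,
                right_hipp = 0, inf_parietal = 0))
  m
}

.evalMu <- function(curve, age) {
  a <- age - 35
  curve$mu[1] + curve$mu[2] * a + curve$mu[3] * a^2
}
.evalSigma <- function(curve, age) {
  a <- age - 35
  pmax(curve$sigma[1] + curve$sigma[2] * a, 1e-8)
}

#' Cohort-simulation configuration
#'
#' Collects the study-design constants of the simulated cohorts: group
#' sizes, the age window, the four 488-frame sessions at TR 0.8 s, the
#' per-group biomarker effect table (normative-SD units), the planted
#' mediation parameters and the true age curves. Validation errors name
#' the offending field.
#'
#' @param nNormative,nDAD,nAD,nControls Group sizes (defaults 724, 10, 8,
#'   5).
#' @param ageRange Age window in years, low < high (default c(36, 100)).
#' @param sessionsPerSubject Resting-state sessions per subject (default 4).
#' @param framesPerSession Frames per session before trimming (default 488).
#' @param tr Repetition time, seconds (default 0.8).
#' @param seed RNG seed (optional).
#' @param effectTable Group x biomarker matrix of mean Z-shifts.
#' @param effectSpread Between-subject SD (in normative-SD units) around
#'   each group shift (default 1; this is also the normative population
#'   SD).
#' @param mediationParams List `a` (hippocampal factor -> NFQ z),
#'   `b` (NFQ z -> recall score), `cprime` (direct), `sigmaM`, `sigmaY`.
#' @param curves True age curves per biomarker (`mu` quadratic
#'   coefficients on age-35, `sigma` linear).
#' @param ageSampler Optional function(n, low, high) overriding the
#'   uniform normative age density.
#' @return A validated `CohortConfig` list.
#' @export
cohortConfig <- function(nNormative = 724, nDAD = 10, nAD = 8,
                         nControls = 5, ageRange = c(36, 100),
                         sessionsPerSubject = 4, framesPerSession = 488,
                         tr = 0.8, seed = NULL,
                         effectTable = .defaultEffects(),
                         effectSpread = 1,
                         mediationParams = list(a = -0.25, b = -4,
                                                cprime = 5, sigmaM = NULL,
                                                sigmaY = 8),
                         curves = .defaultCurves(),
                         ageSampler = NULL) {
  chk <- function(cond, field, what)
    if (!cond) stop("invalid config field '", field, "': ", what,
                    call. = FALSE)
  for (f in c("nNormative", "nDAD", "nAD", "nControls"))
    chk(get(f) >= 0, f, "must be non-negative")
  chk(length(ageRange) == 2 && ageRange[1] < ageRange[2], "ageRange",
      "must be an increasing (low, high) pair")
  chk(tr > 0, "tr", "must be positive")
  chk(framesPerSession > 10, "framesPerSession", "must exceed 10")
  chk(sessionsPerSubject >= 1, "sessionsPerSubject", "must be at least 1")
  chk(all(nfqBiomarkers() %in% colnames(effectTable)), "effectTable",
      "must have one column per biomarker")
  if (is.null(mediationParams$sigmaM))
    mediationParams$sigmaM <- sqrt(max(1 - mediationParams$a^2, 0.01))
  structure(list(nNormative = nNormative, nDAD = nDAD, nAD = nAD,
                 nControls = nControls, ageRange = ageRange,
                 sessionsPerSubject = sessionsPerSubject,
                 framesPerSession = framesPerSession, tr = tr,
                 seed = seed, effectTable = effectTable,
                 effectSpread = effectSpread,
                 mediationParams = mediationParams, curves = curves,
                 ageSampler = ageSampler),
            class = "CohortConfig")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws subjects for the normative, dysexecutive (dAD), amnestic (AD)
#' and control groups with the statistical structure the downstream
#' analysis assumes: biomarker values follow the true age curves with
#' group shifts applied in normative-SD units; hippocampal Z-scores share
#' a common factor which drives the NFQ (mediator) and, together with the
#' NFQ, the recall score - planting a linear mediation structure; raw
#' hippocampal volumes are re-inflated with an ICV term so that ICV
#' correction is exercised downstream.
#'
#' @param config A [cohortConfig()] list.
#' @return List with `subjects` (one row per subject: demographics,
#'   cognition, SUVRs, raw structural values) and `truth` (per-subject
#'   true Z-scores, true NFQ, curves, effect table, mediation effects).
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  bio <- nfqBiomarkers()
  groups <- rep(c("normative", "dAD", "AD", "control"),
                c(config$nNormative, config$nDAD, config$nAD,
                  config$nControls))
  n <- length(groups)
  ids <- paste0(c(normative = "HCA", dAD = "dAD", AD = "AD",
                  control = "CU")[groups],
                stats::ave(seq_len(n), groups, FUN = seq_along))
  lo <- config$ageRange[1]; hi <- config$ageRange[2]
  sampler <- config$ageSampler %||%
    function(k, low, high) stats::runif(k, low, high)
  clampAge <- function(x) pmin(pmax(x, lo), hi)
  age <- numeric(n)
  age[groups == "normative"] <- sampler(sum(groups == "normative"), lo, hi)
  age[groups == "dAD"] <- clampAge(stats::rnorm(sum(groups == "dAD"), 59.5, 3))
  age[groups == "AD"] <- clampAge(stats::rnorm(sum(groups == "AD"), 73, 5))
  age[groups == "control"] <- clampAge(stats::rnorm(sum(groups == "control"), 65, 4))
  pFemale <- c(normative = 405 / 724, dAD = 0.7, AD = 0.25, control = 0.2)
  sex <- ifelse(stats::runif(n) < pFemale[groups], "F", "M")
  site <- ifelse(groups == "normative",
                 sample(c("MGH", "UCLA", "UMinn", "WashU"), n, replace = TRUE),
                 "Mayo")

  shift <- matrix(0, n, length(bio), dimnames = list(NULL, bio))
  pat <- groups %in% rownames(config$effectTable)
  shift[pat, ] <- config$effectTable[groups[pat], bio]

  mp <- config$mediationParams
  hippFactor <- stats::rnorm(n)               # shared L/R hippocampal factor
  loadH <- sqrt(0.7)
  z <- matrix(NA_real_, n, length(bio), dimnames = list(NULL, bio))
  z[, "left_hipp"] <- shift[, "left_hipp"] + config$effectSpread *
    (loadH * hippFactor + sqrt(1 - 0.7) * stats::rnorm(n))
  z[, "right_hipp"] <- shift[, "right_hipp"] + config$effectSpread *
    (loadH * hippFactor + sqrt(1 - 0.7) * stats::rnorm(n))
  z[, "nfq"] <- shift[, "nfq"] + config$effectSpread *
    (mp$a * hippFactor + mp$sigmaM * stats::rnorm(n))
  for (b in c("meta_roi", "inf_parietal"))
    z[, b] <- shift[, b] + config$effectSpread * stats::rnorm(n)

  trueValues <- sapply(bio, function(b) {
    cv <- config$curves[[b]]
    .evalMu(cv, age) + z[, b] * .evalSigma(cv, age)
  })

  # raw hippocampal volumes carry an ICV component removed downstream
  icv <- stats::rnorm(n, 1.45e6, 1.3e5)
  icvBeta <- 0.0025
  lhRaw <- trueValues[, "left_hipp"] + icvBeta * (icv - 1.45e6)
  rhRaw <- trueValues[, "right_hipp"] + icvBeta * (icv - 1.45e6)

  moca <- pmin(30, pmax(0, round(
    26.5 - 0.04 * (age - 35) +
      c(normative = 0, dAD = -16, AD = -15.5, control = 0)[groups] +
      stats::rnorm(n, 0, 1.5))))
  ravlt <- 60 - 0.25 * (age - 58.4) + mp$b * z[, "nfq"] +
    mp$cprime * hippFactor + stats::rnorm(n, 0, mp$sigmaY)
  ravlt <- pmin(75, pmax(0, ravlt))
  tmtb <- exp(4.15 + 0.012 * (age - 58.4) +
                0.35 * (0.45 * z[, "nfq"] +
                          sqrt(1 - 0.45^2) * stats::rnorm(n)))
  suvr <- function(mu, sd) pmax(1.0, stats::rnorm(n, mu, sd))
  amyloid <- ifelse(groups == "normative", NA_real_,
                    ifelse(groups == "dAD", suvr(2.4, 0.25),
                           ifelse(groups == "AD", suvr(2.6, 0.2),
                                  suvr(1.30, 0.01))))
  tau <- ifelse(groups == "normative", NA_real_,
                ifelse(groups == "dAD", suvr(2.2, 0.3),
                       ifelse(groups == "AD", suvr(1.9, 0.3),
                              suvr(1.21, 0.005))))

  subjects <- data.frame(
    id = ids, group = groups, age = age, sex = sex, site = site,
    moca = moca, ravlt_total = ravlt, tmtb = tmtb,
    amyloid_suvr = amyloid, tau_suvr = tau, icv = icv,
    meta_roi = trueValues[, "meta_roi"],
    left_hipp_vol = lhRaw, right_hipp_vol = rhRaw,
    inf_parietal = trueValues[, "inf_parietal"],
    stringsAsFactors = FALSE)
  truth <- list(z = z, trueValues = trueValues,
                trueNFQ = trueValues[, "nfq"],
                hippFactor = hippFactor, icvBeta = icvBeta,
                curves = config$curves, effectTable = config$effectTable,
                mediation = list(a = mp$a, b = mp$b, cprime = mp$cprime,
                                 acme = mp$a * mp$b,
                                 ade = mp$cprime,
                                 proportion = mp$a * mp$b /
                                   (mp$a * mp$b + mp$cprime)))
  list(subjects = subjects, truth = truth)
}

# ---- subsystem correlation structure ------------------------------------

#' Subsystem correlation matrix implying a target NFQ
#'
#' Builds a component-level correlation matrix (defaults: 2 components
#' per subsystem) whose cross-subsystem medians produce the requested
#' NFQ under the default formula: the pDMN-vDMN connectivity is fixed at
#' `denom`, the pDMN-avDMN and pDMN-adDMN connectivities each equal
#' `nfq * denom / 2`, remaining cross pairs sit at `offPair` and
#' within-subsystem correlations at `within`. If the construction is not
#' positive semi-definite it is projected (eigenvalue clipping +
#' rescaling) and the implied NFQ is recomputed from the projected
#' matrix, so the returned ground truth always matches the matrix in use.
#'
#' @param nfq Target NFQ.
#' @param nPerSubsystem Components per subsystem (default 2).
#' @param denom pDMN-vDMN connectivity (default 0.3).
#' @param within Within-subsystem correlation (default 0.5).
#' @param offPair Remaining cross-subsystem correlation (default 0.1).
#' @return List: `R` (correlation matrix), `labels` (component ->
#'   subsystem), `impliedNFQ`.
#' @export
subsystemCorrMatrix <- function(nfq, nPerSubsystem = 2, denom = 0.3,
                                within = 0.5, offPair = 0.1) {
  sys <- dmnSubsystems()
  labels <- stats::setNames(rep(sys, each = nPerSubsystem),
                            paste0(rep(sys, each = nPerSubsystem), "_",
                                   seq_len(nPerSubsystem)))
  k <- length(labels)
  pairVal <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "-")
    switch(key,
           "pDMN-vDMN" = denom,
           "avDMN-pDMN" = nfq * denom / 2,
           "adDMN-pDMN" = nfq * denom / 2,
           offPair)
  }
  R <- matrix(0, k, k, dimnames = list(names(labels), names(labels)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    R[i, j] <- if (i == j) 1
    else if (labels[i] == labels[j]) within
    else pairVal(labels[i], labels[j])
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
    dimnames(R) <- list(names(labels), names(labels))
  }
  implied <- computeNFQ(subsystemConnectivityFromMatrix(R, labels))
  list(R = R, labels = labels, impliedNFQ = implied)
}

#' Median subsystem connectivities implied by a correlation matrix
#'
#' Analytic counterpart of [subsystemConnectivity()]: medians of the
#' cross-subsystem entries of a component correlation matrix.
#'
#' @param R Component correlation matrix.
#' @param labels Component -> subsystem labels aligned with `R`.
#' @return data.frame `sysA`, `sysB`, `connectivity`.
#' @export
subsystemConnectivityFromMatrix <- function(R, labels) {
  combos <- utils::combn(unique(labels), 2, simplify = FALSE)
  do.call(rbind, lapply(combos, function(pr) {
    vals <- R[labels == pr[1], labels == pr[2]]
    data.frame(sysA = pr[1], sysB = pr[2],
               connectivity = stats::median(as.vector(vals)))
  }))
}

# ---- scans ---------------------------------------------------------------

#' Simulate a motion trace
#'
#' Baseline motion is a bounded random walk calibrated so the frame-wise
#' displacement stays below `baseline` (mm) at every frame; spikes are
#' additive translation steps with exponential magnitude occurring at a
#' per-frame rate.
#'
#' @param nFrames Frames.
#' @param baseline Baseline FD amplitude bound, mm (default 0.1).
#' @param spikeRate Per-frame spike probability (default 0).
#' @param spikeMag Mean spike magnitude, mm (default 0.5).
#' @return Frames x 6 motion matrix (mm, mm, mm, rad, rad, rad).
#' @export
simulateMotion <- function(nFrames, baseline = 0.1, spikeRate = 0,
                           spikeMag = 0.5) {
  bT <- 0.15 * baseline   # 3 translations: 3*bT = 0.45*baseline
  bR <- 0.003 * baseline  # 3 rotations at 50 mm: 150*bR = 0.45*baseline
  incT <- matrix(stats::runif(nFrames * 3, -bT, bT), nFrames, 3)
  incR <- matrix(stats::runif(nFrames * 3, -bR, bR), nFrames, 3)
  incT[1, ] <- 0; incR[1, ] <- 0
  if (spikeRate > 0) {
    hits <- which(stats::runif(nFrames) < spikeRate)
    hits <- hits[hits > 1]
    for (h in hits) {
      p <- sample(1:3, 1)
      incT[h, p] <- incT[h, p] +
        sample(c(-1, 1), 1) * stats::rexp(1, 1 / spikeMag)
    }
  }
  cbind(apply(incT, 2, cumsum), apply(incR, 2, cumsum))
}

#' Simulate one resting-state session
#'
#' Component signals are band-limited (white noise passed through the
#' same zero-phase band-pass operator the analysis side uses, so the
#' analysis filter cannot distort the planted structure), then mixed to
#' the target correlation matrix via its Cholesky square root. In volume
#' mode the courses are projected through the atlas maps, voxel noise is
#' added, nuisance signals are injected into the noise ROI, and a
#' motion-correlated artefact is spread over the brain.
#'
#' @param R Target component correlation matrix (components named).
#' @param nFrames Frames (default 488).
#' @param tr Repetition time, s.
#' @param mode `"timecourse"` or `"volume"`.
#' @param atlas [ComponentAtlas-class] with maps (required in volume
#'   mode); `noiseMask` taken from `atlasExtras`.
#' @param atlasExtras Optional list from [simulateAtlas()] providing
#'   `noiseMask` for volume mode.
#' @param band Frequency band of the synthesized signals, Hz.
#' @param motion Optional precomputed motion matrix; otherwise generated
#'   from `motionParams`.
#' @param motionParams List passed to [simulateMotion()].
#' @param voxelNoise Voxel noise SD (volume mode; default 0.05).
#' @param nuisanceAmp Amplitude of the injected noise-ROI signals
#'   (volume mode; default 1).
#' @param motionArtefact Amplitude of the motion-coupled artefact
#'   (volume mode; default 0.5).
#' @param empirical Match the realized (empirical) covariance of the
#'   component signals to `R` exactly rather than only in expectation
#'   (default TRUE; band-limited noise otherwise carries a large
#'   effective sampling error).
#' @return A [ScanSession-class].
#' @export
simulateScan <- function(R, nFrames = 488, tr = 0.8,
                         mode = c("timecourse", "volume"), atlas = NULL,
                         atlasExtras = NULL, band = c(0.009, 0.08),
                         motion = NULL,
                         motionParams = list(baseline = 0.1,
                                             spikeRate = 0,
                                             spikeMag = 0.5),
                         voxelNoise = 0.05, nuisanceAmp = 1,
                         motionArtefact = 0.5, empirical = TRUE) {
  mode <- match.arg(mode)
  if (mode == "volume")
    .stopIfNot(!is.null(atlas) && !is.null(atlasMaps(atlas)),
               "volume mode requires an atlas with spatial maps")
  k <- ncol(R)
  z <- matrix(stats::rnorm(nFrames * k), nFrames, k)
  z <- .bandpassFilter(z, band, tr)
  z <- .centerCols(z)
  # in-band Fourier degrees of freedom limit the realizable rank
  dof <- sum(pmin(0:(nFrames - 1), nFrames - 0:(nFrames - 1)) /
               (nFrames * tr) >= band[1] &
             pmin(0:(nFrames - 1), nFrames - 0:(nFrames - 1)) /
               (nFrames * tr) <= band[2])
  if (empirical && dof <= k) {
    warning("too few in-band frequency bins (", dof, ") for exact ",
            "covariance matching of ", k, " components; ",
            "falling back to expected-covariance mixing")
    empirical <- FALSE
  }
  if (empirical) {
    # exact second-moment matching: band-limited noise has a small
    # effective sample size, so whiten the realized covariance before
    # mixing (mvrnorm(empirical = TRUE) style)
    z <- z %*% backsolve(chol(stats::cov(z)), diag(k))
  } else z <- scale(z, center = FALSE, scale = apply(z, 2, stats::sd))
  courses <- z %*% chol(R)
  colnames(courses) <- colnames(R)
  if (is.null(motion))
    motion <- do.call(simulateMotion, c(list(nFrames = nFrames),
                                        motionParams))
  if (mode == "timecourse")
    return(ScanSession(courses, tr = tr, motion = motion))

  .stopIfNot(!is.null(atlas) && !is.null(atlasMaps(atlas)),
             "volume mode requires an atlas with spatial maps")
  maps <- atlasMaps(atlas)
  d <- dim(maps)
  v <- prod(d[1:3])
  mapMat <- matrix(maps, v, d[4])
  vol <- mapMat %*% t(courses)                       # voxels x frames
  if (voxelNoise > 0)
    vol <- vol + matrix(stats::rnorm(v * nFrames, 0, voxelNoise),
                        v, nFrames)
  noiseMask <- atlasExtras$noiseMask
  if (!is.null(noiseMask) && nuisanceAmp > 0) {
    tt <- seq_len(nFrames) * tr
    nsig <- rbind(sin(2 * pi * 0.003 * tt), cos(2 * pi * 0.11 * tt))
    idx <- which(as.vector(noiseMask))
    w <- matrix(stats::runif(length(idx) * 2, 0.5, 1.5), length(idx), 2)
    vol[idx, ] <- vol[idx, ] + nuisanceAmp * (w %*% nsig)
  }
  if (motionArtefact > 0) {
    fd <- framewiseDisplacement(motion)
    pattern <- stats::runif(v, 0, 1)
    vol <- vol + motionArtefact * outer(pattern, fd - mean(fd))
  }
  ScanSession(array(vol, c(d[1:3], nFrames)), tr = tr, motion = motion,
              mode = "volume", noiseMask = noiseMask)
}

#' Simulate a component atlas on a desk-scale grid
#'
#' Gaussian-blob spatial maps for two components per DMN subsystem on a
#' small grid, plus CSF/WM probability images defining a noise region
#' away from the blobs.
#'
#' @param dim Grid dimensions (default c(30, 36, 30)).
#' @param voxelSize Voxel size in mm (default 2.9 isotropic).
#' @param nPerSubsystem Components per subsystem (default 2).
#' @param sigmaVox Blob SD in voxels (default 2.5).
#' @return List: `atlas` ([ComponentAtlas-class]), `csfProb`, `wmProb`,
#'   `noiseMask` (the 0.9-threshold, 2-voxel-eroded ROI).
#' @export
simulateAtlas <- function(dim = c(30, 36, 30), voxelSize = c(2.9, 2.9, 2.9),
                          nPerSubsystem = 2, sigmaVox = 2.5) {
  sys <- dmnSubsystems()
  k <- length(sys) * nPerSubsystem
  labels <- stats::setNames(rep(sys, each = nPerSubsystem),
                            paste0(rep(sys, each = nPerSubsystem), "_",
                                   seq_len(nPerSubsystem)))
  # deterministic centres: subsystems in the four x-y quadrants of the
  # upper half of the grid (the lower-corner box hosts the noise ROI)
  qx <- c(0.3, 0.3, 0.7, 0.7); qy <- c(0.3, 0.7, 0.3, 0.7)
  zs <- seq(0.45, 0.8, length.out = nPerSubsystem)
  maps <- array(0, c(dim, k))
  gx <- seq_len(dim[1]); gy <- seq_len(dim[2]); gz <- seq_len(dim[3])
  ci <- 0
  for (s in seq_along(sys)) for (j in seq_len(nPerSubsystem)) {
    ci <- ci + 1
    cx <- qx[s] * dim[1]; cy <- qy[s] * dim[2]; cz <- zs[j] * dim[3]
    blob <- outer(outer(exp(-(gx - cx)^2 / (2 * sigmaVox^2)),
                        exp(-(gy - cy)^2 / (2 * sigmaVox^2))),
                  exp(-(gz - cz)^2 / (2 * sigmaVox^2)))
    blob[blob < 1e-4] <- 0
    maps[, , , ci] <- blob
  }
  csf <- array(0, dim); wm <- array(0, dim)
  wm[2:10, 2:10, 2:8] <- 1
  csf[2:10, 2:10, 9:12] <- 1
  noiseMask <- buildNoiseRoi(csf, wm)
  list(atlas = ComponentAtlas(labels, maps = maps, voxelSize = voxelSize),
       csfProb = csf, wmProb = wm, noiseMask = noiseMask)
}

#' Simulate data with a planted linear mediation structure
#'
#' `X ~ N(0, 1)`, `M = a X + N(0, sigmaM)`,
#' `Y = b M + cprime X + N(0, sigmaY)`; the true ACME is `a * b`, the ADE
#' `cprime` and the proportion mediated `a b / (a b + cprime)`.
#'
#' @param n Subjects.
#' @param a,b,cprime Planted path coefficients.
#' @param sigmaM,sigmaY Error SDs (defaults 1).
#' @return List: `data` (X, M, Y), `truth` (acme, ade, total,
#'   proportion).
#' @export
simulateMediationData <- function(n, a = 0.5, b = 2, cprime = 1,
                                  sigmaM = 1, sigmaY = 1) {
  X <- stats::rnorm(n)
  M <- a * X + stats::rnorm(n, 0, sigmaM)
  Y <- b * M + cprime * X + stats::rnorm(n, 0, sigmaY)
  list(data = data.frame(X = X, M = M, Y = Y),
       truth = list(acme = a * b, ade = cprime, total = a * b + cprime,
                    proportion = a * b / (a * b + cprime)))
}
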