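#' Remove initial frames from a session
#'
#' Drops the first `n` frames from the data and the motion trace; resting
#' acquisitions discard initial volumes to let the signal reach steady state.
#'
#' @param session A [ScanSession-class].
#' @param n Number of leading frames to remove (default 10).
#' @return The trimmed [ScanSession-class].
#' @export
trimInitialFrames <- function(session, n = 10) {
  tn <- nFrames(session)
  .stopIfNot(n >= 0, "n must be non-negative")
  if (tn <= n)
    stop("cannot trim ", n, " frames from a ", tn, "-frame session",
         call. = FALSE)
  if (n == 0) return(session)
  keep <- (n + 1):tn
  dat <- if (session@mode == "timecourse") session@data[keep, , drop = FALSE]
         else session@data[, , , keep, drop = FALSE]
  initialize(session, data = dat,
             motion = session@motion[keep, , drop = FALSE])
}

#' Build an anatomical noise ROI from tissue probability maps
#'
#' Binarizes CSF and white-matter probability images at a probability
#' threshold (inclusive, `>=`) and erodes the union with a 6-connected
#' structuring element, applied `erosion` times, to avoid grey-matter
#' contamination.
#'
#' @param csfProb,wmProb 3-D probability arrays in \[0, 1\] on the session
#'   grid.
#' @param threshold Probability threshold (default 0.9).
#' @param erosion Number of one-voxel erosion passes (default 2).
#' @return Logical 3-D mask.
#' @export
buildNoiseRoi <- function(csfProb, wmProb, threshold = 0.9, erosion = 2) {
  .stopIfNot(identical(dim(csfProb), dim(wmProb)),
             "probability images must share a grid")
  .stopIfNot(all(csfProb >= 0 & csfProb <= 1) && all(wmProb >= 0 & wmProb <= 1),
             "probability values must lie in [0, 1]")
  mask <- (csfProb >= threshold) | (wmProb >= threshold)
  if (!any(mask))
    stop("no voxel reaches the ", threshold, " probability threshold",
         call. = FALSE)
  for (i in seq_len(erosion)) mask <- .erode6(mask)
  if (!any(mask))
    stop("noise ROI empty after ", erosion,
         "-voxel erosion; use a smaller erosion on this grid", call. = FALSE)
  mask
}

# one 6-connected erosion pass; outside the grid counts as background
.erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[axis]] <- idx[[axis]] + by
    keep <- src[[axis]] >= 1 & src[[axis]] <= d[axis]
    res <- array(FALSE, d)
    dst <- idx; dst[[axis]] <- idx[[axis]][keep]
    src[[axis]] <- src[[axis]][keep]
    res[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(mask, ax, by)
  out
}

#' Principal-component noise regressors from a noise ROI
#'
#' Extracts voxel time series from the mask and returns the top-`k`
#' principal-component time courses (aCompCor-style): voxels are centred
#' over time and the left singular vectors of the frames x voxels matrix,
#' ordered by explained variance, are rescaled to unit variance.
#'
#' @param session A volume-mode [ScanSession-class].
#' @param mask Logical 3-D noise mask.
#' @param k Number of components (default 6); `k = 0` returns a 0-column
#'   matrix.
#' @return Frames x `k` matrix of component time courses.
#' @export
noiseComponents <- function(session, mask, k = 6) {
  .stopIfNot(session@mode == "volume", "noise components need a volume-mode session")
  .stopIfNot(any(mask), "noise mask is empty")
  d <- dim(session@data)
  tn <- d[4]
  x <- matrix(session@data, prod(d[1:3]), tn)[as.vector(mask), , drop = FALSE]
  x <- t(x)                               # frames x voxels
  x <- .centerCols(x)
  if (k == 0) return(matrix(0, tn, 0))
  sv <- svd(x, nu = min(tn, ncol(x)), nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > rank)
    stop("requested ", k, " noise components but masked data has rank ",
         rank, call. = FALSE)
  comps <- sv$u[, seq_len(k), drop = FALSE]
  sweep(comps, 2, apply(comps, 2, stats::sd), "/")
}

#' Assemble the nuisance regression matrix
#'
#' Columns are the six motion parameters, their backward-difference first
#' temporal derivatives (first row zero), and the noise-ROI principal
#' components; all columns are centred.
#'
#' @param motion Frames x 6 motion-parameter matrix.
#' @param noiseComps Optional frames x k noise-component matrix.
#' @return Frames x (12 + k) centred design matrix.
#' @export
buildNuisanceMatrix <- function(motion, noiseComps = NULL) {
  motion <- as.matrix(motion)
  if (!is.null(noiseComps) && nrow(noiseComps) != nrow(motion))
    stop("motion and noise components have different frame counts",
         call. = FALSE)
  deriv <- rbind(0, diff(motion))
  out <- cbind(motion, deriv, noiseComps)
  colnames(out) <- c(paste0("mot", 1:6), paste0("dmot", 1:6),
                     if (!is.null(noiseComps) && ncol(noiseComps) > 0)
                       paste0("comp", seq_len(ncol(noiseComps))))
  .centerCols(out)
}

# shared zero-phase band-pass operator. Frequency-domain (FFT) mask, the
# realization used by the standard resting-state band-pass tools: exactly
# zero phase, idempotent (re-filtering an already band-limited series is
# the identity), with pass/stop-band behaviour set by the bin mask. The
# same operator is applied to data and nuisance regressors.
.bandpassFilter <- function(x, band, tr) {
  tn <- nrow(x)
  k <- 0:(tn - 1)
  freq <- pmin(k, tn - k) / (tn * tr)
  mask <- freq >= band[1] & freq <= band[2]
  ft <- stats::mvfft(x)
  Re(stats::mvfft(ft * mask, inverse = TRUE)) / tn
}

#' Simultaneous band-pass filtering and nuisance regression
#'
#' Linearly detrends the series, applies the same zero-phase band-pass
#' filter to both the data and the nuisance regressors, regresses the
#' filtered nuisance out of the filtered data by least squares, and
#' variance-normalizes each output column. Filtering data and regressors
#' identically avoids spectral misspecification of motion artefact.
#'
#' @param series Frames x m data matrix (component courses or voxel series).
#' @param nuisance Optional frames x p nuisance matrix.
#' @param band Pass band in Hz (default `c(0.009, 0.08)`).
#' @param tr Repetition time, seconds.
#' @param normalize Scale output columns to unit variance (default TRUE).
#' @return Frames x m cleaned matrix.
#' @export
bandpassAndRegress <- function(series, nuisance = NULL,
                               band = c(0.009, 0.08), tr = 0.8,
                               normalize = TRUE) {
  series <- as.matrix(series)
  .stopIfNot(all(is.finite(series)), "series must be finite")
  nyq <- 1 / (2 * tr)
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] || band[2] >= nyq)
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  y <- .bandpassFilter(.detrendCols(series), band, tr)
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0) {
    x <- .bandpassFilter(.detrendCols(as.matrix(nuisance)), band, tr)
    x <- .centerCols(x)
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      drop <- qx$pivot[seq.int(qx$rank + 1, ncol(x))]
      warning("dropping ", length(drop),
              " linearly dependent nuisance column(s): ",
              paste(colnames(x)[drop] %||% drop, collapse = ", "))
      x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(x)
    }
    y <- y - x %*% qr.coef(qx, y)
  }
  if (normalize) {
    sds <- apply(y, 2, stats::sd)
    pos <- sds > 0
    y[, pos] <- sweep(y[, pos, drop = FALSE], 2, sds[pos], "/")
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian smoothing of a volume series
#'
#' Per-frame separable Gaussian smoothing with
#' sigma = FWHM / (2 sqrt(2 ln 2)) per axis in mm, converted to voxels by
#' the voxel size; kernels are normalized so interior mass is preserved
#' (zero padding at the boundary).
#'
#' @param series 4-D array (x, y, z, frames) or 3-D single volume.
#' @param fwhm Full width at half maximum, mm.
#' @param voxelSize Voxel edge lengths, mm (length 3).
#' @return Smoothed array of the same shape.
#' @export
smoothVolumes <- function(series, fwhm, voxelSize = c(1, 1, 1)) {
  .stopIfNot(fwhm >= 0, "fwhm must be non-negative")
  if (fwhm == 0) return(series)
  single <- length(dim(series)) == 3L
  if (single) dim(series) <- c(dim(series), 1L)
  d <- dim(series)
  sigmaMM <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sig <- sigmaMM / voxelSize[ax]
    r <- max(1L, ceiling(4 * sig))
    kern <- stats::dnorm(-r:r, sd = sig)
    kern <- kern / sum(kern)
    n <- d[ax]
    cm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      cm[i, j] <- kern[j - i + r + 1]
    }
    series <- .applyAlongAxis(series, cm, ax)
  }
  if (single) dim(series) <- d[1:3]
  series
}

# multiply a convolution matrix along one spatial axis of a 4-D array
.applyAlongAxis <- function(arr, cm, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:4, axis))
  ap <- aperm(arr, perm)
  m <- matrix(ap, d[axis], prod(d[-axis]))
  m <- cm %*% m
  ap <- array(m, d[perm])
  aperm(ap, order(perm))
}

#' Dual (spatial-temporal) regression
#'
#' For each frame, regresses the voxel vector jointly on all atlas maps
#' (multivariate spatial regression with an intercept; maps are centred
#' over in-brain voxels) and returns the per-component coefficient time
#' series.
#'
#' @param series 4-D array (x, y, z, frames) on the atlas grid.
#' @param atlas A [ComponentAtlas-class] with spatial maps.
#' @param mask Optional logical 3-D in-brain mask; defaults to voxels where
#'   any map is non-zero.
#' @return Frames x K matrix of component time courses (columns named by
#'   component).
#' @export
dualRegression <- function(series, atlas, mask = NULL) {
  maps <- atlasMaps(atlas)
  .stopIfNot(!is.null(maps), "atlas has no spatial maps")
  d <- dim(series)
  if (!identical(d[1:3], dim(maps)[1:3]))
    stop("series grid ", paste(d[1:3], collapse = "x"),
         " does not match atlas grid ",
         paste(dim(maps)[1:3], collapse = "x"), call. = FALSE)
  k <- nComponents(atlas)
  v <- prod(d[1:3])
  mapMat <- matrix(maps, v, k)
  if (is.null(mask)) mask <- rowSums(abs(mapMat)) > 0
  else mask <- as.vector(mask)
  mm <- .centerCols(mapMat[mask, , drop = FALSE])
  qx <- qr(cbind(1, mm))
  if (qx$rank < k + 1) {
    piv <- qx$pivot[seq.int(qx$rank + 1, k + 1)] - 1L
    stop("collinear atlas maps: ",
         paste(names(componentLabels(atlas))[piv], collapse = ", "),
         call. = FALSE)
  }
  y <- matrix(series, v, d[4])[mask, , drop = FALSE]
  beta <- qr.coef(qx, y)                     # (K+1) x frames
  out <- t(beta[-1, , drop = FALSE])
  colnames(out) <- names(componentLabels(atlas))
  out
}

#' Median inter-subsystem connectivity
#'
#' Pearson-correlates every cross pair of component courses between two
#' subsystems and takes the median per unordered subsystem pair.
#' Same-subsystem pairs are excluded by default (they do not enter the
#' NFQ) but can be requested.
#'
#' @param courses Frames x K matrix of component time courses.
#' @param labels Named character vector component -> subsystem, aligned
#'   with the columns of `courses` (by name when both are named).
#' @param includeSame Also compute within-subsystem medians (default FALSE).
#' @return data.frame with columns `sysA`, `sysB`, `connectivity`, `nPairs`.
#' @export
subsystemConnectivity <- function(courses, labels, includeSame = FALSE) {
  .stopIfNot(nrow(courses) >= 3, "need at least 3 frames")
  .stopIfNot(ncol(courses) == length(labels),
             "one label per course column is required")
  if (!is.null(colnames(courses)) && !is.null(names(labels)))
    labels <- labels[colnames(courses)]
  sds <- apply(courses, 2, stats::sd)
  dead <- sds == 0
  if (any(dead))
    warning("excluding zero-variance course(s): ",
            paste(which(dead), collapse = ", "))
  cc <- suppressWarnings(stats::cor(courses))
  systems <- unique(labels)
  combos <- utils::combn(systems, 2, simplify = FALSE)
  if (includeSame) combos <- c(combos, lapply(systems, function(s) c(s, s)))
  rows <- lapply(combos, function(pr) {
    ia <- which(labels == pr[1] & !dead)
    ib <- which(labels == pr[2] & !dead)
    vals <- if (pr[1] == pr[2]) {
      if (length(ia) < 2) numeric() else cc[t(utils::combn(ia, 2))]
    } else as.vector(cc[ia, ib])
    data.frame(sysA = pr[1], sysB = pr[2],
               connectivity = if (length(vals)) stats::median(vals) else NA_real_,
               nPairs = length(vals))
  })
  out <- do.call(rbind, rows)
  empty <- is.na(out$connectivity) & out$sysA != out$sysB
  if (any(empty))
    stop("no usable component pair for subsystem pair(s): ",
         paste(paste(out$sysA[empty], out$sysB[empty], sep = "-"),
               collapse = ", "), call. = FALSE)
  out
}

#' Network failure quotient
#'
#' The NFQ summarizes DMN disruption as a ratio of median inter-subsystem
#' connectivities. The default formula is
#' \deqn{NFQ = [m(pDMN,avDMN) + m(pDMN,adDMN)] / m(pDMN,vDMN)}
#' with a `"literal"` variant \eqn{[m(pDMN,vDMN) + m(pDMN,adDMN)] /
#' m(pDMN,vDMN)}; the numerator and denominator pair sets are fully
#' configurable. Higher values indicate greater disruption of posterior
#' DMN connectivity relative to its ventral anchor.
#'
#' @param pairs A `data.frame` as returned by [subsystemConnectivity()] or
#'   a [ConnectivityProfile-class].
#' @param variant `"avDMN"` (default) or `"literal"`; ignored when
#'   `numerator`/`denominator` are given.
#' @param numerator List of length-2 character vectors naming the numerator
#'   subsystem pairs.
#' @param denominator Length-2 character vector naming the denominator pair.
#' @param eps Denominators with absolute value below `eps` make the NFQ
#'   undefined (`NA` with a warning; default 1e-6).
#' @return The NFQ (numeric scalar, possibly `NA`).
#' @examples
#' p <- data.frame(sysA = "pDMN", sysB = c("avDMN", "adDMN", "vDMN"),
#'                 connectivity = c(0.3, 0.2, 0.25))
#' computeNFQ(p)   # (0.3 + 0.2) / 0.25 = 2
#' @export
computeNFQ <- function(pairs, variant = c("avDMN", "literal"),
                       numerator = NULL, denominator = NULL, eps = 1e-6) {
  variant <- match.arg(variant)
  if (is(pairs, "ConnectivityProfile")) pairs <- pairs@pairs
  if (is.null(numerator))
    numerator <- if (variant == "avDMN")
      list(c("pDMN", "avDMN"), c("pDMN", "adDMN"))
    else list(c("pDMN", "vDMN"), c("pDMN", "adDMN"))
  if (is.null(denominator)) denominator <- c("pDMN", "vDMN")
  lookup <- function(pr) {
    hit <- (pairs$sysA == pr[1] & pairs$sysB == pr[2]) |
           (pairs$sysA == pr[2] & pairs$sysB == pr[1])
    if (!any(hit))
      stop("pair ", pr[1], "-", pr[2], " missing from connectivity table",
           call. = FALSE)
    pairs$connectivity[which(hit)[1]]
  }
  den <- lookup(denominator)
  if (!is.finite(den) || abs(den) < eps) {
    warning("NFQ undefined: |denominator| < ", eps)
    return(NA_real_)
  }
  sum(vapply(numerator, lookup, numeric(1))) / den
}

#' Per-session connectivity profile
#'
#' Convenience wrapper running the per-session pipeline: frame trimming,
#' (volume mode only) noise-ROI components, nuisance assembly, simultaneous
#' band-pass + nuisance regression, (volume mode) smoothing and dual
#' regression, then median subsystem connectivities and the NFQ.
#'
#' @param session A [ScanSession-class].
#' @param atlas A [ComponentAtlas-class] (labels; maps in volume mode).
#' @param nTrim Leading frames to discard (default 10).
#' @param band Pass band, Hz.
#' @param k Noise components (volume mode; default 6).
#' @param fwhm Smoothing FWHM in mm applied before dual regression in
#'   volume mode (default 0 = none).
#' @param variant,eps Passed to [computeNFQ()].
#' @return A [ConnectivityProfile-class] for the session.
#' @export
sessionProfile <- function(session, atlas, nTrim = 10,
                           band = c(0.009, 0.08), k = 6, fwhm = 0,
                           variant = "avDMN", eps = 1e-6) {
  ses <- trimInitialFrames(session, nTrim)
  if (ses@mode == "volume") {
    comps <- if (!is.null(ses@noiseMask) && k > 0)
      noiseComponents(ses, ses@noiseMask, k) else NULL
    nuis <- buildNuisanceMatrix(scanMotion(ses), comps)
    d <- dim(ses@data)
    vox <- t(matrix(ses@data, prod(d[1:3]), d[4]))
    cleaned <- bandpassAndRegress(vox, nuis, band, scanTR(ses),
                                  normalize = TRUE)
    vol <- array(t(cleaned), d)
    if (fwhm > 0) vol <- smoothVolumes(vol, fwhm, atlas@voxelSize)
    courses <- dualRegression(vol, atlas)
  } else {
    nuis <- buildNuisanceMatrix(scanMotion(ses))
    courses <- bandpassAndRegress(scanData(ses), nuis, band, scanTR(ses))
    colnames(courses) <- colnames(scanData(ses))
  }
  pairs <- subsystemConnectivity(courses, componentLabels(atlas))
  nfq <- computeNFQ(pairs, variant = variant, eps = eps)
  new("ConnectivityProfile", pairs = pairs, nfq = nfq,
      perSession = list(), nSessionsUsed = 1L)
}

#' Average connectivity profiles across sessions
#'
#' Arithmetic mean of the NFQ and of each pair connectivity over
#' QC-passing sessions.
#'
#' @param profiles List of per-session [ConnectivityProfile-class] objects.
#' @param included Logical vector of QC decisions (default: all passing).
#' @return Averaged [ConnectivityProfile-class], or `NULL` (with a warning)
#'   when no session passes: missing data are never fabricated.
#' @export
averageSessions <- function(profiles, included = NULL) {
  if (is.null(included)) included <- rep(TRUE, length(profiles))
  .stopIfNot(length(included) == length(profiles),
             "one QC flag per session is required")
  keep <- profiles[included]
  if (length(keep) == 0) {
    warning("no QC-passing session; subject flagged missing")
    return(NULL)
  }
  nfqs <- vapply(keep, nfqValue, numeric(1))
  if (anyNA(nfqs)) {
    warning("dropping ", sum(is.na(nfqs)), " session(s) with undefined NFQ")
    keep <- keep[!is.na(nfqs)]
    nfqs <- nfqs[!is.na(nfqs)]
    if (!length(keep)) {
      warning("no session with a defined NFQ; subject flagged missing")
      return(NULL)
    }
  }
  base <- keep[[1]]@pairs[, c("sysA", "sysB")]
  vals <- vapply(keep, function(p) {
    vapply(seq_len(nrow(base)), function(i)
      pairConnectivity(p, base$sysA[i], base$sysB[i]), numeric(1))
  }, numeric(nrow(base)))
  conn <- rowMeans(matrix(vals, nrow = nrow(base)))
  new("ConnectivityProfile",
      pairs = cbind(base, connectivity = conn, nPairs = NA_integer_),
      nfq = mean(nfqs), perSession = keep,
      nSessionsUsed = length(keep))
}

#' Intra-class correlation across sessions
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (ICC(2,1)) from the standard mean-squares decomposition, used to check
#' session-to-session consistency of connectivity metrics. A
#' consistency-form ICC(3,1) is available as an option.
#'
#' @param values Subjects x sessions numeric matrix; rows with missing
#'   values are dropped (listwise deletion).
#' @param type `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return The ICC (numeric scalar).
#' @export
sessionICC <- function(values, type = c("ICC2_1", "ICC3_1")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  .stopIfNot(n >= 2 && k >= 2, "need at least 2 subjects and 2 sessions")
  grand <- mean(values)
  ssTot <- sum((values - grand)^2)
  if (ssTot < .Machine$double.eps * n * k)
    stop("zero total variance: ICC undefined", call. = FALSE)
  rowm <- rowMeans(values); colm <- colMeans(values)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- ssTot - k * sum((rowm - grand)^2) - n * sum((colm - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC2_1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}
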