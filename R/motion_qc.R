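#' Frame-wise displacement
#'
#' Power-style FD: per frame, the sum of absolute backward differences of
#' the three translations (mm) plus the rotational differences (radians)
#' scaled by a head radius. The first frame has FD 0 by convention.
#'
#' @param motion Frames x 6 matrix: translations x/y/z in mm, rotations
#'   pitch/yaw/roll in radians.
#' @param radius Rotational lever arm in mm (default 50).
#' @return Numeric vector of per-frame FD values (mm).
#' @export
framewiseDisplacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  .stopIfNot(nrow(motion) >= 2, "FD needs at least 2 frames")
  .stopIfNot(ncol(motion) == 6, "motion must have 6 columns")
  if (!all(is.finite(motion))) stop("non-finite motion parameters", call. = FALSE)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Scan-level FD filter
#'
#' Retains a scan iff its summary FD (mean by default) is strictly below
#' the threshold, and reports how many scans were removed and which
#' subjects lost every scan.
#'
#' @param scans data.frame with columns `subject`, `scan` and either
#'   `mean_fd` or a list-column of motion matrices; alternatively a named
#'   numeric vector of per-scan summary FD values.
#' @param threshold FD threshold in mm (default 0.25).
#' @param stat Summary applied per scan when raw FD series are supplied:
#'   `"mean"` (default), `"median"` or `"max"`.
#' @param subjects Optional subject id per scan (for the lost-subject
#'   summary when `scans` is a numeric vector).
#' @return List: `decisions` (data.frame scan, subject, fd, included),
#'   `nRemoved`, `nScans`, `subjectsLost`.
#' @export
fdScanFilter <- function(scans, threshold = 0.25,
                         stat = c("mean", "median", "max"),
                         subjects = NULL) {
  stat <- match.arg(stat)
  if (is.data.frame(scans)) {
    fd <- scans$mean_fd
    subjects <- scans$subject
    ids <- scans$scan %||% seq_len(nrow(scans))
  } else {
    fd <- as.numeric(scans)
    ids <- names(scans) %||% seq_along(fd)
    if (is.null(subjects)) subjects <- rep(NA_character_, length(fd))
  }
  included <- fd < threshold
  lost <- unique(subjects[!is.na(subjects)])
  lost <- lost[vapply(lost, function(s) !any(included[subjects == s]),
                      logical(1))]
  list(decisions = data.frame(scan = ids, subject = subjects, fd = fd,
                              included = included,
                              stringsAsFactors = FALSE),
       nRemoved = sum(!included), nScans = length(fd),
       subjectsLost = lost)
}

#' Per-scan summary FD
#'
#' @param motion Frames x 6 motion matrix.
#' @param stat `"mean"`, `"median"` or `"max"`.
#' @param radius Rotational radius in mm.
#' @return Scalar summary FD (mm).
#' @export
summaryFD <- function(motion, stat = c("mean", "median", "max"), radius = 50) {
  stat <- match.arg(stat)
  fd <- framewiseDisplacement(motion, radius)
  switch(stat, mean = mean(fd), median = stats::median(fd), max = max(fd))
}

#' Gross-motion exclusion rule
#'
#' Excludes a scan when any translation exceeds the limit in mm
#' peak-to-peak, or any rotation exceeds the same limit expressed in
#' degrees (rotations are stored in radians and converted; a 2-radian
#' threshold would be physically implausible).
#'
#' @param motion Frames x 6 motion matrix (mm, radians).
#' @param limit Peak-to-peak limit, mm for translations and degrees for
#'   rotations (default 2).
#' @return List: `included` flag, `maxRange` per-parameter peak-to-peak
#'   ranges (mm / degrees), `ruleTriggered`.
#' @export
grossMotionFilter <- function(motion, limit = 2) {
  motion <- as.matrix(motion)
  .stopIfNot(all(is.finite(motion)), "motion trace must be finite")
  rng <- apply(motion, 2, function(x) diff(range(x)))
  rng[4:6] <- rng[4:6] * 180 / pi
  names(rng) <- c("x", "y", "z", "pitch", "yaw", "roll")
  bad <- rng > limit
  list(included = !any(bad), maxRange = rng,
       ruleTriggered = if (any(bad)) "gross_motion" else "none")
}

#' Full QC decision for one scan
#'
#' Applies the FD-threshold rule and, optionally, the gross-motion rule.
#' An excluded scan carries exactly one triggering rule (the FD rule takes
#' precedence).
#'
#' @param motion Frames x 6 motion matrix.
#' @param fdThreshold Mean-FD threshold in mm (default 0.25).
#' @param grossLimit Gross-motion limit (default 2); `NULL` disables the
#'   rule.
#' @param stat FD summary statistic per scan.
#' @return List: `included`, `meanFD`, `ruleTriggered`.
#' @export
qcScan <- function(motion, fdThreshold = 0.25, grossLimit = 2,
                   stat = "mean") {
  fd <- summaryFD(motion, stat)
  if (fd >= fdThreshold)
    return(list(included = FALSE, meanFD = fd, ruleTriggered = "fd_threshold"))
  if (!is.null(grossLimit)) {
    gm <- grossMotionFilter(motion, grossLimit)
    if (!gm$included)
      return(list(included = FALSE, meanFD = fd,
                  ruleTriggered = "gross_motion"))
  }
  list(included = TRUE, meanFD = fd, ruleTriggered = "none")
}
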