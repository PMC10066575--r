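#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Canonical DMN subsystem labels
#'
#' The default mode network is decomposed into posterior (pDMN), ventral
#' (vDMN), anterior ventral (avDMN) and anterior dorsal (adDMN) subsystems.
#' Component atlases may label components with any of these (or additional,
#' user-defined) subsystems; the network failure quotient uses the four
#' canonical ones.
#'
#' @return Character vector of subsystem names.
#' @export
dmnSubsystems <- function() c("pDMN", "vDMN", "avDMN", "adDMN")

#' ComponentAtlas: labelled spatial component maps
#'
#' Holds per-component voxel weight maps on a shared grid together with a
#' subsystem label per component. In time-course mode (component time series
#' supplied directly) the maps may be absent and only the labels are used.
#'
#' @slot maps 4-D array (x, y, z, component) of voxel weights, or `NULL`.
#' @slot labels Named character vector mapping component id to subsystem.
#' @slot voxelSize Numeric length-3 voxel edge lengths in mm.
#'
#' @export
setClass("ComponentAtlas",
  representation(maps = "arrayOrNULL", labels = "character",
                 voxelSize = "numeric"),
  prototype(maps = NULL, labels = character(), voxelSize = c(1, 1, 1)))

setValidity("ComponentAtlas", function(object) {
  msg <- character()
  if (length(object@labels) == 0L)
    msg <- c(msg, "atlas must label at least one component")
  if (is.null(names(object@labels)) || anyNA(names(object@labels)) ||
      any(names(object@labels) == ""))
    msg <- c(msg, "labels must be named by component id")
  if (anyDuplicated(names(object@labels)))
    msg <- c(msg, "a component cannot carry two labels")
  if (!is.null(object@maps)) {
    if (length(dim(object@maps)) != 4L)
      msg <- c(msg, "maps must be a 4-D array (x, y, z, component)")
    else if (dim(object@maps)[4] != length(object@labels))
      msg <- c(msg, "number of maps must equal number of labels")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a ComponentAtlas
#'
#' @param labels Named character vector: component id -> subsystem.
#' @param maps Optional 4-D array (x, y, z, component) of spatial weights.
#' @param voxelSize Voxel edge lengths in mm (length 3).
#' @return A [ComponentAtlas-class] object.
#' @examples
#' atl <- ComponentAtlas(c(c1 = "pDMN", c2 = "vDMN"))
#' componentLabels(atl)
#' @export
ComponentAtlas <- function(labels, maps = NULL, voxelSize = c(1, 1, 1)) {
  new("ComponentAtlas", maps = maps, labels = labels,
      voxelSize = as.numeric(voxelSize))
}

#' ScanSession: one resting-state run
#'
#' A single resting-state acquisition, either as component time courses
#' (frames x components matrix) or as a 4-D volume series
#' (x, y, z, frames), with its repetition time, motion trace and QC state.
#'
#' @slot mode `"timecourse"` or `"volume"`.
#' @slot data Frames x components matrix, or 4-D array with frames last.
#' @slot tr Repetition time in seconds.
#' @slot motion Frames x 6 matrix: translations x/y/z (mm) then rotations
#'   pitch/yaw/roll (radians).
#' @slot noiseMask Logical 3-D array marking WM/CSF noise voxels (volume
#'   mode), or `NULL`.
#' @slot qc List with elements `included` (logical) and `reason` (character).
#'
#' @export
setClass("ScanSession",
  representation(mode = "character", data = "ANY", tr = "numeric",
                 motion = "matrix", noiseMask = "arrayOrNULL", qc = "list"),
  prototype(mode = "timecourse", tr = 0.8,
            qc = list(included = TRUE, reason = "none")))

setValidity("ScanSession", function(object) {
  msg <- character()
  if (!object@mode %in% c("timecourse", "volume"))
    msg <- c(msg, "mode must be 'timecourse' or 'volume'")
  tn <- nFrames(object)
  if (tn <= 10L) msg <- c(msg, "a session needs more than 10 frames")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive (seconds)")
  if (nrow(object@motion) != tn)
    msg <- c(msg, "motion trace length must equal frame count")
  if (ncol(object@motion) != 6L)
    msg <- c(msg, "motion trace must have 6 columns")
  if (!all(is.finite(object@motion)))
    msg <- c(msg, "motion trace must be finite")
  if (object@mode == "timecourse" && !is.matrix(object@data))
    msg <- c(msg, "timecourse data must be a frames x components matrix")
  if (object@mode == "volume" && length(dim(object@data)) != 4L)
    msg <- c(msg, "volume data must be a 4-D array with frames last")
  if (length(msg)) msg else TRUE
})

#' Construct a ScanSession
#'
#' @param data Frames x components matrix (time-course mode) or 4-D array
#'   with frames on the last dimension (volume mode).
#' @param tr Repetition time, seconds.
#' @param motion Frames x 6 motion-parameter matrix (mm, mm, mm, rad, rad,
#'   rad). Defaults to an all-zero trace.
#' @param mode `"timecourse"` or `"volume"`; inferred from `data` when
#'   missing.
#' @param noiseMask Optional logical 3-D noise-ROI mask (volume mode).
#' @param qc QC state list (`included`, `reason`).
#' @return A [ScanSession-class].
#' @export
ScanSession <- function(data, tr = 0.8, motion = NULL, mode = NULL,
                        noiseMask = NULL,
                        qc = list(included = TRUE, reason = "none")) {
  if (is.null(mode))
    mode <- if (is.matrix(data)) "timecourse" else "volume"
  tn <- if (mode == "timecourse") nrow(data) else dim(data)[4]
  if (is.null(motion)) motion <- matrix(0, tn, 6)
  new("ScanSession", mode = mode, data = data, tr = tr,
      motion = as.matrix(motion), noiseMask = noiseMask, qc = qc)
}

#' ConnectivityProfile: inter-subsystem connectivities and the NFQ
#'
#' Median pairwise connectivities between DMN subsystems and the derived
#' network failure quotient, for one session or averaged across sessions.
#'
#' @slot pairs data.frame with columns `sysA`, `sysB`, `connectivity`.
#' @slot nfq The network failure quotient (may be `NA` if undefined).
#' @slot perSession List of per-session ConnectivityProfile objects (empty
#'   for a single-session profile).
#' @slot nSessionsUsed Number of QC-passing sessions averaged.
#'
#' @export
setClass("ConnectivityProfile",
  representation(pairs = "data.frame", nfq = "numeric",
                 perSession = "list", nSessionsUsed = "integer"),
  prototype(nfq = NA_real_, perSession = list(), nSessionsUsed = 1L))

setValidity("ConnectivityProfile", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("sysA", "sysB", "connectivity") %in% names(p)))
    msg <- c(msg, "pairs needs columns sysA, sysB, connectivity")
  else if (any(abs(p$connectivity) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "pair connectivities must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' NormativeModel: age-conditional location-scale quantile curves
#'
#' A fitted normative model for one biomarker: smooth location mu(age) and
#' scale sigma(age) curves under a normal family, with fit scores, the
#' candidate table explored during smoothing selection, and quantile-residual
#' diagnostics. The backend is either a fitted `mgcv` location-scale model
#' (`"gam"`) or a dense age-grid representation reloaded from JSON
#' (`"grid"`); both evaluate identically through [predictNormative()].
#'
#' @slot biomarker Biomarker name.
#' @slot engine Fitted engine (a `gam` object or a grid list).
#' @slot backend `"gam"` or `"grid"`.
#' @slot support Numeric length-2 age support (years).
#' @slot scores List: `global_deviance`, `aic`, `sbc`, `edf`.
#' @slot candidates data.frame of candidate smoothing settings and scores.
#' @slot diagnostics List of quantile-residual summaries.
#'
#' @export
setClass("NormativeModel",
  representation(biomarker = "character", engine = "ANY",
                 backend = "character", support = "numeric",
                 scores = "list", candidates = "data.frame",
                 diagnostics = "list"))

setValidity("NormativeModel", function(object) {
  msg <- character()
  if (length(object@support) != 2L || diff(object@support) <= 0)
    msg <- c(msg, "support must be an increasing (min, max) age pair")
  if (!object@backend %in% c("gam", "grid"))
    msg <- c(msg, "backend must be 'gam' or 'grid'")
  if (length(msg)) msg else TRUE
})

#' MediationResult: effects from a causal mediation analysis
#'
#' @slot estimates data.frame with rows acme, ade, total,
#'   proportion_mediated and columns estimate, ci_lo, ci_hi, p.
#' @slot nSims Number of simulation draws used.
#' @slot flaggedFraction Fraction of draws with a near-zero total effect,
#'   excluded from the proportion-mediated summary.
#' @slot models List with the fitted mediator and outcome models.
#' @slot spec List echoing the analysis specification (variables, seed,
#'   method, CI level).
#'
#' @export
setClass("MediationResult",
  representation(estimates = "data.frame", nSims = "integer",
                 flaggedFraction = "numeric", models = "list",
                 spec = "list"))
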