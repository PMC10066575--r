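#' Accessors for netfailq classes
#'
#' Small accessor generics: slot access stays behind functions so the
#' internal representation can evolve.
#'
#' @param object An object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors Subsystem label per component (named character).
#' @export
setGeneric("componentLabels", function(object) standardGeneric("componentLabels"))
#' @export
setMethod("componentLabels", "ComponentAtlas", function(object) object@labels)

#' @describeIn accessors Spatial maps array, or NULL in time-course mode.
#' @export
setGeneric("atlasMaps", function(object) standardGeneric("atlasMaps"))
#' @export
setMethod("atlasMaps", "ComponentAtlas", function(object) object@maps)

#' @describeIn accessors Number of components in an atlas.
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @export
setMethod("nComponents", "ComponentAtlas", function(object) length(object@labels))

#' @describeIn accessors Session data (matrix or 4-D array).
#' @export
setGeneric("scanData", function(object) standardGeneric("scanData"))
#' @export
setMethod("scanData", "ScanSession", function(object) object@data)

#' @describeIn accessors Frames x 6 motion trace.
#' @export
setGeneric("scanMotion", function(object) standardGeneric("scanMotion"))
#' @export
setMethod("scanMotion", "ScanSession", function(object) object@motion)

#' @describeIn accessors Repetition time (seconds).
#' @export
setGeneric("scanTR", function(object) standardGeneric("scanTR"))
#' @export
setMethod("scanTR", "ScanSession", function(object) object@tr)

#' @describeIn accessors Number of frames in a session.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "ScanSession", function(object) {
  if (object@mode == "timecourse") nrow(object@data) else dim(object@data)[4]
})

#' @describeIn accessors Whether a session passed QC.
#' @export
setGeneric("qcPassed", function(object) standardGeneric("qcPassed"))
#' @export
setMethod("qcPassed", "ScanSession", function(object) isTRUE(object@qc$included))

#' @describeIn accessors The network failure quotient of a profile.
#' @export
setGeneric("nfqValue", function(object) standardGeneric("nfqValue"))
#' @export
setMethod("nfqValue", "ConnectivityProfile", function(object) object@nfq)

#' Median connectivity for one subsystem pair
#'
#' @param object A [ConnectivityProfile-class].
#' @param sysA,sysB Subsystem names (unordered).
#' @return Median connectivity for the pair (`NA` if absent).
#' @export
setGeneric("pairConnectivity", function(object, sysA, sysB)
  standardGeneric("pairConnectivity"))
#' @export
setMethod("pairConnectivity", "ConnectivityProfile", function(object, sysA, sysB) {
  p <- object@pairs
  hit <- (p$sysA == sysA & p$sysB == sysB) | (p$sysA == sysB & p$sysB == sysA)
  if (!any(hit)) NA_real_ else p$connectivity[which(hit)[1]]
})

#' @describeIn accessors Age support (min, max) of a normative model.
#' @export
setGeneric("supportRange", function(object) standardGeneric("supportRange"))
#' @export
setMethod("supportRange", "NormativeModel", function(object) object@support)

#' @describeIn accessors Fit scores (global deviance, AIC, SBC, edf).
#' @export
setGeneric("modelScores", function(object) standardGeneric("modelScores"))
#' @export
setMethod("modelScores", "NormativeModel", function(object) object@scores)

#' @describeIn accessors Quantile-residual diagnostics of a normative model.
#' @export
setGeneric("modelDiagnostics", function(object) standardGeneric("modelDiagnostics"))
#' @export
setMethod("modelDiagnostics", "NormativeModel", function(object) object@diagnostics)

#' @describeIn accessors Effect table of a mediation analysis.
#' @export
setGeneric("mediationEstimates", function(object) standardGeneric("mediationEstimates"))
#' @export
setMethod("mediationEstimates", "MediationResult", function(object) object@estimates)

setMethod("show", "ComponentAtlas", function(object) {
  cat("ComponentAtlas with", nComponents(object), "components\n")
  tab <- table(object@labels)
  cat("  subsystems:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(object@maps))
    cat("  grid:", paste(dim(object@maps)[1:3], collapse = " x "),
        "voxels;", paste(object@voxelSize, collapse = " x "), "mm\n")
  else cat("  no spatial maps (time-course mode)\n")
})

setMethod("show", "ScanSession", function(object) {
  cat("ScanSession [", object@mode, "]: ", nFrames(object), " frames, TR ",
      object@tr, " s\n", sep = "")
  cat("  QC:", if (qcPassed(object)) "included" else
      paste0("excluded (", object@qc$reason, ")"), "\n")
})

setMethod("show", "ConnectivityProfile", function(object) {
  cat("ConnectivityProfile: NFQ =", format(object@nfq, digits = 4),
      if (length(object@perSession))
        sprintf("(averaged over %d sessions)", object@nSessionsUsed) else "",
      "\n")
  p <- object@pairs
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s-%s: %.4f\n", p$sysA[i], p$sysB[i], p$connectivity[i]))
})

setMethod("show", "NormativeModel", function(object) {
  cat("NormativeModel for '", object@biomarker, "' (normal family, ",
      object@backend, " backend)\n", sep = "")
  cat(sprintf("  age support: %.1f-%.1f years\n",
              object@support[1], object@support[2]))
  s <- object@scores
  cat(sprintf("  GD %.1f | AIC %.1f | SBC %.1f | edf %.2f\n",
              s$global_deviance, s$aic, s$sbc, s$edf))
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult (", object@spec$method, ", ", object@nSims,
      " draws)\n", sep = "")
  print(format(object@estimates, digits = 3))
})
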