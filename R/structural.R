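#' Desikan-Killiany parcels of the thickness meta-ROI
#'
#' The Alzheimer-signature parcel set averaged by [metaRoiThickness()].
#' The "medial temporal" region sometimes named for this composite is
#' mapped to the DK "middletemporal" parcel (DK has no medial temporal
#' parcel); pass a modified set via the `regions` argument to override.
#'
#' @return Character vector of parcel names.
#' @export
metaRoiRegions <- function() {
  c("entorhinal", "inferiortemporal", "middletemporal",
    "inferiorparietal", "fusiform", "precuneus")
}

#' Meta-ROI cortical thickness
#'
#' Unweighted mean of bilateral thickness estimates over the six
#' Alzheimer-signature parcels (entorhinal, inferior temporal, middle
#' temporal, inferior parietal, fusiform, precuneus), i.e. 12 values.
#'
#' @param stats A regional-stats list as returned by
#'   [parseRegionalStats()], or any list with `thickness_lh` /
#'   `thickness_rh` named numeric vectors (mm).
#' @param regions Parcel names to average (default the signature set).
#' @return Meta-ROI thickness in mm.
#' @export
metaRoiThickness <- function(stats, regions = metaRoiRegions()) {
  vals <- c(stats$thickness_lh[regions], stats$thickness_rh[regions])
  miss <- c(regions[is.na(stats$thickness_lh[regions])],
            regions[is.na(stats$thickness_rh[regions])])
  if (length(miss))
    stop("missing thickness for region(s): ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  mean(vals)
}

#' Summed inferior parietal thickness
#'
#' @param stats Regional-stats list (see [metaRoiThickness()]).
#' @return Left + right inferior parietal thickness, mm.
#' @export
inferiorParietalSum <- function(stats) {
  v <- c(stats$thickness_lh["inferiorparietal"],
         stats$thickness_rh["inferiorparietal"])
  if (anyNA(v)) stop("missing inferiorparietal thickness", call. = FALSE)
  sum(v)
}

#' Reference fit for ICV correction
#'
#' Estimates the volume-on-ICV regression in the normative cohort only;
#' patients are corrected against this reference.
#'
#' @param volumes Structure volumes (mm^3) of the reference subjects.
#' @param icv Intracranial volumes (mm^3), same length.
#' @return List with `beta` (slope), `meanICV`, `n`.
#' @export
icvReference <- function(volumes, icv) {
  keep <- is.finite(volumes) & is.finite(icv)
  volumes <- volumes[keep]; icv <- icv[keep]
  if (length(volumes) < 10)
    warning("ICV reference fitted on fewer than 10 subjects")
  if (stats::var(icv) == 0) {
    warning("zero ICV variance in reference; falling back to ratio method")
    return(list(beta = NA_real_, meanICV = mean(icv), n = length(icv),
                method = "ratio"))
  }
  fit <- stats::lm(volumes ~ icv)
  list(beta = unname(stats::coef(fit)[2]), meanICV = mean(icv),
       n = length(volumes), method = "residual")
}

#' ICV-corrected structure volume
#'
#' Residual method (default): `adjusted = volume - beta * (icv - meanICV)`
#' with `beta` from the reference OLS fit, which preserves the volume
#' units, leaves a subject at the reference mean ICV unchanged, and
#' removes the ICV correlation. The ratio method
#' (`volume / icv * meanICV`) is available by option.
#'
#' @param volume Structure volume(s), mm^3.
#' @param icv Subject ICV(s), mm^3.
#' @param reference Reference fit from [icvReference()].
#' @param method `"residual"` (default) or `"ratio"`.
#' @return Adjusted volume(s), mm^3.
#' @export
icvCorrect <- function(volume, icv, reference,
                       method = c("residual", "ratio")) {
  method <- match.arg(method)
  if (identical(reference$method, "ratio")) method <- "ratio"
  if (method == "residual")
    volume - reference$beta * (icv - reference$meanICV)
  else
    volume / icv * reference$meanICV
}

#' Parse regional structural statistics
#'
#' Reads either FreeSurfer-style stats tables (aparc per hemisphere for
#' thickness, aseg for volumes) or a flat one-row-per-subject TSV, into
#' the regional-stats list used by the biomarker functions.
#'
#' For aparc tables the `StructName` and `ThickAvg` columns are used; for
#' aseg, `StructName` and `Volume_mm3`; ICV is taken from an
#' `# Measure EstimatedTotalIntraCranialVol` header line (or an `icv`
#' column in flat mode). Comment lines start with `#`.
#'
#' @param aparcLH,aparcRH Paths to left/right aparc-style stats tables.
#' @param aseg Path to an aseg-style stats table.
#' @param flat Path to a flat TSV with columns `region`, `hemi`, `value`,
#'   `type` (`thickness`/`volume`/`icv`); overrides the other inputs.
#' @return List: `thickness_lh`, `thickness_rh` (named mm vectors),
#'   `volume` (named mm^3 vector incl. `Left-Hippocampus`,
#'   `Right-Hippocampus`), `icv`, `provenance`.
#' @export
parseRegionalStats <- function(aparcLH = NULL, aparcRH = NULL, aseg = NULL,
                               flat = NULL) {
  if (!is.null(flat)) {
    tab <- utils::read.delim(flat, stringsAsFactors = FALSE)
    need <- c("region", "hemi", "value", "type")
    if (!all(need %in% names(tab)))
      stop("flat stats file ", flat, " must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    th <- tab[tab$type == "thickness", ]
    vol <- tab[tab$type == "volume", ]
    icv <- tab$value[tab$type == "icv"][1]
    out <- list(
      thickness_lh = stats::setNames(th$value[th$hemi == "lh"],
                                     th$region[th$hemi == "lh"]),
      thickness_rh = stats::setNames(th$value[th$hemi == "rh"],
                                     th$region[th$hemi == "rh"]),
      volume = stats::setNames(vol$value, vol$region),
      icv = icv, provenance = c(flat = flat))
  } else {
    .stopIfNot(!is.null(aparcLH) && !is.null(aparcRH) && !is.null(aseg),
               "supply either flat= or all of aparcLH, aparcRH, aseg")
    out <- list(
      thickness_lh = .readAparc(aparcLH),
      thickness_rh = .readAparc(aparcRH),
      volume = .readAseg(aseg),
      icv = .readICVHeader(aseg),
      provenance = c(aparcLH = aparcLH, aparcRH = aparcRH, aseg = aseg))
  }
  for (s in c("Left-Hippocampus", "Right-Hippocampus"))
    if (is.na(out$volume[s]))
      stop("missing required structure: ", s, call. = FALSE)
  out
}

.readStatsTable <- function(path, valueCol) {
  lines <- readLines(path)
  hdr <- grep("^# ColHeaders", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(hdr) == 1) {
    cols <- strsplit(sub("^# ColHeaders\\s+", "", hdr), "\\s+")[[1]]
  } else {
    # headerless fallback: first row is a header
    cols <- strsplit(body[1], "\\s+")[[1]]
    body <- body[-1]
  }
  if (!all(c("StructName", valueCol) %in% cols))
    stop("file ", path, ": required columns StructName/", valueCol,
         " not found", call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) != length(cols))
  if (length(bad))
    stop("file ", path, ", line ", bad[1] + sum(startsWith(lines, "#")),
         ": expected ", length(cols), " columns", call. = FALSE)
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  stats::setNames(as.numeric(m[, valueCol]), m[, "StructName"])
}

.readAparc <- function(path) .readStatsTable(path, "ThickAvg")
.readAseg <- function(path) .readStatsTable(path, "Volume_mm3")

.readICVHeader <- function(path) {
  ln <- grep("EstimatedTotalIntraCranialVol", readLines(path), value = TRUE)
  if (!length(ln)) return(NA_real_)
  as.numeric(strsplit(ln[1], ",")[[1]][4])
}

#' Derive the structural biomarker set for one subject
#'
#' @param stats Regional-stats list from [parseRegionalStats()].
#' @param icvRefs List with per-structure ICV references
#'   (`left`, `right`), from [icvReference()] on the normative cohort.
#' @param icvMethod `"residual"` or `"ratio"`.
#' @return One-row data.frame: `meta_roi`, `left_hipp_adj`,
#'   `right_hipp_adj`, `inf_parietal_sum`.
#' @export
structuralBiomarkers <- function(stats, icvRefs, icvMethod = "residual") {
  data.frame(
    meta_roi = metaRoiThickness(stats),
    left_hipp_adj = icvCorrect(stats$volume[["Left-Hippocampus"]],
                               stats$icv, icvRefs$left, icvMethod),
    right_hipp_adj = icvCorrect(stats$volume[["Right-Hippocampus"]],
                                stats$icv, icvRefs$right, icvMethod),
    inf_parietal_sum = inferiorParietalSum(stats))
}
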