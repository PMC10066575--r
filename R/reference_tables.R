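#' Published patient-level Z-scores and centile ranks (case study)
#'
#' The reference table of age-adjusted Z-scores and 2-decimal centile
#' ranks for the five biomarkers (NFQ, cortical thickness meta-ROI,
#' left/right hippocampal volume, inferior parietal thickness) in the
#' dysexecutive (dAD, n = 10) and amnestic (AD, n = 8) Alzheimer's
#' disease patients and cognitively unimpaired site controls (n = 5) of
#' the case study this package reproduces. Shipped as a plain TSV in
#' `extdata` and used as the input for threshold-count and
#' rank-consistency checks.
#'
#' @param long Return one row per (subject, biomarker) with columns
#'   `z` and `rank_printed` (default TRUE); otherwise the wide table.
#' @return data.frame.
#' @export
referencePatientTable <- function(long = TRUE) {
  path <- system.file("extdata", "patient_biomarker_zscores.tsv",
                      package = "netfailq")
  wide <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!long) return(wide)
  bio <- nfqBiomarkers()
  do.call(rbind, lapply(bio, function(b) {
    data.frame(subject = wide$subject, group = wide$group, biomarker = b,
               z = wide[[paste0("z_", b)]],
               rank_printed = wide[[paste0("rank_", b)]],
               stringsAsFactors = FALSE)
  }))
}

#' Group-median PET SUVRs of the case study
#'
#' Median amyloid- and tau-PET meta-ROI SUVRs per group, used to check
#' the A/T positivity classification (thresholds > 1.42 and > 1.23).
#'
#' @return data.frame: `group`, `amyloid_suvr`, `tau_suvr`.
#' @export
referenceSUVRMedians <- function() {
  data.frame(group = c("dAD", "AD", "control"),
             amyloid_suvr = c(2.48, 2.62, 1.30),
             tau_suvr = c(2.14, 1.89, 1.21),
             stringsAsFactors = FALSE)
}

#' Default centile-threshold rules for the patient counts
#'
#' The rules behind the reported patient-level counts: NFQ at or above
#' the 90th centile, inferior parietal thickness at or below the 2nd,
#' and meta-ROI / hippocampal markers at or below the 10th, per patient
#' group.
#'
#' @return data.frame of rules for [centileThresholdCounts()].
#' @export
defaultThresholdRules <- function() {
  rbind(
    data.frame(biomarker = "nfq", group = c("dAD", "AD"),
               direction = "above", cutoff = 0.90),
    data.frame(biomarker = "inf_parietal", group = c("dAD", "AD"),
               direction = "below", cutoff = 0.02),
    data.frame(biomarker = "right_hipp", group = c("dAD", "AD"),
               direction = "below", cutoff = 0.10),
    data.frame(biomarker = "left_hipp", group = c("dAD", "AD"),
               direction = "below", cutoff = 0.10),
    data.frame(biomarker = "meta_roi", group = c("dAD", "AD"),
               direction = "below", cutoff = 0.10))
}

#' Recompute centile ranks from reference Z-scores
#'
#' Applies the scoring convention (`pnorm(z)` rounded to 2 decimals) to
#' the reference table's Z-scores, returning both the recomputed and the
#' printed ranks for comparison.
#'
#' @return Long data.frame with `centile` (recomputed) and
#'   `rank_printed`.
#' @export
recomputeReferenceCentiles <- function() {
  tab <- referencePatientTable()
  tab$centile <- round(stats::pnorm(tab$z), 2)
  tab
}
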