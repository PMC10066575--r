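#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates the end-to-end analysis on a simulated cohort: cohort
#' generation, per-session scan synthesis, motion QC, per-session
#' connectivity and NFQ with within-subject session averaging, ICV
#' correction of hippocampal volumes, normative quantile-curve fitting on
#' the normative group, age-adjusted Z-scores and centile ranks for
#' patients and controls, centile-threshold counts, group comparisons
#' (ANOVA + Tukey, ROC/AUC), session ICC, and mediation analysis.
#'
#' @param config A [cohortConfig()]; its group sizes, session structure
#'   and planted effects define the run.
#' @param seed RNG seed for the whole run (overrides `config$seed`).
#' @param nTrim Leading frames discarded per session (default 10).
#' @param band Pass band, Hz.
#' @param fdThreshold Scan-level mean-FD threshold, mm (default 0.25).
#' @param grossLimit Gross-motion limit (mm / degrees peak-to-peak;
#'   default 2).
#' @param nfqVariant NFQ formula variant (see [computeNFQ()]).
#' @param icvMethod `"residual"` or `"ratio"` hippocampal ICV correction.
#' @param kGrid Candidate spline basis dimensions for normative fits.
#' @param motionParams Passed to [simulateMotion()] per session.
#' @param mediationSims Draws for the mediation stage (default 2000).
#' @param stages Stages to run, a subset of `"normative"`, `"score"`,
#'   `"stats"`, `"mediation"` (simulation, QC and connectivity always
#'   run; scoring requires the normative stage, stats requires scoring).
#' @param outDir Optional output directory; when given, cohort, Z-score,
#'   count and profile TSVs, normative model JSONs and a manifest are
#'   written there.
#' @return List: `cohort`, `profiles`, `qc`, `biomarkers` (per-subject
#'   observed biomarker table), `models`, `ztable`, `counts`, `report`,
#'   `anova`, `auc`, `icc`, `mediation`, `manifest`.
#' @export
runPipeline <- function(config = cohortConfig(), seed = NULL,
                        nTrim = 10, band = c(0.009, 0.08),
                        fdThreshold = 0.25, grossLimit = 2,
                        nfqVariant = "avDMN", icvMethod = "residual",
                        kGrid = c(4, 6, 9),
                        motionParams = list(baseline = 0.1,
                                            spikeRate = 0.0005,
                                            spikeMag = 1),
                        mediationSims = 2000,
                        stages = c("normative", "score", "stats",
                                   "mediation"),
                        outDir = NULL) {
  if ("score" %in% stages && !"normative" %in% stages)
    stop("stage 'score' requires stage 'normative'; run it first",
         call. = FALSE)
  if ("stats" %in% stages && !"score" %in% stages)
    stop("stage 'stats' requires stage 'score'; run it first",
         call. = FALSE)
  seed <- seed %||% config$seed %||% 1L
  set.seed(seed)
  config$seed <- NULL                  # seeding handled here, once
  cohort <- generateCohort(config)
  subj <- cohort$subjects
  n <- nrow(subj)
  labels <- subsystemCorrMatrix(1)$labels
  atlas <- ComponentAtlas(labels)

  # --- scans, QC, connectivity -------------------------------------------
  nses <- config$sessionsPerSubject
  profiles <- vector("list", n); names(profiles) <- subj$id
  qcRows <- vector("list", n * nses)
  nfqSessions <- matrix(NA_real_, n, nses,
                        dimnames = list(subj$id, NULL))
  for (i in seq_len(n)) {
    Rm <- subsystemCorrMatrix(cohort$truth$trueNFQ[i])$R
    sessionProfiles <- vector("list", nses)
    included <- logical(nses)
    for (s in seq_len(nses)) {
      scan <- simulateScan(Rm, nFrames = config$framesPerSession,
                           tr = config$tr, motionParams = motionParams,
                           band = band)
      qc <- qcScan(scanMotion(scan), fdThreshold, grossLimit)
      qcRows[[(i - 1) * nses + s]] <-
        data.frame(subject = subj$id[i], session = s, mean_fd = qc$meanFD,
                   included = qc$included, rule = qc$ruleTriggered)
      included[s] <- qc$included
      if (qc$included) {
        sessionProfiles[[s]] <- sessionProfile(scan, atlas, nTrim = nTrim,
                                               band = band,
                                               variant = nfqVariant)
        nfqSessions[i, s] <- nfqValue(sessionProfiles[[s]])
      }
    }
    keep <- !vapply(sessionProfiles, is.null, logical(1))
    profiles[[i]] <- if (any(keep))
      suppressWarnings(averageSessions(sessionProfiles[keep])) else NULL
  }
  qcTable <- do.call(rbind, qcRows)
  nfqObs <- vapply(profiles, function(p)
    if (is.null(p)) NA_real_ else nfqValue(p), numeric(1))

  # --- structural biomarkers ---------------------------------------------
  normRows <- subj$group == "normative"
  refL <- icvReference(subj$left_hipp_vol[normRows], subj$icv[normRows])
  refR <- icvReference(subj$right_hipp_vol[normRows], subj$icv[normRows])
  biomarkers <- data.frame(
    id = subj$id, group = subj$group, age = subj$age,
    nfq = unname(nfqObs),
    meta_roi = subj$meta_roi,
    left_hipp = icvCorrect(subj$left_hipp_vol, subj$icv, refL, icvMethod),
    right_hipp = icvCorrect(subj$right_hipp_vol, subj$icv, refR, icvMethod),
    inf_parietal = subj$inf_parietal,
    stringsAsFactors = FALSE)

  # --- normative models and scoring --------------------------------------
  bio <- nfqBiomarkers()
  models <- ztable <- counts <- anova <- aucs <- med <- report <- NULL
  icc <- NA_real_
  if ("normative" %in% stages) {
    normDat <- biomarkers[normRows & !is.na(biomarkers$nfq), ]
    models <- fitNormativeSet(normDat, bio, kGrid = kGrid)
  }
  if ("score" %in% stages) {
    scoreRows <- biomarkers[!is.na(biomarkers$nfq), ]
    ztable <- do.call(rbind, lapply(bio, function(b)
      scoreSubjects(models[[b]], scoreRows[[b]], scoreRows$age,
                    subjects = scoreRows$id, group = scoreRows$group)))
    patientZ <- ztable[ztable$group %in% c("dAD", "AD", "control"), ]
    counts <- centileThresholdCounts(patientZ, defaultThresholdRules())
    report <- makeReport(ztable)
  }

  # --- group statistics ---------------------------------------------------
  if ("stats" %in% stages) {
    anova <- lapply(stats::setNames(bio, bio), function(b) {
      zz <- ztable[ztable$biomarker == b, ]
      suppressWarnings(anovaTukey(zz$z, zz$group))
    })
    aucs <- lapply(stats::setNames(bio, bio), function(b) {
      zz <- ztable[ztable$biomarker == b, ]
      sgn <- if (b == "nfq") 1 else -1   # degeneration markers score low
      lapply(c(dAD = "dAD", AD = "AD", combined = "combined"), function(g) {
        sel <- if (g == "combined") zz$group %in% c("dAD", "AD", "normative")
               else zz$group %in% c(g, "normative")
        rocAuc(sgn * zz$z[sel], zz$group[sel] != "normative")
      })
    })
    iccRows <- normRows & rowSums(is.na(nfqSessions)) == 0
    icc <- if (sum(iccRows) >= 2 && nses >= 2)
      sessionICC(nfqSessions[iccRows, , drop = FALSE]) else NA_real_
  }

  # --- mediation (hippocampal volume -> NFQ -> recall) -------------------
  if ("mediation" %in% stages) med <- local({
    d <- data.frame(
      ravlt = subj$ravlt_total[normRows],
      hipp_sum = biomarkers$left_hipp[normRows] +
        biomarkers$right_hipp[normRows],
      nfq = biomarkers$nfq[normRows])
    fitMediation(d, outcome = "ravlt", treatment = "hipp_sum",
                 mediator = "nfq", nSims = mediationSims, seed = seed)
  })
  manifest <- list(
    package = "netfailq",
    version = as.character(utils::packageVersion("netfailq")),
    seed = seed,
    nSubjects = n, nScans = n * nses,
    nScansRemoved = sum(!qcTable$included),
    subjectsLost = names(which(vapply(profiles, is.null, logical(1)))),
    parameters = list(nTrim = nTrim, band = band,
                      fdThreshold = fdThreshold, grossLimit = grossLimit,
                      nfqVariant = nfqVariant, icvMethod = icvMethod,
                      kGrid = kGrid, mediationSims = mediationSims))

  out <- list(cohort = cohort, profiles = profiles, qc = qcTable,
              biomarkers = biomarkers, models = models, ztable = ztable,
              counts = counts, report = report, anova = anova,
              auc = aucs, icc = icc, mediation = med,
              manifest = manifest)
  if (!is.null(outDir)) out$manifest$checksums <- .writeRun(out, outDir)
  out
}

.writeRun <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "models"), showWarnings = FALSE)
  writeTSV(run$cohort$subjects, file.path(outDir, "cohort.tsv"))
  writeTSV(run$qc, file.path(outDir, "qc.tsv"))
  writeProfiles(run$profiles, file.path(outDir, "profiles.tsv"))
  if (!is.null(run$ztable)) {
    writeTSV(run$ztable, file.path(outDir, "zscores.tsv"))
    writeTSV(run$counts, file.path(outDir, "counts.tsv"))
    writeTSV(run$report, file.path(outDir, "report.tsv"))
  }
  if (!is.null(run$mediation))
    writeTSV(summarizeMediation(run$mediation),
             file.path(outDir, "mediation.tsv"))
  for (b in names(run$models))
    writeNormativeModel(run$models[[b]],
                        file.path(outDir, "models", paste0(b, ".json")))
  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  names(sums) <- substring(names(sums), nchar(outDir) + 2)
  jsonlite::write_json(c(run$manifest, list(checksums = as.list(sums))),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  as.list(sums)
}

#' Patient-level Z-score and centile report
#'
#' Formats the long Z-score table into the patient-by-biomarker layout
#' used for reporting: one row per scored subject, a Z and a centile
#' rank column per biomarker, 2-decimal formatting, subjects ordered by
#' group (dAD, AD, control, then others) and numeric id.
#'
#' @param ztable Long Z-score table from [scoreSubjects()].
#' @param groups Groups to include (default the patient and control
#'   groups).
#' @return data.frame (character columns, formatted to 2 decimals).
#' @export
makeReport <- function(ztable, groups = c("dAD", "AD", "control")) {
  zt <- ztable[ztable$group %in% groups, ]
  bio <- intersect(nfqBiomarkers(), unique(zt$biomarker))
  ids <- unique(zt[, c("subject", "group")])
  ord <- order(match(ids$group, groups),
               as.numeric(gsub("\\D", "", ids$subject)), ids$subject)
  ids <- ids[ord, ]
  out <- data.frame(subject = ids$subject, group = ids$group,
                    stringsAsFactors = FALSE)
  for (b in bio) {
    sub <- zt[zt$biomarker == b, ]
    m <- match(ids$subject, sub$subject)
    out[[paste0(b, "_z")]] <- sprintf("%.2f", sub$z[m])
    out[[paste0(b, "_rank")]] <- sprintf("%.2f", sub$centile[m])
  }
  rownames(out) <- NULL
  out
}
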