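# shared fixtures, built in code at test time

# courses with an exactly planted correlation matrix (empirical matching)
exactCourses <- function(R, n = 200) {
  z <- matrix(rnorm(n * ncol(R)), n, ncol(R))
  z <- sweep(z, 2, colMeans(z))
  z <- z %*% backsolve(chol(cov(z)), diag(ncol(R)))
  x <- z %*% chol(R)
  colnames(x) <- colnames(R)
  x
}

# one component blob per subsystem on a tiny grid; disjoint supports with
# graded weights (flat disjoint indicators would be collinear with the
# intercept of the spatial regression)
tinyVolumeAtlas <- function(dim = c(8, 8, 4)) {
  labels <- c(p1 = "pDMN", v1 = "vDMN", av1 = "avDMN", ad1 = "adDMN")
  maps <- array(0, c(dim, 4))
  w <- array(seq(0.5, 1.5, length.out = 9), c(3, 3))
  maps[1:3, 1:3, 1, 1] <- w
  maps[5:7, 1:3, 2, 2] <- w
  maps[1:3, 5:7, 3, 3] <- w
  maps[5:7, 5:7, 4, 4] <- w
  ComponentAtlas(labels, maps = maps)
}

# FreeSurfer-style stats fixtures written to a temp dir
writeStatsFixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  aparcRow <- function(name, thick)
    sprintf("%s  1000  800  2000  %.3f  0.4  0.1  0.02  10  1.2", name, thick)
  regions <- c("entorhinal", "inferiortemporal", "middletemporal",
               "inferiorparietal", "fusiform", "precuneus", "insula")
  lhT <- c(3.2, 2.8, 2.9, 2.31, 2.7, 2.4, 3.0)
  rhT <- c(3.1, 2.75, 2.85, 2.28, 2.65, 2.35, 2.95)
  hdr <- c("# Table of cortical parcellation statistics",
           "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd")
  writeLines(c(hdr, mapply(aparcRow, regions, lhT)),
             file.path(dir, "lh.aparc.stats"))
  writeLines(c(hdr, mapply(aparcRow, regions, rhT)),
             file.path(dir, "rh.aparc.stats"))
  asegRow <- function(idx, name, vol)
    sprintf("%d  %d  5000  %.1f  %s  80  10  20  120  5", idx, idx + 10, vol, name)
  asegHdr <- c(
    "# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1450000.0, mm^3",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean normMin normMax normRange normStdDev")
  writeLines(c(asegHdr,
               asegRow(1, "Left-Hippocampus", 4123.5),
               asegRow(2, "Right-Hippocampus", 4201.0),
               asegRow(3, "Left-Amygdala", 1500.0)),
             file.path(dir, "aseg.stats"))
  list(dir = dir,
       aparcLH = file.path(dir, "lh.aparc.stats"),
       aparcRH = file.path(dir, "rh.aparc.stats"),
       aseg = file.path(dir, "aseg.stats"),
       lh = setNames(lhT, regions), rh = setNames(rhT, regions))
}
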