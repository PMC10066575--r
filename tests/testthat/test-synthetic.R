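test_that("cohort generation is seed-deterministic and validates its config", {
  cfg <- cohortConfig(nNormative = 50, seed = 42)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(c1, c2)
  expect_equal(table(c1$subjects$group)[["dAD"]], 10)
  expect_true(all(c1$subjects$age >= 36 & c1$subjects$age <= 100))
  expect_error(cohortConfig(tr = -1), "tr")
  expect_error(cohortConfig(nDAD = -2), "nDAD")
  expect_error(cohortConfig(ageRange = c(90, 40)), "ageRange")
  expect_error(cohortConfig(framesPerSession = 5), "framesPerSession")
})

test_that("null effect shifts leave patient and normative distributions aligned", {
  eff <- netfailq:::.defaultEffects()
  eff[, ] <- 0
  cfg <- cohortConfig(nNormative = 400, nDAD = 200, nAD = 0, nControls = 0,
                      effectTable = eff, seed = 7)
  co <- generateCohort(cfg)
  z <- co$truth$z
  for (b in c("nfq", "meta_roi", "inf_parietal")) {
    dz <- mean(z[co$subjects$group == "dAD", b]) -
      mean(z[co$subjects$group == "normative", b])
    expect_lt(abs(dz), 3 * sqrt(1 / 400 + 1 / 200))
  }
})

test_that("planted age slopes are recovered by OLS on generated values", {
  curves <- netfailq:::.defaultCurves()
  curves$meta_roi$mu <- c(3.0, -0.004, 0)
  cfg <- cohortConfig(nNormative = 500, nDAD = 0, nAD = 0, nControls = 0,
                      curves = curves, seed = 8)
  co <- generateCohort(cfg)
  fit <- summary(lm(meta_roi ~ age, co$subjects))
  slope <- fit$coefficients["age", ]
  expect_lt(abs(slope["Estimate"] - (-0.004)), 3 * slope["Std. Error"])
})

test_that("planted correlation matrices are valid and NFQ-consistent", {
  for (nfq in c(-0.5, 0.3, 1, 1.8, 2.6, 3.4)) {
    sm <- subsystemCorrMatrix(nfq)
    ev <- eigen(sm$R, symmetric = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(diag(sm$R), rep(1, 8), ignore_attr = TRUE)
    expect_equal(sm$R, t(sm$R))
    expect_equal(sm$impliedNFQ, nfq, tolerance = 1e-6)
  }
})

test_that("empirical correlations converge to the planted matrix", {
  set.seed(9)
  labels <- subsystemCorrMatrix(1)$labels
  idm <- diag(8); dimnames(idm) <- list(names(labels), names(labels))
  scan <- simulateScan(idm, nFrames = 10000, empirical = FALSE)
  pc <- subsystemConnectivity(scanData(scan), labels)
  expect_lt(max(abs(pc$connectivity)), 0.05)
})

test_that("quadrupling frames halves the sampling error of correlations", {
  set.seed(10)
  sm <- subsystemCorrMatrix(1.5)
  sampleDev <- function(nFrames, reps = 60) {
    replicate(reps, {
      s <- simulateScan(sm$R, nFrames = nFrames, empirical = FALSE)
      cor(scanData(s)[, 1], scanData(s)[, 3]) - sm$R[1, 3]
    })
  }
  sd1 <- sd(sampleDev(400))
  sd4 <- sd(sampleDev(1600))
  expect_lt(abs(sd1 / sd4 - 2), 2 * 0.2 * 2)   # ratio 2 within ~20%
})

test_that("generated signals are band-limited", {
  set.seed(11)
  sm <- subsystemCorrMatrix(1.2)
  scan <- simulateScan(sm$R, nFrames = 488, tr = 0.8)
  x <- scanData(scan)[, 1]
  spec <- Mod(fft(x - mean(x)))^2
  freq <- pmin(0:487, 488 - 0:487) / (488 * 0.8)
  inBand <- freq >= 0.009 & freq <= 0.08
  expect_gt(sum(spec[inBand]) / sum(spec), 0.95)
})

test_that("spikeless motion keeps FD under the baseline at every frame", {
  set.seed(12)
  m <- simulateMotion(488, baseline = 0.1, spikeRate = 0)
  expect_lt(max(framewiseDisplacement(m)), 0.1)
  mSpike <- simulateMotion(488, baseline = 0.1, spikeRate = 0.05,
                           spikeMag = 1)
  expect_gt(max(framewiseDisplacement(mSpike)), 0.1)
})

test_that("volume mode round-trips courses through dual regression", {
  set.seed(13)
  sim <- simulateAtlas(dim = c(20, 24, 20))
  sm <- subsystemCorrMatrix(1.5)
  courses <- exactCourses(sm$R, 80)
  maps <- atlasMaps(sim$atlas)
  v <- prod(dim(maps)[1:3])
  vol <- array(matrix(maps, v, 8) %*% t(courses), c(dim(maps)[1:3], 80))
  rec <- dualRegression(vol, sim$atlas)
  for (j in 1:8) expect_gt(cor(rec[, j], courses[, j]), 0.99)
  # full volume-mode session with nuisance injection still recovers NFQ
  scan <- simulateScan(sm$R, nFrames = 120, mode = "volume",
                       atlas = sim$atlas, atlasExtras = sim,
                       voxelNoise = 0.02)
  expect_s4_class(scan, "ScanSession")
  expect_true(!is.null(scan@noiseMask))
  # the injected nuisance field is low-rank, so some of the six noise PCs
  # are dependent after filtering; the dropped-column warning is expected
  prof <- suppressWarnings(sessionProfile(scan, sim$atlas, nTrim = 10))
  expect_true(is.finite(nfqValue(prof)))
  expect_error(simulateScan(sm$R, 50, mode = "volume"), "atlas")
})

test_that("two OLS fits recover the planted mediation product", {
  set.seed(14)
  sim <- simulateMediationData(10000, a = 0.5, b = 2, cprime = 1)
  aFit <- summary(lm(M ~ X, sim$data))$coefficients["X", ]
  bFit <- summary(lm(Y ~ X + M, sim$data))$coefficients["M", ]
  prod <- aFit["Estimate"] * bFit["Estimate"]
  seProd <- sqrt(aFit["Std. Error"]^2 * bFit["Estimate"]^2 +
                   bFit["Std. Error"]^2 * aFit["Estimate"]^2)
  expect_lt(abs(prod - sim$truth$acme), 3 * seProd)
})
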