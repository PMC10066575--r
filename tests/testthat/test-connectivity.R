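test_that("initial-frame trimming drops exactly the leading frames", {
  set.seed(1)
  dat <- matrix(rnorm(488 * 4), 488, 4)
  mot <- matrix(rnorm(488 * 6, sd = 0.01), 488, 6)
  ses <- ScanSession(dat, motion = mot)
  tr10 <- trimInitialFrames(ses, 10)
  expect_equal(nFrames(tr10), 478)
  expect_identical(scanData(tr10), dat[11:488, ])
  expect_identical(scanMotion(tr10), mot[11:488, ])
  expect_identical(scanData(trimInitialFrames(ses, 0)), dat)
  small <- ScanSession(dat[1:12, ], motion = mot[1:12, ])
  expect_error(trimInitialFrames(small, 12), "cannot trim")
})

test_that("noise ROI thresholding is inclusive and erosion is 6-connected", {
  cube <- array(0, c(14, 14, 14))
  cube[3:12, 3:12, 3:12] <- 1            # 10^3 cube of probability 1
  zero <- array(0, dim(cube))
  mask <- buildNoiseRoi(cube, zero, threshold = 0.9, erosion = 2)
  expect_equal(sum(mask), 6^3)           # two-voxel erosion per face
  expect_true(all(which(mask, arr.ind = TRUE) >= 5) &&
              all(which(mask, arr.ind = TRUE) <= 10))
  expect_error(buildNoiseRoi(zero, zero), "threshold")
  # boundary: 0.89 excluded, 0.90 included (inclusive >=)
  one <- array(0.89, c(6, 6, 6))
  expect_error(buildNoiseRoi(one, array(0, dim(one)), erosion = 0),
               "threshold")
  one[] <- 0.90
  expect_equal(sum(buildNoiseRoi(one, array(0, dim(one)), erosion = 0)),
               216)
  # erosion can empty a thin mask, with advice
  thin <- array(0, c(5, 5, 5)); thin[, , 3] <- 1
  expect_error(buildNoiseRoi(thin, array(0, dim(thin)), erosion = 2),
               "smaller erosion")
})

test_that("noise components recover dominant signals in variance order", {
  set.seed(2)
  tt <- seq_len(120)
  s1 <- sin(2 * pi * tt / 30); s2 <- sin(2 * pi * tt / 11)
  vol <- array(0, c(4, 3, 2, 120))
  for (v in 1:12) vol[((v - 1) %% 4) + 1, ((v - 1) %/% 4) %% 3 + 1, 1, ] <-
    3 * s1 + rnorm(120, sd = 1e-3)
  for (v in 1:12) vol[((v - 1) %% 4) + 1, ((v - 1) %/% 4) %% 3 + 1, 2, ] <-
    1 * s2 + rnorm(120, sd = 1e-3)
  ses <- ScanSession(vol, mode = "volume")
  mask <- array(TRUE, c(4, 3, 2))
  comps <- noiseComponents(ses, mask, k = 2)
  expect_equal(dim(comps), c(120, 2))
  expect_gt(abs(cor(comps[, 1], s1)), 0.999)   # larger amplitude first
  expect_gt(abs(cor(comps[, 2], s2)), 0.999)
  expect_equal(unname(apply(comps, 2, sd)), c(1, 1), tolerance = 1e-8)
  # oracle: eigendecomposition of the frame-space covariance
  x <- t(matrix(vol, 24, 120)); x <- sweep(x, 2, colMeans(x))
  ev <- eigen(tcrossprod(x), symmetric = TRUE)
  for (j in 1:2)
    expect_gt(abs(cor(comps[, j], ev$vectors[, j])), 0.999)
  expect_equal(ncol(noiseComponents(ses, mask, k = 0)), 0)
  expect_error(noiseComponents(ses, mask, k = 50), "rank")
})

test_that("nuisance matrix is 6 motion + 6 derivatives + k components", {
  mot <- matrix(rnorm(50 * 6), 50, 6)
  comps <- matrix(rnorm(50 * 6), 50, 6)
  nm <- buildNuisanceMatrix(mot, comps)
  expect_equal(ncol(nm), 18)
  expect_equal(unname(colMeans(nm)), rep(0, 18), tolerance = 1e-12)
  # constant trace -> zero derivative columns
  nmC <- buildNuisanceMatrix(matrix(1, 50, 6))
  expect_true(all(abs(nmC[, 7:12]) < 1e-12))
  # ramp -> backward difference (0, 1, 1, ...), centred
  ramp <- matrix(0, 20, 6); ramp[, 1] <- 0:19
  nmR <- buildNuisanceMatrix(ramp)
  expected <- c(0, rep(1, 19)); expected <- expected - mean(expected)
  expect_equal(unname(nmR[, 7]), expected)
  expect_error(buildNuisanceMatrix(mot, comps[1:10, ]), "frame counts")
})

test_that("band-pass keeps in-band signal, rejects stop-band, projects out nuisance", {
  t <- (0:477) * 0.8
  inband <- matrix(sin(2 * pi * 0.04 * t))
  out1 <- bandpassAndRegress(inband, tr = 0.8, normalize = FALSE)
  expect_gt(var(out1[, 1]) / var(inband[, 1]), 0.95)
  stopb <- matrix(sin(2 * pi * 0.2 * t))
  out2 <- bandpassAndRegress(stopb, tr = 0.8, normalize = FALSE)
  expect_lt(var(out2[, 1]) / var(stopb[, 1]), 0.10)
  # exact projection on a nuisance column
  set.seed(3)
  nuis <- matrix(rnorm(478 * 3), 478, 3)
  dat <- cbind(nuis[, 1] + sin(2 * pi * 0.03 * t))
  res <- bandpassAndRegress(dat, nuis, tr = 0.8)
  filtN <- bandpassAndRegress(nuis, tr = 0.8, normalize = FALSE)
  dots <- abs(crossprod(res, sweep(filtN, 2, colMeans(filtN))))
  norms <- outer(sqrt(colSums(res^2)),
                 sqrt(colSums(sweep(filtN, 2, colMeans(filtN))^2)))
  expect_true(all(dots / norms < 1e-6))
  expect_equal(unname(apply(res, 2, sd)), 1, tolerance = 1e-10)
  expect_error(bandpassAndRegress(dat, band = c(0.01, 0.7), tr = 0.8),
               "Nyquist")
  expect_warning(bandpassAndRegress(dat, cbind(nuis, nuis[, 1]), tr = 0.8),
                 "dependent")
})

test_that("Gaussian smoothing preserves mass and matches the analytic kernel", {
  img <- array(0, c(21, 21, 21)); img[11, 11, 11] <- 1
  sm <- smoothVolumes(img, fwhm = 8, voxelSize = c(2, 2, 2))
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  sig <- 8 / (2 * sqrt(2 * log(2))) / 2       # voxels
  r <- ceiling(4 * sig)
  k1 <- dnorm(-r:r, sd = sig); k1 <- k1 / sum(k1)
  expect_equal(sm[11, 11, 11], k1[r + 1]^3, tolerance = 1e-10)
  expect_equal(sm[11 + 2, 11, 11], k1[r + 3] * k1[r + 1]^2,
               tolerance = 1e-10)
  expect_identical(smoothVolumes(img, 0), img)
  flat <- array(1, c(16, 16, 16))
  smf <- smoothVolumes(flat, 6, c(2, 2, 2))
  expect_equal(smf[8, 8, 8], 1, tolerance = 1e-6)   # interior unchanged
  expect_error(smoothVolumes(img, -1), "non-negative")
})

test_that("dual regression solves the joint spatial model exactly", {
  atl <- tinyVolumeAtlas()
  d <- c(dim(atlasMaps(atl))[1:3], 50)
  tt <- seq_len(50)
  s <- sin(2 * pi * tt / 25)
  mapMat <- matrix(atlasMaps(atl), prod(d[1:3]), 4)
  vol <- array(mapMat %*% rbind(s, 0, 0, 0), d)
  rec <- dualRegression(vol, atl)
  expect_gt(cor(rec[, 1], s), 0.999999)
  expect_true(all(abs(rec[, 2:4]) < 1e-8))
  expect_true(all(dualRegression(array(0, d), atl) == 0))
  # correlated maps: joint regression separates, univariate does not
  set.seed(4)
  labels <- c(a = "pDMN", b = "vDMN")
  maps <- array(0, c(6, 6, 2, 2))
  base <- array(runif(72), c(6, 6, 2))
  maps[, , , 1] <- base
  maps[, , , 2] <- 0.7 * base + 0.3 * array(runif(72), c(6, 6, 2))
  atl2 <- ComponentAtlas(labels, maps = maps)
  s1 <- rnorm(80); s2 <- rnorm(80)
  m2 <- matrix(maps, 72, 2)
  vol2 <- array(m2 %*% rbind(s1, s2) +
                  matrix(rnorm(72 * 80, sd = 0.01), 72, 80), c(6, 6, 2, 80))
  recJ <- dualRegression(vol2, atl2)
  expect_gt(cor(recJ[, 1], s1), 0.99)
  expect_gt(cor(recJ[, 2], s2), 0.99)
  # univariate per-map regression is contaminated by the shared support
  y <- matrix(vol2, 72, 80)
  uni1 <- as.numeric(crossprod(m2[, 1] - mean(m2[, 1]), y)) /
    sum((m2[, 1] - mean(m2[, 1]))^2)
  expect_lt(cor(uni1, s1), 0.99)
  # brute-force normal equations agree
  X <- cbind(1, sweep(m2, 2, colMeans(m2)))
  bf <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(recJ), unname(t(bf[-1, ])), tolerance = 1e-10)
  # collinear maps are named
  maps3 <- array(0, c(6, 6, 2, 2))
  maps3[, , , 1] <- base; maps3[, , , 2] <- 2 * base
  expect_error(dualRegression(vol2, ComponentAtlas(labels, maps = maps3)),
               "collinear")
  expect_error(dualRegression(array(0, c(5, 5, 2, 10)), atl2), "grid")
})

test_that("subsystem connectivity is the median over cross pairs", {
  set.seed(5)
  # single component per subsystem, identical courses -> all 1
  x <- matrix(rnorm(50), 50, 1)[, c(1, 1, 1, 1)]
  colnames(x) <- c("p", "v", "av", "ad")
  labels <- c(p = "pDMN", v = "vDMN", av = "avDMN", ad = "adDMN")
  pc <- subsystemConnectivity(x, labels)
  expect_equal(pc$connectivity, rep(1, 6), tolerance = 1e-12)
  # hand-built 2x2 cross correlations {0.1, 0.2, 0.3, 0.4} -> median 0.25
  R <- rbind(c(1, .5, .1, .2), c(.5, 1, .3, .4),
             c(.1, .3, 1, .5), c(.2, .4, .5, 1))
  dimnames(R) <- list(c("a1", "a2", "b1", "b2"), c("a1", "a2", "b1", "b2"))
  stopifnot(min(eigen(R)$values) > 0)
  xc <- exactCourses(R, 300)
  lab2 <- c(a1 = "pDMN", a2 = "pDMN", b1 = "vDMN", b2 = "vDMN")
  pc2 <- subsystemConnectivity(xc, lab2)
  expect_equal(pc2$connectivity[pc2$sysA == "pDMN" & pc2$sysB == "vDMN"],
               0.25, tolerance = 1e-10)
  # orthogonal sinusoids -> zero connectivity
  tt <- seq_len(64)
  xo <- cbind(sin(2 * pi * tt / 64), cos(2 * pi * tt / 64),
              sin(4 * pi * tt / 64), cos(4 * pi * tt / 64))
  colnames(xo) <- names(labels)
  pco <- subsystemConnectivity(xo, labels)
  expect_true(all(abs(pco$connectivity) < 1e-6))
  # zero-variance course excluded with a warning
  xz <- xc; xz[, 1] <- 5
  expect_warning(pcz <- subsystemConnectivity(xz, lab2), "zero-variance")
  expect_equal(pcz$nPairs[1], 2)
})

test_that("the NFQ formula, variants and degenerate guard behave as specified", {
  p <- data.frame(sysA = "pDMN", sysB = c("avDMN", "adDMN", "vDMN"),
                  connectivity = c(0.3, 0.2, 0.25))
  expect_equal(computeNFQ(p), 2.0)
  expect_equal(computeNFQ(p, variant = "literal"), 1.8)
  # scale cancellation: all pairs equal c != 0 -> 2 under default formula
  for (cc in c(0.1, 0.37, -0.2)) {
    pe <- data.frame(sysA = "pDMN", sysB = c("avDMN", "adDMN", "vDMN"),
                     connectivity = cc)
    expect_equal(computeNFQ(pe), 2.0)
  }
  pz <- transform(p, connectivity = c(0.3, 0.2, 1e-9))
  expect_warning(nfq <- computeNFQ(pz), "undefined")
  expect_true(is.na(nfq))
  expect_error(computeNFQ(p[1:2, ]), "missing")
})

test_that("session averaging uses only QC-passing sessions", {
  mk <- function(nfq) new("ConnectivityProfile",
                          pairs = data.frame(sysA = "pDMN", sysB = "vDMN",
                                             connectivity = 0.3),
                          nfq = nfq)
  avg <- averageSessions(list(mk(1), mk(2), mk(3), mk(4)))
  expect_equal(nfqValue(avg), 2.5)
  expect_equal(avg@nSessionsUsed, 4L)
  expect_equal(nfqValue(averageSessions(list(mk(7)))), 7)
  avg2 <- averageSessions(list(mk(1), mk(2), mk(3), mk(10)),
                          included = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nfqValue(avg2), 2)
  expect_warning(res <- averageSessions(list(mk(1)), included = FALSE),
                 "missing")
  expect_null(res)
})

test_that("session ICC matches the mean-squares decomposition", {
  # identical sessions, differing subjects -> 1
  m <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(sessionICC(m), 1)
  # hand matrix against an independent ANOVA-table computation
  h <- rbind(c(9, 2), c(1, 5), c(8, 6))
  n <- 3; k <- 2
  dat <- data.frame(y = as.vector(h),
                    subj = factor(rep(1:3, k)),
                    sess = factor(rep(1:2, each = n)))
  ms <- anova(lm(y ~ subj + sess, dat))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(sessionICC(h), icc_oracle, tolerance = 1e-12)
  # iid noise -> near zero
  set.seed(6)
  nullIcc <- sessionICC(matrix(rnorm(200 * 4), 200, 4))
  expect_lt(abs(nullIcc), 3 / sqrt(200))
  expect_error(sessionICC(matrix(2, 5, 3)), "undefined")
})

test_that("the pipeline is equivariant to intensity scaling and ordering", {
  set.seed(7)
  sm <- subsystemCorrMatrix(1.6)
  atlas <- ComponentAtlas(sm$labels)
  scan <- simulateScan(sm$R, nFrames = 200)
  p1 <- sessionProfile(scan, atlas)
  scaled <- ScanSession(scanData(scan) * 7.3, motion = scanMotion(scan))
  p2 <- sessionProfile(scaled, atlas)
  expect_equal(nfqValue(p1), nfqValue(p2), tolerance = 1e-10)
  expect_equal(p1@pairs$connectivity, p2@pairs$connectivity,
               tolerance = 1e-10)
  # component order permutation
  perm <- sample(ncol(scanData(scan)))
  scanP <- ScanSession(scanData(scan)[, perm], motion = scanMotion(scan))
  atlasP <- ComponentAtlas(componentLabels(atlas)[perm])
  p3 <- sessionProfile(scanP, atlasP)
  expect_equal(nfqValue(p1), nfqValue(p3), tolerance = 1e-10)
})

test_that("planted subsystem structure survives the full per-session pipeline", {
  set.seed(8)
  sm <- subsystemCorrMatrix(1.5)
  atlas <- ComponentAtlas(sm$labels)
  scan <- simulateScan(sm$R, nFrames = 2010)
  prof <- sessionProfile(scan, atlas)
  tgt <- subsystemConnectivityFromMatrix(sm$R, sm$labels)
  cmp <- merge(prof@pairs, tgt, by = c("sysA", "sysB"))
  expect_lt(max(abs(cmp$connectivity.x - cmp$connectivity.y)), 0.05)
})
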