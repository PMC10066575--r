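# a grid-backed model with known constant curves, for exact oracles
constantModel <- function(mu = 10, sigma = 2, support = c(40, 90)) {
  new("NormativeModel", biomarker = "toy",
      engine = list(muFun = function(a) rep(mu, length(a)),
                    logSigmaFun = function(a) rep(log(sigma), length(a))),
      backend = "grid", support = support,
      scores = list(global_deviance = 0, aic = 0, sbc = 0, edf = 2),
      candidates = data.frame(), diagnostics = list())
}

test_that("location and scale curves are recovered from planted data", {
  set.seed(1)
  n <- 1000
  age <- runif(n, 36, 100)
  y <- rnorm(n, 10 + 0.05 * age, 2)
  m <- fitNormative(y, age, biomarker = "planted")
  g <- seq(40, 96, 2)
  p <- predictNormative(m, g)
  expect_lt(max(abs(p$mu - (10 + 0.05 * g))), 0.15)
  expect_lt(max(abs(p$sigma / 2 - 1)), 0.10)
  expect_true(all(is.finite(unlist(modelScores(m)[c("global_deviance",
                                                    "aic", "sbc")]))))
  expect_equal(nrow(m@candidates), 3)
  # null data: no age trend appears
  y0 <- rnorm(n, 5, 1)
  m0 <- fitNormative(y0, age)
  p0 <- predictNormative(m0, c(40, 70, 95))
  expect_lt(diff(range(p0$mu)), 3 * sd(y0) / sqrt(n) * 5)
  expect_error(fitNormative(y[1:30], rep(1:3, 10)), "distinct ages")
})

test_that("the linear smoothing limit agrees with OLS", {
  set.seed(2)
  age <- runif(1500, 36, 100)
  y <- rnorm(1500, 3 + 0.02 * age, 1)     # homoscedastic
  m <- fitNormative(y, age, kGrid = 6, sp = c(1e8, 1e8))
  g <- seq(40, 95, 5)
  ols <- predict(lm(y ~ age), data.frame(age = g))
  expect_lt(max(abs(predictNormative(m, g)$mu - ols)), 1e-3)
})

test_that("centile curves follow mu + qnorm(c) sigma and stay ordered", {
  cm <- constantModel(mu = 10, sigma = 2)
  cc <- centileCurves(cm, centiles = c(0.1, 0.5, 0.9, 0.975),
                      ageGrid = c(45, 60, 75))
  expect_equal(cc$c0.5, rep(10, 3))                 # median = mu
  expect_equal(cc$c0.9 - 10, 10 - cc$c0.1)          # symmetric
  expect_equal(cc$c0.975, rep(10 + qnorm(0.975) * 2, 3))
  expect_equal(cc$c0.975[1], 13.9199, tolerance = 1e-4)
  # monotone in the centile at every age, on a fitted model too
  set.seed(3)
  age <- runif(400, 36, 100)
  m <- fitNormative(rnorm(400, 8 - 0.03 * age, 1 + 0.004 * age), age)
  full <- centileCurves(m)
  mat <- as.matrix(full[, -(1:2)])
  expect_true(all(apply(mat, 1, function(r) all(diff(r) > 0))))
  expect_true(any(centileCurves(cm, ageGrid = c(30, 50))$extrapolated))
})

test_that("Z-scores map to 2-decimal centile ranks through the normal CDF", {
  cm <- constantModel(mu = 0, sigma = 1)
  sc <- scoreSubjects(cm, c(-0.47, 0, 1.35), c(60, 60, 60))
  expect_equal(sc$centile, c(0.32, 0.50, 0.91))
  # independent oracle: numeric integration of the standard normal density
  phi135 <- integrate(dnorm, -Inf, 1.35)$value
  expect_equal(round(phi135, 2), 0.91)
  expect_equal(sc$centile_raw[3], phi135, tolerance = 1e-6)
  expect_false(any(sc$extrapolated))
  scX <- scoreSubjects(cm, 1, 30)
  expect_true(scX$extrapolated)
  expect_true(is.finite(scX$z))
})

test_that("Z-scores are equivariant under affine biomarker transforms", {
  set.seed(4)
  age <- runif(500, 36, 100)
  y <- rnorm(500, 10 + 0.05 * age, 2)
  m1 <- fitNormative(y, age)
  m2 <- fitNormative(3 * y + 7, age)
  newAge <- c(50, 65, 80)
  v <- c(12, 13, 14)
  z1 <- scoreSubjects(m1, v, newAge)$z
  z2 <- scoreSubjects(m2, 3 * v + 7, newAge)$z
  expect_equal(z1, z2, tolerance = 1e-3)
  expect_equal(predictNormative(m2, newAge)$mu,
               3 * predictNormative(m1, newAge)$mu + 7, tolerance = 1e-3)
})

test_that("quantile residual diagnostics detect mis-specification", {
  set.seed(5)
  age <- runif(1000, 36, 100)
  y <- rnorm(1000, 5 + 0.02 * age, 1.5)
  m <- fitNormative(y, age)
  d <- wormDiagnostics(m, y, age)
  expect_lt(abs(d$mean), 0.05)
  expect_lt(abs(d$skewness), 1)
  expect_lt(abs(d$kurtosis - 3), 1)
  expect_length(d$flags, 0)
  expect_equal(d$sd, 1, tolerance = 0.1)
  # heavy tails under the normal family get flagged
  yT <- 5 + 0.02 * age + 1.5 * rt(1000, df = 3)
  mT <- fitNormative(yT, age)
  dT <- wormDiagnostics(mT, yT, age)
  expect_gt(dT$kurtosis, 4)
  expect_true(any(grepl("kurtosis", dT$flags)))
  # worm band: perfectly normal residuals stay inside ~95% of the band
  inside <- replicate(40, {
    r <- rnorm(400)
    w <- wormDiagnostics(constantModel(0, 1), r, rep(60, 400))$worm
    mean(abs(w$deviation) <= w$band)
  })
  expect_gt(mean(inside), 0.90)
})

test_that("models round-trip through JSON with scoring intact", {
  set.seed(6)
  age <- runif(400, 36, 100)
  y <- rnorm(400, 10 - 0.04 * age, 1.2)
  m <- fitNormative(y, age, biomarker = "rt")
  path <- withr::local_tempfile(fileext = ".json")
  writeNormativeModel(m, path)
  m2 <- readNormativeModel(path)
  expect_equal(m2@biomarker, "rt")
  ages <- c(45, 60, 75, 90)
  s1 <- scoreSubjects(m, c(8, 8, 8, 8), ages)
  s2 <- scoreSubjects(m2, c(8, 8, 8, 8), ages)
  expect_equal(s1$z, s2$z, tolerance = 1e-6)
  expect_equal(s1$centile, s2$centile)
})
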