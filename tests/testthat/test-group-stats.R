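test_that("standardized simple associations and FDR behave correctly", {
  set.seed(1)
  n <- 200
  x <- rnorm(n)
  d <- data.frame(y = x, exact = x, noise1 = rnorm(n), noise2 = rnorm(n),
                  skewed = exp(rnorm(n)), flat = rep(1, n))
  expect_warning(
    res <- simpleAssociations(d, "y", c("exact", "noise1", "noise2",
                                        "skewed", "flat"),
                              methods = c(skewed = "spearman")),
    "zero-variance")
  ex <- res[res$predictor == "exact", ]
  expect_equal(ex$coefficient, 1, tolerance = 1e-10)
  expect_lt(ex$p_fdr, 1e-10)
  expect_equal(res$method[res$predictor == "skewed"], "spearman")
  # FDR: adjusted never below raw, monotone in raw order
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  o <- order(res$p)
  expect_true(all(diff(res$p_fdr[o]) >= -1e-15))
  # CI contains the point estimate
  expect_true(all(res$ci_lo <= res$coefficient &
                  res$coefficient <= res$ci_hi))
})

test_that("multivariate regression reports exact OLS and flags aliasing", {
  set.seed(2)
  n <- 64
  q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))    # orthonormal predictors
  beta <- c(2, -1, 0.5)
  d <- data.frame(y = q %*% beta, x1 = q[, 1], x2 = q[, 2], x3 = q[, 3])
  res <- multivariateRegression(d, "y", c("x1", "x2", "x3"))
  expect_equal(unname(coef(res$fit)[-1]), beta, tolerance = 1e-10)
  # df bookkeeping at the study design size: n = 704, p = 8
  d2 <- as.data.frame(matrix(rnorm(704 * 9), 704, 9))
  names(d2) <- c("y", paste0("x", 1:8))
  res2 <- multivariateRegression(d2, "y", paste0("x", 1:8))
  expect_equal(res2$df, c(8, 695))
  expect_lt(res2$r2, 0.1)
  d3 <- d; d3$x4 <- d$x1
  expect_error(multivariateRegression(d3, "y", c("x1", "x2", "x3", "x4")),
               "aliased")
})

test_that("ANOVA with Tukey HSD handles identical, shifted and tiny groups", {
  vals <- rep(c(1, 2, 3), 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anovaTukey(vals, grp)
  expect_equal(res$F, 0)
  expect_true(all(res$tukey$p_adj == 1))
  # two groups: Tukey p agrees with a permutation test of the mean difference
  set.seed(3)
  a <- rnorm(8, 1); b <- rnorm(10)
  res2 <- anovaTukey(c(a, b), rep(c("a", "b"), c(8, 10)))
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perm <- replicate(4000, {
    idx <- sample(18, 8)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  pPerm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(res2$tukey$p_adj - pPerm), 0.02)
  # singleton group excluded from post hoc tests
  expect_warning(
    res3 <- anovaTukey(c(a, b, 5), rep(c("a", "b", "c"), c(8, 10, 1))),
    "singleton")
  expect_equal(nrow(res3$tukey), 1)
})

test_that("a planted patient shift separates patients from the normative group", {
  set.seed(4)
  hits <- replicate(25, {
    z <- c(rnorm(100), rnorm(10, 1.5), rnorm(8, 1.5))
    g <- rep(c("normative", "dAD", "AD"), c(100, 10, 8))
    tk <- anovaTukey(z, g)$tukey
    p <- setNames(tk$p_adj, tk$comparison)
    c(p[["normative-AD"]] < 0.05, p[["normative-dAD"]] < 0.05,
      p[["dAD-AD"]] > 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.8)   # AD vs normative detected
  expect_gte(mean(hits[2, ]), 0.8)   # dAD vs normative detected
  expect_gte(mean(hits[3, ]), 0.8)   # phenotypes not distinguished
})

test_that("Cohen's D matches hand computation and is scale invariant", {
  x <- rnorm(20)
  expect_equal(cohensD(x, x)$d, 0)
  res <- cohensD(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$d, -1)            # pooled SD is exactly 1
  expect_true(res$ci_lo <= -1 && -1 <= res$ci_hi)
  res10 <- cohensD(c(10, 20, 30), c(20, 30, 40))
  expect_equal(res10$d, res$d, tolerance = 1e-12)
  expect_equal(cohensD(rnorm(50, 1), rnorm(50))$magnitude,
               "large")
  expect_error(cohensD(c(1, 1, 1), c(1, 1, 1)), "undefined")
})

test_that("AUC equals the pairwise win rate and DeLong CI covers it", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # brute-force pair counting on a small hand-checkable set
  scores <- c(3, 4, 1, 2, 3)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- rocAuc(scores, labels)
  wins <- 0
  for (i in which(labels)) for (j in which(!labels))
    wins <- wins + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_equal(res$auc, wins / 6)
  expect_equal(res$auc, 5.5 / 6)
  # null calibration and the reflection identity
  set.seed(5)
  s <- rnorm(200); l <- rep(c(TRUE, FALSE), 100)
  resN <- rocAuc(s, l)
  seNull <- sqrt((100 + 100 + 1) / (12 * 100 * 100))
  expect_lt(abs(resN$auc - 0.5), 3 * seNull)
  expect_equal(rocAuc(-s, l)$auc, 1 - resN$auc)
  expect_error(rocAuc(s, rep(TRUE, 200)), "case")
})

test_that("centile-threshold counting uses rounded ranks inclusively", {
  zt <- data.frame(biomarker = "nfq", group = "dAD",
                   centile = c(0.90, 0.89, 0.91, 1.00, 0.50))
  rules <- data.frame(biomarker = "nfq", group = "dAD",
                      direction = "above", cutoff = 0.90)
  expect_equal(centileThresholdCounts(zt, rules)$count, 3)  # 0.90 counts
  rules2 <- data.frame(biomarker = "nfq", group = "dAD",
                       direction = "below", cutoff = 0.50)
  expect_equal(centileThresholdCounts(zt, rules2)$count, 1)
  empty <- centileThresholdCounts(zt, rules[0, ])
  expect_equal(nrow(empty), 0)
  badRule <- data.frame(biomarker = "tau", group = "dAD",
                        direction = "above", cutoff = 0.9)
  expect_error(centileThresholdCounts(zt, badRule), "no rows")
})

test_that("A/T positivity uses strict SUVR thresholds", {
  res <- atClassify(c(2.48, 1.30, 1.42), c(2.14, 1.21, 1.23))
  expect_equal(res$status, c("A+/T+", "A-/T-", "A-/T-"))
  expect_error(atClassify(NA, 1), "finite")
})
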