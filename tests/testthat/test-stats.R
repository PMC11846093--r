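test_that("percent bias follows its defining arithmetic", {
  expect_identical(percentBias(2, 2), 0)
  expect_identical(percentBias(3, 2), 50)
  expect_equal(percentBias(2.9, 2.0), 45)
  expect_error(percentBias(1, 0), "> 0")
})

test_that("coefficient of variation uses the sample SD and is scale-free", {
  expect_identical(coefficientOfVariation(c(2, 2, 2)), 0)
  expect_equal(coefficientOfVariation(c(1, 3)), 100 * sqrt(2) / 2)
  set.seed(5)
  x <- runif(20, 1, 4)
  expect_equal(coefficientOfVariation(x), coefficientOfVariation(7 * x))
  expect_error(coefficientOfVariation(c(-3, 1)), "mean")
})

test_that("Lin's concordance penalizes shifts and is bounded by |rho|", {
  x <- c(1, 2, 3, 4)
  expect_identical(linCcc(x, x), 1)
  expect_lt(linCcc(x, x + 1), 1)
  y <- c(1.1, 2.1, 2.9, 4.2)
  # direct evaluation of the formula with population moments
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  rho <- mean((x - mx) * (y - my)) / sqrt(sx2 * sy2)
  expect_equal(linCcc(x, y),
               2 * rho * sqrt(sx2) * sqrt(sy2) /
                 (sx2 + sy2 + (mx - my)^2))
  set.seed(8)
  for (i in seq_len(50)) {
    a <- rnorm(10); b <- rnorm(10, sd = runif(1, 0.5, 2))
    expect_lte(abs(linCcc(a, b)), abs(stats::cor(a, b)) + 1e-12)
  }
  # equal moments reduce LCC to Pearson rho
  b <- rev(x)
  expect_equal(linCcc(x, b), stats::cor(x, b))
  expect_error(linCcc(c(1, 1), c(1, 1)), "undefined")
})

test_that("Cohen's d uses the pooled sample SD", {
  expect_identical(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(2.5, 3.5); y <- c(1.5, 2.5)  # means 3, 2; pooled sd = sqrt(0.5)
  expect_equal(cohensD(x, y), 1 / sqrt(0.5))
  # null distribution is centred on zero
  set.seed(13)
  ds <- vapply(seq_len(1000), function(i)
    cohensD(rnorm(12), rnorm(12)), numeric(1))
  expect_lt(abs(mean(ds)), 0.05)
  expect_error(cohensD(c(1, 1), c(1, 1)), "zero")
})

test_that("ROC AUC equals the all-pairs Mann-Whitney estimator", {
  bruteAuc <- function(hc, pd) {
    # probability that a control exceeds a case, ties counted half
    mean(outer(hc, pd, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_identical(rocAuc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  set.seed(21)
  for (i in seq_len(25)) {
    hc <- round(rnorm(8, 1), 1); pd <- round(rnorm(6, 0.5), 1)
    expect_equal(rocAuc(hc, pd, positiveIsLower = TRUE)$auc,
                 bruteAuc(hc, pd))
  }
  # orientation flip complements the AUC when there are no ties
  hc <- c(1.1, 2.3, 3.7); pd <- c(0.4, 2.9)
  expect_equal(rocAuc(hc, pd, TRUE)$auc + rocAuc(hc, pd, FALSE)$auc, 1)
  a <- rocAuc(rnorm(20, 2), rnorm(20, 1))
  expect_true(a$ciLow <= a$auc && a$auc <= a$ciHigh)
  expect_error(rocAuc(numeric(0), c(1)), "non-empty")
})

test_that("Bland-Altman summarizes differences with 95% limits", {
  x <- c(1, 2, 3, 4)
  ba <- blandAltman(x, x)
  expect_identical(c(ba$meanDiff, ba$sdDiff), c(0, 0))
  ba2 <- blandAltman(x, x - 1)
  expect_identical(c(ba2$meanDiff, ba2$sdDiff), c(1, 0))
  set.seed(2)
  a <- rnorm(2000); b <- a + rnorm(2000, 0, 0.3)
  ba3 <- blandAltman(a, b)
  inside <- mean(ba3$diffs > ba3$loaLow & ba3$diffs < ba3$loaHigh)
  expect_equal(inside, 0.95, tolerance = 0.02)
})

test_that("TRV is symmetric, scale-free and matches hand arithmetic", {
  expect_identical(trv(3, 3), 0)
  expect_equal(trv(4, 5), 100 / 4.5)
  set.seed(3)
  for (i in seq_len(20)) {
    a <- runif(1, 0.5, 5); b <- runif(1, 0.5, 5)
    expect_equal(trv(a, b), trv(b, a))
    expect_equal(trv(10 * a, 10 * b), trv(a, b))
  }
  expect_error(trv(1, -2), "> 0")
})

test_that("ALC annualizes percent change with sign = decline", {
  expect_identical(alc(4, 4, 2), 0)
  expect_equal(alc(4.0, 3.6, 2), 5)
  expect_equal(alc(4.0, 3.6, 1), 2 * alc(4.0, 3.6, 2))
  expect_equal(alc(30, 27, 1.5), alc(10, 9, 1.5))  # scale invariance
  expect_lt(alc(4, 4.4, 2), 0)                     # increase is negative
  expect_error(alc(0, 1, 1), "> 0")
  expect_error(alc(1, 1, 0), "> 0")
})

test_that("paired t-tests apply the Bonferroni threshold", {
  set.seed(17)
  spread <- rnorm(5, 0, 10)
  shifted <- rnorm(30, 5, 1)
  res <- pairedTBonferroni(list(null = spread, shift = shifted), 3L)
  expect_equal(attr(res, "threshold"), 0.05 / 3, tolerance = 1e-12)
  expect_false(res$significant[res$comparison == "null"])
  expect_true(res$significant[res$comparison == "shift"])
  expect_error(pairedTBonferroni(list(const = rep(2, 5))), "degenerate")
  # p-value ranks agree with a permutation oracle
  permP <- function(d, n = 2000) {
    obs <- abs(mean(d))
    set.seed(99)
    hits <- vapply(seq_len(n), function(i)
      abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE))) >= obs,
      logical(1))
    mean(hits)
  }
  d1 <- rnorm(12, 0.2); d2 <- rnorm(12, 1.5); d3 <- rnorm(12, 0)
  tres <- pairedTBonferroni(list(a = d1, b = d2, c = d3), 3L)
  expect_identical(order(tres$p), order(c(permP(d1), permP(d2), permP(d3))))
})

test_that("statistics are invariant to subject reordering", {
  set.seed(41)
  x <- rnorm(15, 3); y <- rnorm(15, 2.8)
  perm <- sample(15)
  expect_equal(linCcc(x[perm], y[perm]), linCcc(x, y))
  expect_equal(cohensD(x[perm], y[perm]), cohensD(x, y))
  expect_equal(blandAltman(x[perm], y[perm])$meanDiff,
               blandAltman(x, y)$meanDiff)
  expect_equal(rocAuc(x[perm], y[perm])$auc, rocAuc(x, y)$auc)
})
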