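test_that("SUVR is exact on identity and scaled curves", {
  tgt <- TimeActivityCurve(fixSchedule, 2 * activity(fixRef), "t")
  expect_identical(computeSuvr(fixRef, fixRef, lateWindow()), 1)
  expect_equal(computeSuvr(tgt, fixRef, lateWindow()), 2, tolerance = 1e-15)
  # symmetric under common rescaling of both curves
  half <- TimeActivityCurve(fixSchedule, activity(fixRef) / 2, "r")
  halfT <- TimeActivityCurve(fixSchedule, activity(tgt) / 2, "t")
  expect_equal(computeSuvr(halfT, half, lateWindow()),
               computeSuvr(tgt, fixRef, lateWindow()))
})

test_that("SUVR window handling errors are informative", {
  expect_error(computeSuvr(fixRef, fixRef, SuvrWindow(90.5, 91)),
               "no frame midpoints")
  neg <- TimeActivityCurve(fixSchedule, -activity(fixRef), "r")
  expect_error(computeSuvr(fixRef, neg, lateWindow()), "not positive")
})

test_that("late SUVR exceeds early SUVR and both track DVR", {
  suvrLate <- c(); suvrEarly <- c(); dvrs <- c()
  for (bp in c(0.5, 1, 2, 3, 4)) {
    tgt <- srtmForward(fixRef, SrtmParams(1, 0.10, bp))
    suvrLate <- c(suvrLate, computeSuvr(tgt, fixRef, lateWindow()))
    suvrEarly <- c(suvrEarly, computeSuvr(tgt, fixRef, earlyWindow()))
    dvrs <- c(dvrs, bp + 1)
  }
  expect_true(all(suvrLate > suvrEarly))
  expect_gt(summary(stats::lm(suvrLate ~ dvrs))$r.squared, 0.9)
  expect_gt(summary(stats::lm(suvrEarly ~ dvrs))$r.squared, 0.9)
})

test_that("clearance fit recovers noiseless exponentials and flat curves", {
  tac <- exactExpTac(fixSchedule, 2.0, 0.015)
  expect_equal(fitClearanceRate(tac, lateWindow()), 0.015,
               tolerance = 1e-6)
  flat <- exactExpTac(fixSchedule, 3.0, 0)
  expect_equal(fitClearanceRate(flat, lateWindow()), 0, tolerance = 1e-8)
  # rising curves yield negative rates, carried through unclamped
  rising <- exactExpTac(fixSchedule, 1.0, -0.01)
  expect_lt(fitClearanceRate(rising, lateWindow()), 0)
})

test_that("clearance fit matches a brute-force grid-search oracle under noise", {
  tac <- exactExpTac(fixSchedule, 2.0, 0.015)
  idx <- which(frameMidpoints(fixSchedule) >= 50 &
               frameMidpoints(fixSchedule) < 80)
  s <- frameStarts(fixSchedule)[idx]; d <- frameDurations(fixSchedule)[idx]
  gridFit <- function(y) {
    betas <- seq(0.001, 0.04, by = 1e-5)
    rss <- vapply(betas, function(b) {
      m <- exp(-b * s) * (1 - exp(-b * d)) / (b * d)
      A <- sum(d * m * y) / sum(d * m * m)
      sum(d * (y - A * m)^2)
    }, numeric(1))
    betas[which.min(rss)]
  }
  ours <- c(); oracle <- c()
  for (i in seq_len(100)) {
    noisy <- addFrameNoise(tac, 0.02, seed = 7000L + i)
    ours <- c(ours, fitClearanceRate(noisy, lateWindow()))
    oracle <- c(oracle, gridFit(activity(noisy)[idx]))
  }
  expect_lt(max(abs(ours - oracle)), 2e-5)
  expect_equal(sd(ours), sd(oracle), tolerance = 0.05)
})

test_that("clearance fit rejects bad windows and non-positive activity", {
  expect_error(fitClearanceRate(fixRef, SuvrWindow(89, 93)), ">= 3 frames")
  bad <- TimeActivityCurve(fixSchedule, activity(fixRef) - 50, "r")
  expect_error(fitClearanceRate(bad, lateWindow()), "strictly positive")
})

test_that("composite TAC is a volume-weighted frame-wise mean", {
  c1 <- exactExpTac(fixSchedule, 2, 0.01, "caudate")
  expect_equal(activity(compositeTac(list(c1, c1), c(1, 1))), activity(c1))
  zero <- TimeActivityCurve(fixSchedule, rep(0, 37), "putamen")
  comp <- compositeTac(list(c1, zero), c(1, 3))
  expect_equal(activity(comp), 0.25 * activity(c1))
  # composite lies frame-wise between its inputs
  c2 <- exactExpTac(fixSchedule, 3, 0.02, "putamen")
  mid <- activity(compositeTac(list(c1, c2), c(4, 6)))
  lo <- pmin(activity(c1), activity(c2))
  hi <- pmax(activity(c1), activity(c2))
  expect_true(all(mid >= lo - 1e-12 & mid <= hi + 1e-12))
  expect_error(compositeTac(list(c1, c2), c(-1, 1)), "> 0")
})

test_that("regression clearance estimator follows its defining algebra", {
  expect_identical(estimateBetaTar(4, 4, 0.014, 0.0024), 0.014)
  expect_identical(estimateBetaTar(2, 4, 0.014, 0), 0.014)
  expect_equal(estimateBetaTar(2, 4, 0.014, 0.0024),
               0.014 + 0.0024 * (0.5 - 0.25), tolerance = 1e-15)
  expect_error(estimateBetaTar(-1, 4, 0.014, 0.0024), "> 0")
  # affine in 1/SUVRtar with slope a (finite differences)
  a <- 0.0024
  s <- c(1.5, 2.5, 4, 6)
  b <- estimateBetaTar(s, 4, 0.014, a)
  slopes <- diff(b) / diff(1 / s)
  expect_equal(slopes, rep(a, 3), tolerance = 1e-12)
  # strictly decreasing in target availability
  expect_true(all(diff(b) < 0))
})

test_that("SUVRc equals SUVR at equilibrium and matches hand evaluation", {
  expect_identical(correctSuvr(2.7, 0, 0), 2.7)
  expect_equal(correctSuvr(3.0, 0.02, 0.012), 3.0 / 1.16,
               tolerance = 1e-15)
  expect_error(correctSuvr(3.0, 0.2, -0.05), "not positive")
})

test_that("SUVRc inverts its denominator and is monotone in SUVR", {
  cfg <- CorrectionConfig()
  set.seed(31)
  for (i in seq_len(200)) {
    s <- runif(1, 0.5, 8); br <- runif(1, 0, 0.04); bt <- runif(1, 0, 0.03)
    den <- 1 - br / cfg@k2Ref + bt * s / (cfg@k2Ref * cfg@r1Assumed)
    if (den <= 0) next
    expect_equal(correctSuvr(s, br, bt, cfg) * den, s, tolerance = 1e-14)
  }
  s <- seq(1, 6, by = 0.5)
  out <- correctSuvr(s, 0.02, 0.012)
  expect_true(all(diff(out) > 0))
})

test_that("leave-one-out OLS recovers the radiotracer constant exactly", {
  makeSubject <- function(i, a) {
    sC <- 3 + 0.2 * i
    sT <- c(r1 = sC * 1.05, r2 = sC * 0.5, r3 = sC * 0.8)
    bC <- 0.012 + 0.0005 * i
    list(suvrTar = sT, suvrComposite = sC, betaComposite = bC,
         betaTar = bC + a * (1 / sT - 1 / sC))
  }
  training <- lapply(1:6, makeSubject, a = 0.0024)
  est <- estimateRadiotracerConstant(training)
  expect_equal(est$a, 0.0024, tolerance = 1e-9)
  expect_true(all(abs(est$folds - 0.0024) < 1e-9))
  trainingZero <- lapply(1:6, makeSubject, a = 0)
  expect_lt(abs(estimateRadiotracerConstant(trainingZero)$a), 1e-12)
  degenerate <- lapply(1:4, function(i)
    list(suvrTar = c(a = 3, b = 3), suvrComposite = 3,
         betaComposite = 0.012, betaTar = c(a = 0.012, b = 0.012)))
  expect_error(estimateRadiotracerConstant(degenerate), "degenerate")
  expect_error(estimateRadiotracerConstant(training[1:2]), "at least 3")
})

test_that("identity subject quantifies to DVR = SUVR = SUVRc = 1", {
  regions <- c("accumbens", "caudate", "putamen", "SMS", "SN", "cerebellum")
  tacs <- lapply(setNames(regions, regions), function(r)
    TimeActivityCurve(fixSchedule, activity(fixRef), r))
  ts <- TacSet(tacs, volumes = c(caudate = 4, putamen = 6))
  q <- quantifySubject(ts)
  expect_equal(q$outcomes$dvr, rep(1, 6), tolerance = 1e-5)
  expect_equal(q$outcomes$suvr_50_80, rep(1, 6), tolerance = 1e-12)
  expect_equal(q$outcomes$suvrc, rep(1, 6), tolerance = 1e-10)
  expect_equal(q$clearance@betaRef, q$clearance@betaComposite,
               tolerance = 1e-12)
})

test_that("quantifySubject validates required regions", {
  tacs <- list(cerebellum = fixRef,
               caudate = srtmForward(fixRef, SrtmParams(1, 0.1, 2),
                                     region = "caudate"))
  ts <- TacSet(tacs)
  expect_error(quantifySubject(ts), "composite member")
  expect_error(quantifySubject(ts, refRegion = "pons"), "reference region")
})
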