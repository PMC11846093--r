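test_that("all-unity spec collapses every region onto the reference", {
  recs <- generateCrossSectional(identitySpecIo())
  for (ts in recs) {
    ref <- activity(getTac(ts, "cerebellum"))
    for (r in setdiff(rownames(ts), "cerebellum")) {
      expect_equal(activity(getTac(ts, r)), ref, tolerance = 1e-10)
      expect_equal(computeSuvr(getTac(ts, r), getTac(ts, "cerebellum"),
                               lateWindow()), 1, tolerance = 1e-10)
      expect_equal(computeSuvr(getTac(ts, r), getTac(ts, "cerebellum"),
                               earlyWindow()), 1, tolerance = 1e-10)
    }
  }
})

test_that("cohort generation is reproducible from the spec alone", {
  a <- generateCrossSectional(smallSpec())
  b <- generateCrossSectional(smallSpec())
  expect_length(a, 6L)
  for (i in seq_along(a)) {
    expect_identical(SummarizedExperiment::assay(a[[i]], "activity"),
                     SummarizedExperiment::assay(b[[i]], "activity"))
    expect_identical(S4Vectors::metadata(a[[i]])$truth,
                     S4Vectors::metadata(b[[i]])$truth)
  }
  # a different master seed changes the data
  c1 <- generateCrossSectional(smallSpec(seed = 12L))
  expect_false(identical(
    SummarizedExperiment::assay(a[[1]], "activity"),
    SummarizedExperiment::assay(c1[[1]], "activity")))
})

test_that("subject metadata carries group, visit and truth", {
  recs <- generateCrossSectional(smallSpec())
  md <- S4Vectors::metadata(recs[[1]])
  expect_equal(md$group, "HC")
  expect_equal(md$visit, "single")
  expect_true(all(c("k1Ref", "k2Ref", "plasma", "regions") %in%
                  names(md$truth)))
  expect_true(all(md$truth$regions$dvr >= 1))
  groups <- vapply(recs, function(x) S4Vectors::metadata(x)$group,
                   character(1))
  expect_equal(as.integer(table(groups)[c("HC", "PD")]), c(3L, 3L))
})

test_that("noise-free, jitter-free test-retest pairs have zero TRV", {
  prs <- generateTestRetest(identitySpecIo())
  expect_length(prs, 1L)
  q1 <- quantifySubject(prs[[1]]$test)$outcomes
  q2 <- quantifySubject(prs[[1]]$retest)$outcomes
  for (col in c("dvr", "suvr_50_80", "suvr_15_45", "suvrc"))
    expect_equal(trv(q1[[col]], q2[[col]]), rep(0, nrow(q1)),
                 tolerance = 1e-8)
})

test_that("test-retest keeps the truth fixed and perturbs the scan", {
  spec <- smallSpec()
  prs <- generateTestRetest(spec)
  expect_length(prs, spec@nTestRetest)
  t1 <- S4Vectors::metadata(prs[[1]]$test)$truth
  t2 <- S4Vectors::metadata(prs[[1]]$retest)$truth
  expect_identical(t1$regions, t2$regions)
  expect_false(t1$k1Ref == t2$k1Ref)       # between-scan perturbation
  expect_false(t1$plasma[["l3"]] == t2$plasma[["l3"]])
})

test_that("zero-decline longitudinal cohorts change nothing", {
  prs <- generateLongitudinal(identitySpecIo())
  p <- prs[[1]]
  expect_equal(p$trueAlc, setNames(rep(0, 5), names(p$trueAlc)))
  q1 <- quantifySubject(p$baseline)$outcomes
  q2 <- quantifySubject(p$followup)$outcomes
  expect_equal(alc(q1$dvr, q2$dvr, p$intervalYears), rep(0, nrow(q1)),
               tolerance = 1e-6)
})

test_that("longitudinal decline lowers follow-up DVR and raises clearance", {
  spec <- smallSpec()
  prs <- generateLongitudinal(spec)
  expect_length(prs, spec@nLongitudinal)
  p <- prs[[1]]
  t1 <- S4Vectors::metadata(p$baseline)$truth
  t2 <- S4Vectors::metadata(p$followup)$truth
  striatal <- t1$regions$region %in% c("caudate", "putamen")
  expect_true(all(t2$regions$dvr[striatal] < t1$regions$dvr[striatal]))
  expect_true(all(t2$regions$k2a[striatal] > t1$regions$k2a[striatal]))
  expect_gt(p$intervalYears, 0.5)
  # the drawn interval is exactly what the true ALC uses
  expect_equal(p$trueAlc[["putamen"]],
               100 * (t1$regions$dvr[3] - t2$regions$dvr[3]) /
                 t1$regions$dvr[3] / p$intervalYears)
})

test_that("catastrophic decline is truncated at DVR = 1 and flagged", {
  reg <- data.frame(region = c("accumbens", "caudate", "putamen",
                               "SMS", "SN"),
                    hcMean = c(3.4, 4.3, 4.6, 4.5, 1.9), hcSd = 0,
                    pdMean = c(1.1, 1.1, 1.1, 1.1, 1.05), pdSd = 0,
                    declineMean = 40, declineSd = 0)
  spec <- cohortSpec(nHc = 1L, nPd = 1L, regions = reg, noiseScale = 0,
                     nLongitudinal = 1L, seed = 5L)
  p <- generateLongitudinal(spec)[[1]]
  t2 <- S4Vectors::metadata(p$followup)$truth
  expect_true(any(p$declineTruncated))
  expect_true(all(t2$regions$dvr >= 1))
})

test_that("R1 sensitivity table has the stated shape and null point", {
  expect_error(r1SensitivityExperiment(r1Grid = c(0, 1)), "\\(0, 2\\]")
  grid <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  tab <- r1SensitivityExperiment(r1Grid = grid)
  expect_equal(nrow(tab), 2L * length(grid))
  expect_setequal(unique(tab$scenario), c("HC", "PD"))
  for (sc in c("HC", "PD")) {
    sub <- tab[tab$scenario == sc, ]
    expect_lt(abs(sub$suvrcErrorPct[sub$r1True == 1]), 1)
    # error grows monotonically as the assumed R1 = 1 becomes wrong
    below <- sub[sub$r1True <= 1, ]
    above <- sub[sub$r1True >= 1, ]
    expect_true(all(diff(abs(below$suvrcErrorPct)) <= 0))
    expect_true(all(diff(abs(above$suvrcErrorPct)) >= 0))
  }
})

test_that("training cohorts have the documented structure", {
  tr <- simulateTrainingCohort(n = 5L, seed = 2L)
  expect_length(tr, 5L)
  s <- tr[[1]]
  expect_named(s, c("suvrTar", "suvrComposite", "betaComposite", "betaTar"))
  expect_length(s$suvrTar, 4L)
  expect_true(all(s$suvrTar > 0))
  # noiseless generation is recovered exactly through the LOO estimator
  clean <- simulateTrainingCohort(n = 6L, a = 0.003, betaNoiseSd = 0,
                                  seed = 4L)
  expect_equal(estimateRadiotracerConstant(clean)$a, 0.003,
               tolerance = 1e-12)
})

test_that("scan-derived training subjects carry SRTM-based clearances", {
  recs <- generateCrossSectional(identitySpecIo())
  tr <- trainingFromCohort(recs[1])
  expect_length(tr[[1]]$suvrTar, 5L)
  expect_equal(unname(tr[[1]]$suvrComposite), 1, tolerance = 1e-8)
  expect_equal(unname(tr[[1]]$betaTar),
               rep(tr[[1]]$betaComposite, 5), tolerance = 1e-4)
})
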