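# Shared fixtures, built in code. The default schedule and one noiseless
# reference curve are reused across test files.

fixSchedule <- fePe2iSchedule()
fixRef <- simulateReferenceTac(K1 = 0.35, k2Prime = 0.10,
                               schedule = fixSchedule)

# exact frame-averaged mono-exponential A*exp(-beta t) on a schedule
exactExpTac <- function(schedule, A, beta, region = "x") {
  s <- frameStarts(schedule); d <- frameDurations(schedule)
  vals <- if (beta == 0) rep(A, length(s)) else
    A * exp(-beta * s) * (1 - exp(-beta * d)) / (beta * d)
  TimeActivityCurve(schedule, vals, region)
}

# small fast cohort spec for pipeline-level tests
smallSpec <- function(seed = 11L)
  cohortSpec(nHc = 3L, nPd = 3L, nTestRetest = 2L, nLongitudinal = 2L,
             seed = seed)

# degenerate spec: unit DVR everywhere, no noise, no heterogeneity
identitySpecIo <- function(seed = 3L) {
  reg <- data.frame(
    region = c("accumbens", "caudate", "putamen", "SMS", "SN"),
    hcMean = 1, hcSd = 0, pdMean = 1, pdSd = 0,
    declineMean = 0, declineSd = 0)
  cohortSpec(nHc = 1L, nPd = 1L, regions = reg, r1Mean = 1, r1Sd = 0,
             noiseScale = 0, nTestRetest = 1L, testRetestJitter = 0,
             nLongitudinal = 1L, intervalSdYears = 0, seed = seed)
}
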