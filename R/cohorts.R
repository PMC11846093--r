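# Synthetic cohort generation. Regional DVR distributions, kinetic
# parameters and the plasma input are calibration choices of this package
# (no regional DVR tables exist to copy); they are set so that the
# quantification path yields group-mean target clearance rates near
# 0.010 min^-1 (HC-like) and 0.013 min^-1 (PD-like) in the 50-80 min
# window, with striatal group separation of Cohen's d > 1. See the
# vignette for the calibration procedure.

.defaultRegionTable <- function() {
  data.frame(
    region      = c("accumbens", "caudate", "putamen", "SMS", "SN"),
    hcMean      = c(3.4, 4.3, 4.6, 4.5, 1.9),
    hcSd        = c(0.50, 0.80, 0.90, 0.90, 0.18),
    pdMean      = c(2.6, 3.2, 2.9, 2.5, 1.6),
    pdSd        = c(0.45, 0.70, 0.80, 0.70, 0.14),
    declineMean = c(3.8, 5.3, 4.5, 4.0, 0.4),
    declineSd   = c(3.0, 3.0, 3.0, 3.0, 2.0))
}

#' Construct a cohort specification
#'
#' Defaults emulate dopamine-transporter PET in healthy controls (HC) and
#' Parkinson's disease (PD): 38 subjects per cross-sectional group, 9
#' test-retest pairs, 21 longitudinal pairs with a 2.3 +- 0.5 year
#' interval, striatal DVR reduced in PD, and a ~4-5 %/year true striatal
#' DVR decline. All values are generator calibration choices, not measured
#' data.
#'
#' @param nHc,nPd cross-sectional group sizes.
#' @param regions region table, see [CohortSpec-class].
#' @param dvrFloor lower truncation for drawn DVR (no negative binding).
#' @param r1Mean,r1Sd true delivery-ratio distribution.
#' @param k2RefMean,k2RefSd reference efflux-rate distribution (min^-1).
#' @param k1RefMean,k1RefSd reference K1 distribution (min^-1).
#' @param plasma plasma-input parameters, see [fengInput()].
#' @param noiseScale frame-noise scale, see [addFrameNoise()]; default
#'   calibrated to give striatal DVR test-retest variability near 3%.
#' @param nTestRetest number of test-retest pairs.
#' @param testRetestJitter SD of the multiplicative between-scan jitter on
#'   reference K1 and plasma terminal clearance (physiological day-to-day
#'   variation).
#' @param nLongitudinal number of longitudinal pairs.
#' @param intervalMeanYears,intervalSdYears longitudinal scan-interval
#'   distribution.
#' @param seed master seed; every subject/visit is regenerable from
#'   `(spec, subject index, visit index)` via a fixed affine seed scheme.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nHc = 38L, nPd = 38L,
                       regions = .defaultRegionTable(),
                       dvrFloor = 1.0,
                       r1Mean = 1.0, r1Sd = 0.05,
                       k2RefMean = 0.10, k2RefSd = 0.010,
                       k1RefMean = 0.35, k1RefSd = 0.04,
                       plasma = defaultPlasmaParams(),
                       noiseScale = 1.2,
                       nTestRetest = 9L, testRetestJitter = 0.03,
                       nLongitudinal = 21L,
                       intervalMeanYears = 2.3, intervalSdYears = 0.5,
                       seed = 20260921L) {
  new("CohortSpec", nHc = as.integer(nHc), nPd = as.integer(nPd),
      regions = regions, dvrFloor = dvrFloor,
      r1Mean = r1Mean, r1Sd = r1Sd,
      k2RefMean = k2RefMean, k2RefSd = k2RefSd,
      k1RefMean = k1RefMean, k1RefSd = k1RefSd,
      plasma = plasma, noiseScale = noiseScale,
      nTestRetest = as.integer(nTestRetest),
      testRetestJitter = testRetestJitter,
      nLongitudinal = as.integer(nLongitudinal),
      intervalMeanYears = intervalMeanYears,
      intervalSdYears = intervalSdYears,
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: HC n=%d, PD n=%d; test-retest n=%d; longitudinal n=%d\n",
    object@nHc, object@nPd, object@nTestRetest, object@nLongitudinal))
  cat(sprintf("  noiseScale=%.3g, seed=%d\n", object@noiseScale, object@seed))
})

# deterministic per-(subject, visit) seed, kept below 2^31
.subjectSeed <- function(master, subjectIndex, visitIndex) {
  as.integer((as.numeric(master) + 10007 * subjectIndex +
              101 * visitIndex) %% 2147483647)
}

# truncated-normal draw by rejection (falls back to the bound)
.rtrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lower), upper)
}

# draw subject-level kinetic truth (deterministic given seed).
# Regional efflux is tied to binding: all regions of a subject share a
# near-common apparent clearance rate k2a (the composite's SRTM value,
# jittered ~5% per region), i.e. k2 = k2a * DVR. This reproduces the
# narrow regional clearance-rate spread observed for fast DAT tracers;
# fully independent regional efflux would make low-binding regions clear
# far faster than the striatum, which is not what such tracers show.
.drawTruth <- function(spec, group, subjectIndex, visitIndex) {
  set.seed(.subjectSeed(spec@seed, subjectIndex, visitIndex))
  reg <- spec@regions
  mu <- if (group == "HC") reg$hcMean else reg$pdMean
  sg <- if (group == "HC") reg$hcSd else reg$pdSd
  dvrTrue <- .rtrunc(nrow(reg), mu, sg, lower = spec@dvrFloor)
  r1 <- .rtrunc(nrow(reg), spec@r1Mean, spec@r1Sd, 0.7, 1.3)
  k2Ref <- .rtrunc(1, spec@k2RefMean, spec@k2RefSd, 0.05, 0.2)
  k1Ref <- .rtrunc(1, spec@k1RefMean, spec@k1RefSd, 0.15, 0.6)
  names(dvrTrue) <- reg$region
  dvrComp <- (4 * dvrTrue[["caudate"]] + 6 * dvrTrue[["putamen"]]) / 10
  k2aJitter <- exp(rnorm(nrow(reg), 0, 0.05))
  k2a <- k2Ref / dvrComp * k2aJitter
  list(group = group, subjectIndex = subjectIndex,
       visitIndex = visitIndex,
       k1Ref = k1Ref, k2Ref = k2Ref, plasma = spec@plasma,
       k2aJitter = k2aJitter,
       regions = data.frame(region = reg$region, dvr = unname(dvrTrue),
                            r1 = r1, k2a = k2a, k2 = k2a * dvrTrue))
}

# render one scan (TacSet) from a truth record, adding seeded frame noise
.renderScan <- function(spec, truth, schedule, fineDt = 1 / 60,
                        noiseSeedOffset = 0L) {
  t <- .fineGrid(schedule, fineDt)
  cp <- fengInput(t, truth$plasma)
  refFine <- truth$k1Ref * .convExp(cp, fineDt, truth$k2Ref)
  refTac <- TimeActivityCurve(schedule, .frameAverage(t, refFine, schedule),
                              "cerebellum")
  tacs <- list()
  for (i in seq_len(nrow(truth$regions))) {
    rr <- truth$regions[i, ]
    k2 <- rr$k2; k2a <- rr$k2a
    ct <- .srtmForwardFine(t, refFine, rr$r1, k2, k2a, fineDt)
    tacs[[rr$region]] <- TimeActivityCurve(
      schedule, .frameAverage(t, ct, schedule), rr$region)
  }
  tacs$cerebellum <- refTac
  baseSeed <- .subjectSeed(spec@seed, truth$subjectIndex,
                           truth$visitIndex) + 500000L + noiseSeedOffset
  if (spec@noiseScale > 0) {
    for (i in seq_along(tacs))
      tacs[[i]] <- addFrameNoise(tacs[[i]], spec@noiseScale,
                                 baseSeed + 17L * i)
  }
  TacSet(tacs, schedule,
         volumes = c(caudate = 4, putamen = 6),
         metadata = list(truth = truth))
}

#' Generate a cross-sectional synthetic cohort
#'
#' Draws per-subject regional DVR, delivery ratio and reference kinetics,
#' forward-simulates all regional TACs under SRTM, and adds seeded frame
#' noise. Deterministic given the spec (one fixed seed scheme per subject).
#'
#' @param spec a [CohortSpec-class].
#' @param schedule acquisition schedule (default [fePe2iSchedule()]).
#' @return list of [TacSet-class], one per subject; `metadata()` carries
#'   `subject`, `group`, `visit` and the simulation `truth`.
#' @export
generateCrossSectional <- function(spec = cohortSpec(),
                                   schedule = fePe2iSchedule()) {
  stopifnot(is(spec, "CohortSpec"))
  records <- list()
  idx <- 0L
  for (group in c("HC", "PD")) {
    n <- if (group == "HC") spec@nHc else spec@nPd
    for (i in seq_len(n)) {
      idx <- idx + 1L
      truth <- .drawTruth(spec, group, idx, 1L)
      ts <- .renderScan(spec, truth, schedule)
      S4Vectors::metadata(ts)$subject <- sprintf("%s%02d", group, i)
      S4Vectors::metadata(ts)$group <- group
      S4Vectors::metadata(ts)$visit <- "single"
      records[[length(records) + 1L]] <- ts
    }
  }
  records
}

#' Generate a test-retest synthetic cohort
#'
#' Each subject is scanned twice with identical true kinetic parameters,
#' independent frame-noise realisations, and a small seeded between-scan
#' perturbation of the reference-curve shape (multiplicative jitter on
#' reference K1 and on the plasma terminal clearance), emulating
#' physiological day-to-day variation.
#'
#' @inheritParams generateCrossSectional
#' @param group cohort group label (default `"PD"`).
#' @return list of length `nTestRetest`; each element is a list of two
#'   [TacSet-class] objects (`test`, `retest`).
#' @export
generateTestRetest <- function(spec = cohortSpec(),
                               schedule = fePe2iSchedule(),
                               group = "PD") {
  stopifnot(is(spec, "CohortSpec"))
  pairs <- list()
  for (i in seq_len(spec@nTestRetest)) {
    idx <- 1000L + i
    truth <- .drawTruth(spec, group, idx, 1L)
    test <- .renderScan(spec, truth, schedule)
    # retest: same kinetic truth, perturbed physiology, independent noise
    set.seed(.subjectSeed(spec@seed, idx, 2L))
    truth2 <- truth
    truth2$visitIndex <- 2L
    truth2$k1Ref <- truth$k1Ref * (1 + spec@testRetestJitter * rnorm(1))
    truth2$plasma["l3"] <- truth$plasma[["l3"]] *
      (1 + spec@testRetestJitter * rnorm(1))
    retest <- .renderScan(spec, truth2, schedule)
    for (v in c("test", "retest")) {
      ts <- if (v == "test") test else retest
      S4Vectors::metadata(ts)$subject <- sprintf("TR%02d", i)
      S4Vectors::metadata(ts)$group <- group
      S4Vectors::metadata(ts)$visit <- v
      if (v == "test") test <- ts else retest <- ts
    }
    pairs[[i]] <- list(test = test, retest = retest)
  }
  pairs
}

#' Generate a longitudinal synthetic cohort
#'
#' Baseline and follow-up scans per subject. The follow-up DVR of each
#' region is the baseline DVR reduced by a drawn annual percent decline
#' compounded over a drawn scan interval, truncated at DVR = 1 (and flagged
#' when truncated). Because follow-up binding is lower, the follow-up
#' target clearance increases through the kinetics, not by construction.
#'
#' @inheritParams generateTestRetest
#' @return list of length `nLongitudinal`; each element has `baseline` and
#'   `followup` [TacSet-class] objects plus `intervalYears` and the true
#'   per-region annualized change `trueAlc` (percent/year).
#' @export
generateLongitudinal <- function(spec = cohortSpec(),
                                 schedule = fePe2iSchedule(),
                                 group = "PD") {
  stopifnot(is(spec, "CohortSpec"))
  out <- list()
  for (i in seq_len(spec@nLongitudinal)) {
    idx <- 2000L + i
    truth <- .drawTruth(spec, group, idx, 1L)
    baseline <- .renderScan(spec, truth, schedule)
    set.seed(.subjectSeed(spec@seed, idx, 2L))
    interval <- .rtrunc(1, spec@intervalMeanYears, spec@intervalSdYears,
                        lower = 0.5)
    reg <- spec@regions
    declinePct <- .rtrunc(nrow(reg), reg$declineMean, reg$declineSd,
                          lower = -10, upper = 30)
    truth2 <- truth
    truth2$visitIndex <- 2L
    dvrF <- truth$regions$dvr * (1 - declinePct / 100)^interval
    truncated <- dvrF < spec@dvrFloor
    dvrF <- pmax(dvrF, spec@dvrFloor)
    truth2$regions$dvr <- dvrF
    # binding loss speeds apparent clearance: k2a re-anchored to the
    # follow-up composite DVR (same per-region jitter), k2 = k2a * DVR
    names(dvrF) <- truth$regions$region
    dvrCompF <- (4 * dvrF[["caudate"]] + 6 * dvrF[["putamen"]]) / 10
    truth2$regions$k2a <- truth$k2Ref / dvrCompF * truth$k2aJitter
    truth2$regions$k2 <- truth2$regions$k2a * truth2$regions$dvr
    truth2$declineTruncated <- truncated
    followup <- .renderScan(spec, truth2, schedule)
    trueAlc <- 100 * (truth$regions$dvr - dvrF) / truth$regions$dvr / interval
    names(trueAlc) <- reg$region
    for (v in c("baseline", "followup")) {
      ts <- if (v == "baseline") baseline else followup
      S4Vectors::metadata(ts)$subject <- sprintf("LG%02d", i)
      S4Vectors::metadata(ts)$group <- group
      S4Vectors::metadata(ts)$visit <- v
      if (v == "baseline") baseline <- ts else followup <- ts
    }
    out[[i]] <- list(baseline = baseline, followup = followup,
                     intervalYears = interval, trueAlc = trueAlc,
                     declineTruncated = truncated)
  }
  out
}

#' Delivery-ratio sensitivity experiment
#'
#' Quantifies the error that the a-priori assumption `R1 = 1` induces in
#' the corrected SUVR when the true delivery ratio differs from 1.
#' Noiseless putamen-like TACs are simulated with each true R1 from the
#' grid, quantified with `r1Assumed = 1`, and the percent error of SUVRc
#' against the true DVR is tabulated. Since the curves are noiseless, the
#' target clearance is fit directly from the simulated curve in the window.
#'
#' @param r1Grid numeric grid of true R1 values, all in (0, 2].
#' @param scenarios character, any of `"HC"` (putamen DVR 4.6) and `"PD"`
#'   (putamen DVR 2.6).
#' @param config a [CorrectionConfig-class] (its `r1Assumed` is used for
#'   the correction).
#' @param spec a [CohortSpec-class] supplying the kinetic and plasma
#'   defaults.
#' @param schedule acquisition schedule.
#' @return data.frame with one row per (scenario, grid point): `scenario`,
#'   `r1True`, `dvrTrue`, `suvr`, `suvrc`, `suvrErrorPct`, `suvrcErrorPct`.
#' @export
r1SensitivityExperiment <- function(r1Grid = seq(0.7, 1.3, by = 0.1),
                                    scenarios = c("HC", "PD"),
                                    config = CorrectionConfig(),
                                    spec = cohortSpec(),
                                    schedule = fePe2iSchedule()) {
  if (any(r1Grid <= 0) || any(r1Grid > 2))
    stop("r1Grid must lie in (0, 2]")
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  fineDt <- 1 / 60
  t <- .fineGrid(schedule, fineDt)
  cp <- fengInput(t, spec@plasma)
  refFine <- spec@k1RefMean * .convExp(cp, fineDt, spec@k2RefMean)
  ref <- TimeActivityCurve(schedule, .frameAverage(t, refFine, schedule),
                           "cerebellum")
  win <- config@window
  betaRef <- fitClearanceRate(ref, win)
  rows <- list()
  for (sc in scenarios) {
    reg <- spec@regions
    dvrTrue <- if (sc == "HC") reg$hcMean[reg$region == "putamen"] else
      reg$pdMean[reg$region == "putamen"]
    for (r1 in r1Grid) {
      k2 <- r1 * spec@k2RefMean
      ct <- .srtmForwardFine(t, refFine, r1, k2, k2 / dvrTrue, fineDt)
      tac <- TimeActivityCurve(schedule, .frameAverage(t, ct, schedule),
                               "putamen")
      suvr <- computeSuvr(tac, ref, win)
      betaTar <- fitClearanceRate(tac, win)
      suvrc <- correctSuvr(suvr, betaRef, betaTar, config)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, r1True = r1, dvrTrue = dvrTrue,
        suvr = suvr, suvrc = suvrc,
        suvrErrorPct = percentBias(suvr, dvrTrue),
        suvrcErrorPct = percentBias(suvrc, dvrTrue))
    }
  }
  do.call(rbind, rows)
}

#' Simulate a training cohort for the radiotracer constant
#'
#' Generates training subjects directly from the clearance regression with
#' a known generating constant `a`, plus Gaussian measurement noise on the
#' reference clearance values, for parameter-recovery checks of
#' [estimateRadiotracerConstant()]. Region SUVR profiles span high-binding
#' (caudate, putamen, ventral striatum) and low-binding (SN) tissue so the
#' inverse-SUVR regressor has realistic spread.
#'
#' @param n number of subjects.
#' @param a generating radiotracer constant (min^-1).
#' @param betaNoiseSd SD of the noise added to each reference clearance
#'   value (min^-1); the default, 0.0007, corresponds to ~5% single-scan
#'   measurement error on a typical clearance of 0.013 min^-1.
#' @param seed integer seed.
#' @return list of training subjects as accepted by
#'   [estimateRadiotracerConstant()].
#' @export
simulateTrainingCohort <- function(n = 20L, a = 0.0024,
                                   betaNoiseSd = 7e-4, seed = 1L) {
  set.seed(as.integer(seed))
  ratios <- c(caudate = 1.05, putamen = 0.95, ventral_striatum = 0.78,
              SN = 0.40)
  lapply(seq_len(n), function(i) {
    sC <- runif(1, 2.5, 4.5)
    sT <- sC * ratios * exp(rnorm(length(ratios), 0, 0.08))
    bC <- rnorm(1, 0.013, 0.002)
    bT <- bC + a * (1 / sT - 1 / sC) + rnorm(length(sT), 0, betaNoiseSd)
    list(suvrTar = sT, suvrComposite = sC, betaComposite = bC,
         betaTar = setNames(bT, names(sT)))
  })
}

#' Build training subjects from simulated scans
#'
#' Converts simulated [TacSet-class] scans into the training-subject format
#' of [estimateRadiotracerConstant()]: per-region SUVR in the window,
#' composite SUVR and clearance, and reference target clearances derived
#' from low-noise SRTM fits (the clearance of the fitted model curve within
#' the window).
#'
#' @param records list of [TacSet-class] scans.
#' @param config a [CorrectionConfig-class].
#' @param refRegion reference region name.
#' @return list of training subjects.
#' @export
trainingFromCohort <- function(records, config = CorrectionConfig(),
                               refRegion = "cerebellum") {
  win <- config@window
  lapply(records, function(ts) {
    ref <- getTac(ts, refRegion)
    members <- names(config@compositeVolumes)
    comp <- compositeTac(lapply(setNames(members, members),
                                function(r) getTac(ts, r)),
                         config@compositeVolumes)
    targets <- setdiff(rownames(ts), refRegion)
    suvrTar <- vapply(targets, function(r)
      computeSuvr(getTac(ts, r), ref, win), numeric(1))
    betaTar <- vapply(targets, function(r) {
      fit <- srtmFit(getTac(ts, r), ref)
      model <- srtmForward(ref, fit, region = r)
      fitClearanceRate(model, win)
    }, numeric(1))
    list(suvrTar = suvrTar,
         suvrComposite = computeSuvr(comp, ref, win),
         betaComposite = fitClearanceRate(comp, win),
         betaTar = betaTar)
  })
}
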