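# Windowed SUVR, tissue clearance rates, and the clearance-corrected SUVR
# (SUVRc). The correction divides SUVR by
#   1 - betaRef/k2Ref + betaTar*SUVR/(k2Ref*R1)
# which reduces to SUVR at true equilibrium (both clearance rates zero).

.framesInWindow <- function(schedule, window) {
  mids <- frameMidpoints(schedule)
  which(mids >= window@start & mids < window@end)
}

#' Windowed standardized uptake value ratio
#'
#' Ratio of the duration-weighted mean target activity to the
#' duration-weighted mean reference activity over the frames whose midpoints
#' fall in the half-open window `[start, end)`.
#'
#' @param target,ref [TimeActivityCurve-class] objects on one schedule.
#' @param window a [SuvrWindow-class].
#' @return unitless SUVR.
#' @export
computeSuvr <- function(target, ref, window) {
  stopifnot(is(target, "TimeActivityCurve"), is(ref, "TimeActivityCurve"),
            is(window, "SuvrWindow"))
  sched <- tacSchedule(target)
  idx <- .framesInWindow(sched, window)
  if (length(idx) == 0L)
    stop(sprintf("no frame midpoints in window [%g, %g)",
                 window@start, window@end))
  w <- frameDurations(sched)[idx]
  num <- sum(w * activity(target)[idx]) / sum(w)
  den <- sum(w * activity(ref)[idx]) / sum(w)
  if (den <= 0)
    stop("reference mean activity in window is not positive")
  num / den
}

# frame-averaged exp(-beta t) over [s, e): exp(-beta s)(1-exp(-beta d))/(beta d)
.frameAvgExp <- function(beta, s, d) {
  bd <- beta * d
  small <- abs(bd) < 1e-8
  out <- numeric(length(s))
  out[!small] <- exp(-beta * s[!small]) * (-expm1(-bd[!small])) / bd[!small]
  out[small] <- exp(-beta * s[small]) *
    (1 - bd[small] / 2 + bd[small]^2 / 6)
  out
}

#' Mono-exponential clearance rate within a window
#'
#' Least-squares fit of `A * exp(-beta * t)` to the frames of a TAC whose
#' midpoints fall in the window, weighted by frame duration. The model is
#' frame-averaged before comparison with the data (frame values are
#' time-averages), so noiseless frame-averaged exponentials are recovered
#' essentially exactly. `beta > 0` for decaying curves; negative rates
#' (still-rising uptake) are legal and returned as-is.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param window a [SuvrWindow-class] containing at least 3 frame midpoints.
#' @param betaRange numeric length-2 search bracket (min^-1).
#' @return clearance rate beta (min^-1).
#' @export
fitClearanceRate <- function(tac, window, betaRange = c(-0.2, 0.5)) {
  stopifnot(is(tac, "TimeActivityCurve"), is(window, "SuvrWindow"))
  sched <- tacSchedule(tac)
  idx <- .framesInWindow(sched, window)
  if (length(idx) < 3L)
    stop(sprintf("clearance fit needs >= 3 frames in window [%g, %g)",
                 window@start, window@end))
  y <- activity(tac)[idx]
  if (any(y <= 0))
    stop("clearance fit requires strictly positive activity in the window")
  s <- frameStarts(sched)[idx]; d <- frameDurations(sched)[idx]
  w <- d
  obj <- function(beta) {
    m <- .frameAvgExp(beta, s, d)
    A <- sum(w * m * y) / sum(w * m * m)
    sum(w * (y - A * m)^2)
  }
  opt <- optimize(obj, betaRange, tol = 1e-12)
  # polish: golden/parabolic search in a narrow bracket around the optimum
  span <- 1e-3
  opt2 <- optimize(obj, c(opt$minimum - span, opt$minimum + span),
                   tol = .Machine$double.eps^0.5)
  if (opt2$objective <= opt$objective) opt2$minimum else opt$minimum
}

#' Volume-weighted composite TAC
#'
#' Frame-wise volume-weighted mean of several regional TACs, e.g. the
#' caudate + putamen composite used to anchor clearance estimation.
#'
#' @param tacs list of [TimeActivityCurve-class] objects on one schedule.
#' @param volumes numeric volumes (mL), one per curve; matched by name when
#'   both are named.
#' @param region name of the composite region.
#' @return a [TimeActivityCurve-class].
#' @export
compositeTac <- function(tacs, volumes, region = "composite") {
  stopifnot(length(tacs) >= 1L, length(volumes) == length(tacs))
  if (any(volumes <= 0)) stop("volumes must be > 0")
  if (!is.null(names(volumes)) && !is.null(names(tacs))) {
    if (!setequal(names(volumes), names(tacs)))
      stop("volume names do not match TAC names")
    volumes <- volumes[names(tacs)]
  }
  sched <- tacSchedule(tacs[[1L]])
  for (tt in tacs[-1L]) {
    s2 <- tacSchedule(tt)
    if (!isTRUE(all.equal(frameStarts(sched), frameStarts(s2))) ||
        !isTRUE(all.equal(frameDurations(sched), frameDurations(s2))))
      stop("all TACs must share one schedule")
  }
  mat <- do.call(rbind, lapply(tacs, activity))
  TimeActivityCurve(sched, as.numeric(volumes %*% mat) / sum(volumes),
                    region = region)
}

#' Regression estimate of the target clearance rate
#'
#' Clearance of a target tissue from the composite-region clearance and the
#' inverse-SUVR difference:
#' `betaTar = betaComposite + a * (1/SUVRtar - 1/SUVRcomposite)`.
#' The estimate decreases with target availability: tissue holding more
#' tracer clears it more slowly.
#'
#' @param suvrTar,suvrComposite positive SUVR values.
#' @param betaComposite composite clearance rate (min^-1).
#' @param a radiotracer constant (min^-1).
#' @return estimated target clearance rate (min^-1). Vectorised over its
#'   arguments.
#' @export
estimateBetaTar <- function(suvrTar, suvrComposite, betaComposite, a) {
  if (any(suvrTar <= 0) || any(suvrComposite <= 0))
    stop("SUVR values must be > 0")
  betaComposite + a * (1 / suvrTar - 1 / suvrComposite)
}

#' Clearance-corrected SUVR
#'
#' Divides a windowed SUVR by the non-equilibrium correction factor
#' `1 - betaRef/k2Ref + betaTar*SUVR/(k2Ref*R1)`. When both clearance rates
#' are zero (true equilibrium) the correction is the identity. A
#' non-positive denominator indicates the correction left its domain of
#' validity and is raised as an error with the offending values, never
#' silently clamped.
#'
#' @param suvr windowed SUVR (target/reference).
#' @param betaRef reference clearance rate (min^-1).
#' @param betaTar target clearance rate (min^-1).
#' @param config a [CorrectionConfig-class] supplying `k2Ref` and
#'   `r1Assumed`.
#' @return corrected SUVR (unitless). Vectorised over `suvr`/`betaTar`.
#' @export
correctSuvr <- function(suvr, betaRef, betaTar, config = CorrectionConfig()) {
  stopifnot(is(config, "CorrectionConfig"))
  den <- 1 - betaRef / config@k2Ref +
    betaTar * suvr / (config@k2Ref * config@r1Assumed)
  bad <- den <= 0
  if (any(bad))
    stop(sprintf(
      paste0("SUVRc denominator not positive (first offence: SUVR=%.4g, ",
             "betaRef=%.4g, betaTar=%.4g, denominator=%.4g)"),
      suvr[bad][1L], betaRef, betaTar[bad][1L], den[bad][1L]))
  suvr / den
}

#' Leave-one-out estimate of the radiotracer constant
#'
#' For each left-out subject, the constant `a` of the clearance regression
#' is fit by through-origin ordinary least squares on the remaining
#' subjects' pooled (region, subject) points of
#' `betaTar - betaComposite  ~  a * (1/SUVRtar - 1/SUVRcomposite)`,
#' where `betaTar` is the low-noise reference value (e.g. derived from SRTM
#' fits to full dynamic data). The final estimate is the mean over folds.
#'
#' @param training list of training subjects; each element is a list with
#'   `suvrTar` (named numeric over target regions), `suvrComposite`
#'   (scalar), `betaComposite` (scalar) and `betaTar` (named numeric,
#'   reference values, same regions as `suvrTar`).
#' @return list with `a` (mean of folds) and `folds` (numeric per left-out
#'   subject).
#' @export
estimateRadiotracerConstant <- function(training) {
  n <- length(training)
  if (n < 3L) stop("need at least 3 training subjects")
  for (s in training) {
    if (length(s$suvrTar) < 2L)
      stop("each training subject needs >= 2 target regions")
    stopifnot(!is.null(s$suvrComposite), !is.null(s$betaComposite),
              length(s$betaTar) == length(s$suvrTar))
  }
  point <- function(s)
    list(x = 1 / s$suvrTar - 1 / s$suvrComposite,
         y = s$betaTar - s$betaComposite)
  folds <- vapply(seq_len(n), function(i) {
    pts <- lapply(training[-i], point)
    x <- unlist(lapply(pts, `[[`, "x"))
    y <- unlist(lapply(pts, `[[`, "y"))
    sxx <- sum(x * x)
    if (sxx < 1e-14)
      stop("degenerate training design: all inverse-SUVR differences equal")
    sum(x * y) / sxx
  }, numeric(1))
  list(a = mean(folds), folds = folds)
}

#' Quantify one scan end to end
#'
#' Runs the full quantification of one [TacSet-class]: SRTM fits per region
#' for DVR, windowed SUVR for each requested window, clearance rates of the
#' reference and the composite region within the correction window,
#' regression estimates of each region's clearance, and the corrected SUVRc
#' for the correction window. The volume-weighted caudate + putamen
#' composite is also quantified as the `striatum` region.
#'
#' @param tacs a [TacSet-class] containing the reference region and all
#'   composite members.
#' @param config a [CorrectionConfig-class].
#' @param windows named list of [SuvrWindow-class]; names become measure
#'   suffixes (defaults `suvr_50_80`, `suvr_15_45`).
#' @param refRegion name of the reference region (default `"cerebellum"`).
#' @return list with `outcomes` (data.frame: region, dvr, one SUVR column
#'   per window, suvrc), `clearance` (a [ClearanceSet-class]) and `config`.
#' @export
quantifySubject <- function(tacs, config = CorrectionConfig(),
                            windows = list(suvr_50_80 = lateWindow(),
                                           suvr_15_45 = earlyWindow()),
                            refRegion = "cerebellum") {
  stopifnot(is(tacs, "TacSet"), is(config, "CorrectionConfig"))
  if (!refRegion %in% rownames(tacs))
    stop(sprintf("reference region '%s' missing", refRegion))
  members <- names(config@compositeVolumes)
  if (!all(members %in% rownames(tacs)))
    stop("composite member regions missing: ",
         paste(setdiff(members, rownames(tacs)), collapse = ", "))
  ref <- getTac(tacs, refRegion)
  targets <- setdiff(rownames(tacs), refRegion)
  tacList <- lapply(setNames(targets, targets), function(r) getTac(tacs, r))
  tacList$striatum <- compositeTac(tacList[members],
                                   config@compositeVolumes,
                                   region = "striatum")
  comp <- tacList$striatum
  win <- config@window
  betaRef <- fitClearanceRate(ref, win)
  betaComp <- fitClearanceRate(comp, win)
  suvrComp <- computeSuvr(comp, ref, win)
  # which requested window is the correction window
  corrName <- NULL
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (w@start == win@start && w@end == win@end) corrName <- nm
  }
  rows <- lapply(names(tacList), function(r) {
    tac <- tacList[[r]]
    fit <- tryCatch(srtmFit(tac, ref), error = function(e)
      stop(sprintf("region '%s', stage SRTM fit: %s", r, conditionMessage(e))))
    out <- list(region = r, dvr = dvr(fit), r1 = fit@R1)
    for (nm in names(windows))
      out[[nm]] <- computeSuvr(tac, ref, windows[[nm]])
    suvrWin <- computeSuvr(tac, ref, win)
    bt <- estimateBetaTar(suvrWin, suvrComp, betaComp, config@a)
    out$beta_tar <- bt
    out$suvrc <- tryCatch(
      correctSuvr(suvrWin, betaRef, bt, config),
      error = function(e)
        stop(sprintf("region '%s', stage SUVRc: %s", r, conditionMessage(e))))
    as.data.frame(out)
  })
  outcomes <- do.call(rbind, rows)
  betaTar <- setNames(outcomes$beta_tar, outcomes$region)
  list(outcomes = outcomes,
       clearance = ClearanceSet(betaRef, betaComp, betaTar, suvrComp),
       config = config,
       correctionWindow = if (is.null(corrName)) "suvr_50_80" else corrName)
}
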