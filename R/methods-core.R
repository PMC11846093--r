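#' Construct a frame schedule
#'
#' @param starts frame start times.
#' @param durations frame durations.
#' @param units `"min"` (default) or `"s"`; seconds are converted to minutes
#'   on construction, all internal times are minutes.
#' @return a [FrameSchedule-class] object.
#' @examples
#' FrameSchedule(c(0, 1, 2), c(1, 1, 1))
#' @export
FrameSchedule <- function(starts, durations, units = c("min", "s")) {
  units <- match.arg(units)
  starts <- as.numeric(starts); durations <- as.numeric(durations)
  if (units == "s") {
    starts <- starts / 60; durations <- durations / 60
  }
  new("FrameSchedule", starts = starts, durations = durations)
}

#' Default 37-frame dynamic acquisition schedule
#'
#' The 93-minute schedule used throughout: 8 x 10 s, 5 x 20 s, 4 x 30 s,
#' 4 x 60 s, 4 x 180 s, 12 x 360 s.
#'
#' @return a [FrameSchedule-class] with 37 frames totalling 93 minutes.
#' @export
fePe2iSchedule <- function() {
  dur_s <- c(rep(10, 8), rep(20, 5), rep(30, 4), rep(60, 4),
             rep(180, 4), rep(360, 12))
  FrameSchedule(cumsum(c(0, dur_s[-length(dur_s)])), dur_s, units = "s")
}

#' @rdname FrameSchedule-class
#' @export
setMethod("frameStarts", "FrameSchedule", function(x) x@starts)
#' @rdname FrameSchedule-class
#' @export
setMethod("frameDurations", "FrameSchedule", function(x) x@durations)
#' @rdname FrameSchedule-class
#' @export
setMethod("frameMidpoints", "FrameSchedule",
          function(x) x@starts + x@durations / 2)
#' @rdname FrameSchedule-class
#' @export
setMethod("frameEnds", "FrameSchedule", function(x) x@starts + x@durations)
#' @rdname FrameSchedule-class
#' @export
setMethod("length", "FrameSchedule", function(x) length(x@starts))

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.4g-%.4g min\n",
              length(object), object@starts[1L],
              max(frameEnds(object))))
})

#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param activity numeric vector, one decay-corrected activity value per
#'   frame.
#' @param region region name.
#' @return a [TimeActivityCurve-class].
#' @export
TimeActivityCurve <- function(schedule, activity, region = "region") {
  new("TimeActivityCurve", schedule = schedule,
      activity = as.numeric(activity), region = as.character(region))
}

#' @rdname TimeActivityCurve-class
#' @param ... unused.
#' @export
setMethod("activity", "TimeActivityCurve", function(x, ...) x@activity)
#' @rdname TimeActivityCurve-class
#' @export
setMethod("regionName", "TimeActivityCurve", function(x) x@region)
#' @rdname TimeActivityCurve-class
#' @export
setMethod("tacSchedule", "TimeActivityCurve", function(x) x@schedule)
#' @rdname TimeActivityCurve-class
#' @export
setMethod("length", "TimeActivityCurve", function(x) length(x@activity))

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s': %d frames, peak %.4g\n",
              object@region, length(object), max(object@activity)))
})

#' Construct a TacSet
#'
#' Bundle regional TACs of one scan into a [TacSet-class] (rows = regions,
#' columns = frames).
#'
#' @param tacs a named list of [TimeActivityCurve-class] objects sharing one
#'   schedule, or a regions x frames numeric matrix with rownames.
#' @param schedule the shared [FrameSchedule-class]; taken from the first
#'   TAC when `tacs` is a list.
#' @param volumes optional named numeric of region volumes (mL).
#' @param metadata optional list of scan-level annotation.
#' @return a [TacSet-class].
#' @export
TacSet <- function(tacs, schedule = NULL, volumes = NULL, metadata = list()) {
  if (is.list(tacs)) {
    stopifnot(length(tacs) > 0L)
    if (is.null(schedule)) schedule <- tacSchedule(tacs[[1L]])
    nms <- vapply(tacs, regionName, character(1))
    if (!is.null(names(tacs)) && all(nzchar(names(tacs)))) nms <- names(tacs)
    mat <- do.call(rbind, lapply(tacs, activity))
    rownames(mat) <- nms
  } else {
    mat <- as.matrix(tacs)
    if (is.null(rownames(mat))) stop("matrix input needs region rownames")
    if (is.null(schedule)) stop("matrix input needs an explicit schedule")
  }
  if (ncol(mat) != length(schedule))
    stop("activity columns must match the number of frames")
  cd <- S4Vectors::DataFrame(frame_start = frameStarts(schedule),
                             frame_duration = frameDurations(schedule))
  rd <- S4Vectors::DataFrame(row.names = rownames(mat))
  rd$volume_ml <- if (is.null(volumes)) NA_real_ else
    unname(volumes[rownames(mat)])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = mat), colData = cd, rowData = rd,
    metadata = metadata)
  new("TacSet", se)
}

#' @rdname TacSet-class
#' @export
setMethod("tacSchedule", "TacSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  FrameSchedule(cd$frame_start, cd$frame_duration)
})

#' @rdname TacSet-class
#' @export
setMethod("getTac", "TacSet", function(x, region) {
  if (!region %in% rownames(x))
    stop(sprintf("region '%s' not present in TacSet", region))
  TimeActivityCurve(tacSchedule(x),
                    SummarizedExperiment::assay(x, "activity")[region, ],
                    region = region)
})

#' @rdname TacSet-class
#' @export
setMethod("regionVolumes", "TacSet", function(x) {
  v <- SummarizedExperiment::rowData(x)$volume_ml
  setNames(as.numeric(v), rownames(x))
})

setMethod("show", "TacSet", function(object) {
  md <- S4Vectors::metadata(object)
  id <- if (!is.null(md$subject)) sprintf(" subject=%s", md$subject) else ""
  cat(sprintf("TacSet:%s %d regions x %d frames (%s)\n", id,
              nrow(object), ncol(object),
              paste(rownames(object), collapse = ", ")))
})

#' Construct SRTM parameters
#'
#' @param R1 delivery ratio (> 0).
#' @param k2 target efflux rate, min^-1 (> 0).
#' @param bp binding potential BPND.
#' @param atBoundary logical boundary flag (fit results only).
#' @return a [SrtmParams-class].
#' @export
SrtmParams <- function(R1, k2, bp, atBoundary = FALSE) {
  new("SrtmParams", R1 = as.numeric(R1), k2 = as.numeric(k2),
      bp = as.numeric(bp), atBoundary = isTRUE(atBoundary))
}

#' @rdname SrtmParams-class
#' @export
setMethod("dvr", "SrtmParams", function(x) x@bp + 1)
#' @rdname SrtmParams-class
#' @export
setMethod("bpnd", "SrtmParams", function(x) x@bp)

setMethod("show", "SrtmParams", function(object) {
  cat(sprintf("SrtmParams: R1=%.4g k2=%.4g min^-1 BPND=%.4g (DVR=%.4g)%s\n",
              object@R1, object@k2, object@bp, object@bp + 1,
              if (object@atBoundary) " [k2a at search boundary]" else ""))
})

#' Construct a SUVR window
#'
#' @param start,end window bounds in minutes, `0 <= start < end`.
#' @return a [SuvrWindow-class].
#' @export
SuvrWindow <- function(start, end) {
  new("SuvrWindow", start = as.numeric(start), end = as.numeric(end))
}

#' @rdname SuvrWindow-class
#' @export
lateWindow <- function() SuvrWindow(50, 80)

#' @rdname SuvrWindow-class
#' @export
earlyWindow <- function() SuvrWindow(15, 45)

setMethod("show", "SuvrWindow", function(object) {
  cat(sprintf("SuvrWindow: [%.4g, %.4g) min\n", object@start, object@end))
})

#' Construct a correction configuration
#'
#' Defaults are the a-priori constants of the clearance correction for a
#' fast dopamine-transporter tracer: `k2Ref = 0.10` min^-1 (median reference
#' efflux across regions), `r1Assumed = 1`, radiotracer constant
#' `a = 0.0024` min^-1, late window 50-80 min, and a caudate:putamen
#' composite with 4:6 mL volumes.
#'
#' @param k2Ref assumed reference efflux rate, min^-1.
#' @param r1Assumed assumed delivery ratio.
#' @param a radiotracer constant, min^-1.
#' @param window a [SuvrWindow-class] the correction applies to.
#' @param compositeVolumes named numeric, composite member volumes (mL).
#' @return a [CorrectionConfig-class].
#' @export
CorrectionConfig <- function(k2Ref = 0.10, r1Assumed = 1, a = 0.0024,
                             window = lateWindow(),
                             compositeVolumes = c(caudate = 4, putamen = 6)) {
  new("CorrectionConfig", k2Ref = k2Ref, r1Assumed = r1Assumed, a = a,
      window = window, compositeVolumes = compositeVolumes)
}

setMethod("show", "CorrectionConfig", function(object) {
  cat(sprintf(
    "CorrectionConfig: k2Ref=%.3g R1=%.3g a=%.4g min^-1, window [%g,%g) min\n",
    object@k2Ref, object@r1Assumed, object@a,
    object@window@start, object@window@end))
  cat("  composite:", paste(sprintf("%s=%g mL", names(object@compositeVolumes),
                                    object@compositeVolumes), collapse = " "),
      "\n")
})

#' Construct a clearance set
#'
#' @param betaRef,betaComposite scalar clearance rates (min^-1).
#' @param betaTar named numeric of per-region rates (min^-1).
#' @param suvrComposite composite-region SUVR.
#' @return a [ClearanceSet-class].
#' @export
ClearanceSet <- function(betaRef, betaComposite, betaTar, suvrComposite) {
  new("ClearanceSet", betaRef = betaRef, betaComposite = betaComposite,
      betaTar = betaTar, suvrComposite = suvrComposite)
}

setMethod("show", "ClearanceSet", function(object) {
  cat(sprintf("ClearanceSet: betaRef=%.4g betaComposite=%.4g min^-1 (SUVRcomp=%.3g)\n",
              object@betaRef, object@betaComposite, object@suvrComposite))
  print(round(object@betaTar, 5))
})
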