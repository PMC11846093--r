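#' @import methods
#' @importFrom stats approx optimize rnorm runif sd t.test var setNames
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment colData rowData
#'   assay assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Dynamic PET frame schedule
#'
#' Represents the time grid of a dynamic PET acquisition as frame start times
#' and frame durations, both in minutes. Frames must be non-overlapping and
#' ordered; gaps are permitted.
#'
#' @slot starts numeric vector of frame start times (minutes).
#' @slot durations numeric vector of frame durations (minutes).
#'
#' @seealso [FrameSchedule()], [fePe2iSchedule()]
#' @export
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@starts; d <- object@durations
  if (length(s) != length(d))
    return("'starts' and 'durations' must have equal length")
  if (length(s) == 0L)
    return("schedule must contain at least one frame")
  if (!all(is.finite(s)) || !all(is.finite(d)))
    return("frame times must be finite")
  if (any(d <= 0))
    return("all frame durations must be > 0")
  if (s[1L] < 0)
    return("first frame start must be >= 0")
  if (length(s) > 1L) {
    if (any(diff(s) <= 0))
      return("frame starts must be strictly increasing")
    if (any(s[-length(s)] + d[-length(d)] > s[-1L] + 1e-9))
      return("frames must not overlap")
  }
  TRUE
})

#' Regional time-activity curve
#'
#' Decay-corrected activity concentration of one region, one value per frame
#' of a [FrameSchedule]. Noiseless curves are non-negative; noisy curves may
#' dip slightly below zero and are carried through unclipped.
#'
#' @slot schedule a [FrameSchedule].
#' @slot region region name (length-1 character).
#' @slot activity numeric activity per frame (kBq/mL-equivalent units).
#'
#' @export
setClass("TimeActivityCurve",
  representation(schedule = "FrameSchedule", region = "character",
                 activity = "numeric"))

setValidity("TimeActivityCurve", function(object) {
  if (length(object@region) != 1L || is.na(object@region))
    return("'region' must be a single non-missing name")
  if (length(object@activity) != length(object@schedule@starts))
    return("'activity' length must equal the number of frames")
  if (!all(is.finite(object@activity)))
    return("'activity' must be finite")
  TRUE
})

#' Set of regional TACs for one scan
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding all
#' regional time-activity curves of one dynamic scan: rows are regions,
#' columns are frames. The single assay is named `"activity"`; `colData`
#' carries `frame_start` and `frame_duration` (minutes) and `rowData` may
#' carry `volume_ml`. Scan-level annotation (subject id, group, visit,
#' simulation truth) lives in `metadata()`.
#'
#' @seealso [TacSet()], [getTac()]
#' @export
setClass("TacSet", contains = "SummarizedExperiment")

setValidity("TacSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("frame_start", "frame_duration") %in% colnames(cd)))
    return("colData must contain 'frame_start' and 'frame_duration'")
  if (!"activity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'activity' is required")
  sched <- try(FrameSchedule(cd$frame_start, cd$frame_duration), silent = TRUE)
  if (inherits(sched, "try-error"))
    return("colData frame columns do not form a valid schedule")
  TRUE
})

#' SRTM kinetic parameters
#'
#' Parameters of the simplified reference tissue model for one region:
#' delivery ratio R1, target efflux rate k2 (min^-1) and binding potential
#' BPND. The distribution volume ratio is derived, `DVR = BPND + 1`, via
#' [dvr()]. Fit results additionally record whether the apparent efflux rate
#' `k2a` landed on the search boundary.
#'
#' @slot R1 numeric, target-to-reference delivery ratio (> 0).
#' @slot k2 numeric, target efflux rate, min^-1 (> 0).
#' @slot bp numeric, binding potential BPND.
#' @slot atBoundary logical, TRUE when a fit hit the k2a search boundary.
#'
#' @export
setClass("SrtmParams",
  representation(R1 = "numeric", k2 = "numeric", bp = "numeric",
                 atBoundary = "logical"),
  prototype(atBoundary = FALSE))

setValidity("SrtmParams", function(object) {
  for (nm in c("R1", "k2", "bp"))
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      return(sprintf("'%s' must be a finite scalar", nm))
  if (object@R1 <= 0) return("R1 must be > 0")
  if (object@k2 <= 0) return("k2 must be > 0")
  TRUE
})

#' SUVR integration window
#'
#' Half-open time window `[start, end)` in minutes; a frame belongs to the
#' window when its midpoint falls inside.
#'
#' @slot start window start (minutes, >= 0).
#' @slot end window end (minutes, > start).
#' @export
setClass("SuvrWindow", representation(start = "numeric", end = "numeric"))

setValidity("SuvrWindow", function(object) {
  if (length(object@start) != 1L || length(object@end) != 1L)
    return("start and end must be scalars")
  if (!is.finite(object@start) || !is.finite(object@end))
    return("window bounds must be finite")
  if (object@start < 0) return("window start must be >= 0")
  if (object@end <= object@start) return("window end must exceed start")
  TRUE
})

#' Configuration of the SUVRc correction
#'
#' Constants entering the clearance correction: the assumed reference efflux
#' rate `k2Ref` (min^-1), the assumed delivery ratio `r1Assumed`, the
#' radiotracer constant `a` (min^-1) of the clearance regression, the SUVR
#' window the correction applies to, and the volumes (mL) of the composite
#' region members.
#'
#' @slot k2Ref numeric, reference efflux rate assumed a priori (min^-1).
#' @slot r1Assumed numeric, assumed delivery ratio.
#' @slot a numeric, radiotracer constant (min^-1, >= 0).
#' @slot window a [SuvrWindow].
#' @slot compositeVolumes named numeric, member volumes in mL.
#' @export
setClass("CorrectionConfig",
  representation(k2Ref = "numeric", r1Assumed = "numeric", a = "numeric",
                 window = "SuvrWindow", compositeVolumes = "numeric"))

setValidity("CorrectionConfig", function(object) {
  if (object@k2Ref <= 0) return("k2Ref must be > 0")
  if (object@r1Assumed <= 0) return("r1Assumed must be > 0")
  if (object@a < 0) return("a must be >= 0")
  if (length(object@compositeVolumes) < 1L ||
      is.null(names(object@compositeVolumes)) ||
      any(!nzchar(names(object@compositeVolumes))))
    return("compositeVolumes must be a named numeric vector")
  if (any(object@compositeVolumes <= 0))
    return("composite volumes must be > 0")
  TRUE
})

#' Clearance rates of one scan
#'
#' Mono-exponential clearance rates estimated within the SUVR window:
#' reference tissue (`betaRef`), composite region (`betaComposite`) and one
#' rate per target region (`betaTar`), plus the composite-region SUVR used by
#' the regression estimator. Negative rates (still-rising curves) are legal
#' and preserved.
#'
#' @slot betaRef numeric scalar (min^-1).
#' @slot betaComposite numeric scalar (min^-1).
#' @slot betaTar named numeric, per-region rates (min^-1).
#' @slot suvrComposite numeric scalar.
#' @export
setClass("ClearanceSet",
  representation(betaRef = "numeric", betaComposite = "numeric",
                 betaTar = "numeric", suvrComposite = "numeric"))

setValidity("ClearanceSet", function(object) {
  if (!is.finite(object@betaRef) || !is.finite(object@betaComposite) ||
      !is.finite(object@suvrComposite) || !all(is.finite(object@betaTar)))
    return("all clearance values must be finite")
  TRUE
})

#' Specification of a synthetic PET cohort
#'
#' All knobs of the synthetic-data generator: group sizes, per-region DVR
#' distributions for healthy controls (HC) and Parkinson's disease (PD),
#' kinetic and plasma-input parameters, frame-noise scale, test-retest
#' perturbation, longitudinal decline, and the master seed. Defaults emulate
#' a dopamine-transporter tracer with fast kinetics; see the package vignette
#' for how they were calibrated.
#'
#' @slot nHc,nPd integer group sizes.
#' @slot regions data.frame with columns `region`, `hcMean`, `hcSd`,
#'   `pdMean`, `pdSd`, `declineMean`, `declineSd` (DVR distributions and
#'   true annual percent decline in PD).
#' @slot dvrFloor numeric, lower truncation bound for drawn DVR (>= 1).
#' @slot r1Mean,r1Sd numeric, distribution of the true delivery ratio.
#' @slot k2RefMean,k2RefSd numeric, distribution of the reference efflux
#'   rate k2' (min^-1).
#' @slot k1RefMean,k1RefSd numeric, distribution of reference K1 (min^-1).
#' @slot plasma named numeric, tri-exponential plasma input parameters
#'   (`A1`,`A2`,`A3`,`l1`,`l2`,`l3`).
#' @slot noiseScale numeric, frame-noise scale (see [addFrameNoise()]).
#' @slot nTestRetest integer, number of test-retest pairs.
#' @slot testRetestJitter numeric, SD of the multiplicative between-scan
#'   jitter applied to reference K1 and to the plasma terminal clearance.
#' @slot nLongitudinal integer, number of longitudinal pairs.
#' @slot intervalMeanYears,intervalSdYears numeric, scan-interval
#'   distribution of the longitudinal arm.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
  representation(nHc = "integer", nPd = "integer", regions = "data.frame",
                 dvrFloor = "numeric",
                 r1Mean = "numeric", r1Sd = "numeric",
                 k2RefMean = "numeric", k2RefSd = "numeric",
                 k1RefMean = "numeric", k1RefSd = "numeric",
                 plasma = "numeric", noiseScale = "numeric",
                 nTestRetest = "integer", testRetestJitter = "numeric",
                 nLongitudinal = "integer",
                 intervalMeanYears = "numeric", intervalSdYears = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  need <- c("region", "hcMean", "hcSd", "pdMean", "pdSd",
            "declineMean", "declineSd")
  if (!all(need %in% colnames(object@regions)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  if (object@nHc < 1L || object@nPd < 1L)
    return("group sizes must be >= 1")
  if (any(object@regions$hcMean < 1) || any(object@regions$pdMean < 1))
    return("DVR means must be >= 1")
  striatal <- object@regions$region %in% c("caudate", "putamen")
  if (any(object@regions$pdMean[striatal] >
          object@regions$hcMean[striatal]))
    return("PD striatal DVR means must not exceed HC means")
  if (object@dvrFloor < 1) return("dvrFloor must be >= 1")
  if (object@noiseScale < 0) return("noiseScale must be >= 0")
  if (object@intervalMeanYears <= 0)
    return("longitudinal interval must be > 0")
  if (!all(c("A1", "A2", "A3", "l1", "l2", "l3") %in% names(object@plasma)))
    return("plasma must name A1,A2,A3,l1,l2,l3")
  TRUE
})
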