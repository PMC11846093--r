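#' @rdname FrameSchedule-class
#' @param x a `FrameSchedule` (or object carrying one).
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameMidpoints", function(x) standardGeneric("frameMidpoints"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameEnds", function(x) standardGeneric("frameEnds"))

#' @rdname TimeActivityCurve-class
#' @param x a `TimeActivityCurve` or `TacSet`.
#' @export
setGeneric("activity", function(x, ...) standardGeneric("activity"))

#' @rdname TimeActivityCurve-class
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))

#' @rdname TimeActivityCurve-class
#' @export
setGeneric("tacSchedule", function(x) standardGeneric("tacSchedule"))

#' @rdname SrtmParams-class
#' @param x a `SrtmParams`.
#' @export
setGeneric("dvr", function(x) standardGeneric("dvr"))

#' @rdname SrtmParams-class
#' @export
setGeneric("bpnd", function(x) standardGeneric("bpnd"))

#' @rdname TacSet-class
#' @param x a `TacSet`.
#' @param region region name.
#' @export
setGeneric("getTac", function(x, region) standardGeneric("getTac"))

#' @rdname TacSet-class
#' @export
setGeneric("regionVolumes", function(x) standardGeneric("regionVolumes"))
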