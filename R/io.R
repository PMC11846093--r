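# File formats: TAC CSV dialect, long-format outcome tables, cohort
# manifests and run configurations. All numeric serialization is
# full-precision (%.17g) so write -> read round trips are bit exact.

.SCHEMA_VERSION <- "1.0"

.fmt <- function(x) sprintf("%.17g", x)

#' Write a TacSet to the TAC CSV dialect
#'
#' Columns: `frame_start`, `frame_duration`, `units` (`"min"` or `"s"`,
#' constant per file), then one column per region. UTF-8, `.` decimal,
#' full-precision decimals so a write/read round trip is exact.
#'
#' @param tacs a [TacSet-class].
#' @param path output file.
#' @param units time units to write the schedule in.
#' @return `path`, invisibly.
#' @export
writeTacTable <- function(tacs, path, units = c("min", "s")) {
  units <- match.arg(units)
  sched <- tacSchedule(tacs)
  fac <- if (units == "s") 60 else 1
  mat <- SummarizedExperiment::assay(tacs, "activity")
  df <- data.frame(frame_start = .fmt(frameStarts(sched) * fac),
                   frame_duration = .fmt(frameDurations(sched) * fac),
                   units = units, check.names = FALSE)
  for (r in rownames(mat)) df[[r]] <- .fmt(mat[r, ])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TAC CSV file
#'
#' Parses the TAC CSV dialect written by [writeTacTable()], validating the
#' schedule (positive durations, strictly increasing non-overlapping
#' frames) and converting seconds to minutes when the units column says
#' `"s"`.
#'
#' @param path input file.
#' @param volumes optional named numeric of region volumes (mL).
#' @param metadata optional scan-level metadata list.
#' @return a [TacSet-class].
#' @export
readTacTable <- function(path, volumes = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("frame_start", "frame_duration", "units")
  if (!all(need %in% colnames(df)))
    stop("malformed TAC header: expected columns ",
         paste(need, collapse = ", "))
  regions <- setdiff(colnames(df), need)
  if (length(regions) == 0L) stop("no region columns in ", path)
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(x))
      stop(sprintf("non-numeric cell in column '%s', row %d",
                   col, which(is.na(x))[1L]))
    x
  }
  units <- unique(df$units)
  if (length(units) != 1L || !units %in% c("s", "min"))
    stop("units column must be constant 's' or 'min'")
  sched <- FrameSchedule(num("frame_start"), num("frame_duration"),
                         units = units)
  mat <- t(vapply(regions, num, numeric(nrow(df))))
  rownames(mat) <- regions
  TacSet(mat, sched, volumes = volumes, metadata = metadata)
}

#' Write a long-format outcome table
#'
#' One row per (subject, visit, region, measure); the measure set is
#' `DVR`, `SUVR_50_80`, `SUVRc_50_80`, `SUVR_15_45`. A `schema_version`
#' column stamps the file format.
#'
#' @param outcomes outcome data.frame (see [quantifyCohort()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeOutcomeTable <- function(outcomes, path) {
  df <- outcomes
  df$schema_version <- .SCHEMA_VERSION
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- .fmt(df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format outcome table
#'
#' @param path CSV written by [writeOutcomeTable()].
#' @return outcome data.frame.
#' @export
readOutcomeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("subject", "group", "visit", "region", "measure", "value")
  if (!all(need %in% colnames(df)))
    stop("malformed outcome table: expected columns ",
         paste(need, collapse = ", "))
  df$schema_version <- NULL
  df
}

# serialize a CohortSpec to plain lists (JSON/YAML friendly)
.specToList <- function(spec) {
  list(nHc = spec@nHc, nPd = spec@nPd,
       regions = as.list(spec@regions),
       dvrFloor = spec@dvrFloor,
       r1Mean = spec@r1Mean, r1Sd = spec@r1Sd,
       k2RefMean = spec@k2RefMean, k2RefSd = spec@k2RefSd,
       k1RefMean = spec@k1RefMean, k1RefSd = spec@k1RefSd,
       plasma = as.list(spec@plasma),
       noiseScale = spec@noiseScale,
       nTestRetest = spec@nTestRetest,
       testRetestJitter = spec@testRetestJitter,
       nLongitudinal = spec@nLongitudinal,
       intervalMeanYears = spec@intervalMeanYears,
       intervalSdYears = spec@intervalSdYears,
       seed = spec@seed)
}

.specFromList <- function(lst) {
  cohortSpec(nHc = lst$nHc, nPd = lst$nPd,
             regions = as.data.frame(lst$regions),
             dvrFloor = lst$dvrFloor,
             r1Mean = lst$r1Mean, r1Sd = lst$r1Sd,
             k2RefMean = lst$k2RefMean, k2RefSd = lst$k2RefSd,
             k1RefMean = lst$k1RefMean, k1RefSd = lst$k1RefSd,
             plasma = unlist(lst$plasma),
             noiseScale = lst$noiseScale,
             nTestRetest = lst$nTestRetest,
             testRetestJitter = lst$testRetestJitter,
             nLongitudinal = lst$nLongitudinal,
             intervalMeanYears = lst$intervalMeanYears,
             intervalSdYears = lst$intervalSdYears,
             seed = lst$seed)
}

#' Write a simulated cohort to a directory
#'
#' One TAC CSV per scan plus a `manifest.json` holding the cohort spec,
#' the schema version, and the per-scan simulation truth, so any cohort
#' is exactly regenerable and fully documented on disk.
#'
#' @param records list of [TacSet-class] scans (flattened pairs are fine).
#' @param dir output directory (created if needed).
#' @param spec the generating [CohortSpec-class] (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
writeCohortDir <- function(records, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(records, function(ts) {
    md <- S4Vectors::metadata(ts)
    fname <- sprintf("%s_%s.csv", md$subject, md$visit)
    writeTacTable(ts, file.path(dir, fname))
    truth <- md$truth
    if (!is.null(truth$regions)) truth$regions <- as.list(truth$regions)
    entry <- list(file = fname, subject = md$subject, group = md$group,
                  visit = md$visit, truth = truth)
    if (length(md$intervalYears) == 1L)
      entry$intervalYears <- md$intervalYears
    entry
  })
  manifest <- list(schema_version = .SCHEMA_VERSION,
                   spec = if (is.null(spec)) NULL else .specToList(spec),
                   scans = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory written by [writeCohortDir()].
#' @return list with `records` (list of [TacSet-class]) and `spec` (a
#'   [CohortSpec-class] or NULL).
#' @export
readCohortDir <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  scans <- manifest$scans
  records <- lapply(scans, function(e) {
    truth <- e$truth
    if (!is.null(truth$regions)) truth$regions <- as.data.frame(truth$regions)
    md <- list(subject = e$subject, group = e$group, visit = e$visit,
               truth = truth)
    if (length(e$intervalYears) == 1L)
      md$intervalYears <- as.numeric(e$intervalYears)
    readTacTable(file.path(dir, e$file),
                 volumes = c(caudate = 4, putamen = 6), metadata = md)
  })
  spec <- if (!is.null(manifest$spec)) .specFromList(manifest$spec) else NULL
  list(records = records, spec = spec)
}

#' Default run configuration
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @return a list with `windows`, `correction`, `cohort`, `stats`,
#'   `outdir` and `seed` fields; serializable to YAML via
#'   [writeRunConfig()].
#' @export
defaultRunConfig <- function(seed = 20260921L, outdir = "suvrclear-run") {
  list(schema_version = .SCHEMA_VERSION,
       windows = list(suvr_50_80 = c(50, 80), suvr_15_45 = c(15, 45)),
       correction = list(k2Ref = 0.10, r1Assumed = 1, a = 0.0024,
                         window = c(50, 80),
                         compositeVolumes = list(caudate = 4, putamen = 6)),
       cohort = .specToList(cohortSpec(seed = seed)),
       stats = list(bonferroniFamily = 3L, positiveIsLower = TRUE,
                    ciLevel = 0.95),
       outdir = outdir,
       seed = as.integer(seed))
}

#' @rdname defaultRunConfig
#' @param config a run-config list.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  for (nm in names(base)) if (is.null(cfg[[nm]])) cfg[[nm]] <- base[[nm]]
  cfg
}

# materialize S4 config objects from a run-config list
.correctionFromConfig <- function(config) {
  cc <- config$correction
  CorrectionConfig(k2Ref = cc$k2Ref, r1Assumed = cc$r1Assumed, a = cc$a,
                   window = SuvrWindow(cc$window[[1]], cc$window[[2]]),
                   compositeVolumes = unlist(cc$compositeVolumes))
}

.windowsFromConfig <- function(config) {
  lapply(config$windows, function(w) SuvrWindow(w[[1]], w[[2]]))
}
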