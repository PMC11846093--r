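# Validation-arm drivers: turn cohorts of TacSets into long-format outcome
# tables and the cross-sectional / test-retest / longitudinal reports.

.MEASURES <- c("DVR", "SUVR_50_80", "SUVRc_50_80", "SUVR_15_45")

#' Flatten cohort pairs into a list of scans
#'
#' @param pairs list of pairs from [generateTestRetest()] or
#'   [generateLongitudinal()].
#' @return flat list of [TacSet-class] scans; longitudinal scans carry
#'   `intervalYears` in their metadata.
#' @export
flattenPairs <- function(pairs) {
  out <- list()
  for (p in pairs) {
    for (nm in intersect(names(p), c("test", "retest", "baseline",
                                     "followup"))) {
      ts <- p[[nm]]
      if (!is.null(p$intervalYears))
        S4Vectors::metadata(ts)$intervalYears <- p$intervalYears
      out[[length(out) + 1L]] <- ts
    }
  }
  out
}

#' Quantify a cohort into a long-format outcome table
#'
#' Runs [quantifySubject()] on every scan and collects one row per
#' (subject, visit, region, measure), with the clearance rates used for
#' the correction attached to every row of the scan.
#'
#' @param records list of [TacSet-class] scans (see [flattenPairs()] for
#'   paired designs).
#' @param config a [CorrectionConfig-class].
#' @param windows named list of [SuvrWindow-class] objects; the names map
#'   to measures (`suvr_50_80` -> `SUVR_50_80` and `SUVRc_50_80`,
#'   `suvr_15_45` -> `SUVR_15_45`).
#' @return data.frame with columns `subject`, `group`, `visit`, `region`,
#'   `measure`, `value`, `beta_tar`, `beta_ref`, `beta_composite`, and
#'   `interval_years` where available.
#' @export
quantifyCohort <- function(records, config = CorrectionConfig(),
                           windows = list(suvr_50_80 = lateWindow(),
                                          suvr_15_45 = earlyWindow())) {
  rows <- lapply(records, function(ts) {
    md <- S4Vectors::metadata(ts)
    q <- quantifySubject(ts, config, windows)
    oc <- q$outcomes
    long <- do.call(rbind, lapply(seq_len(nrow(oc)), function(i) {
      r <- oc[i, ]
      meas <- c(DVR = r$dvr,
                SUVR_50_80 = r$suvr_50_80,
                SUVRc_50_80 = r$suvrc,
                SUVR_15_45 = r$suvr_15_45)
      data.frame(subject = md$subject, group = md$group, visit = md$visit,
                 region = r$region, measure = names(meas),
                 value = unname(meas),
                 beta_tar = r$beta_tar,
                 beta_ref = q$clearance@betaRef,
                 beta_composite = q$clearance@betaComposite,
                 interval_years = if (is.null(md$intervalYears)) NA_real_
                                  else md$intervalYears)
    }))
    long
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.checkMeasures <- function(outcomes) {
  missing <- setdiff(.MEASURES, unique(outcomes$measure))
  if (length(missing) > 0L)
    stop("outcome table lacks measures: ", paste(missing, collapse = ", "))
}

# wide per-subject table of one measure within one region
.measureWide <- function(outcomes, region, visit = NULL) {
  df <- outcomes[outcomes$region == region, ]
  if (!is.null(visit)) df <- df[df$visit == visit, ]
  out <- NULL
  for (m in unique(df$measure)) {
    sub <- df[df$measure == m, c("subject", "group", "value")]
    names(sub)[3L] <- m
    out <- if (is.null(out)) sub else merge(out, sub, by = c("subject",
                                                             "group"))
  }
  out[order(out$subject), ]
}

#' Cross-sectional validation report
#'
#' Computes, per region: mean +- SD percent bias of each SUVR measure
#' against DVR (with paired Bonferroni-corrected t-tests between the
#' measures' biases), per-group coefficients of variation, Cohen's d,
#' ROC AUC with DeLong CI, Lin's concordance, and least-squares
#' slope / r-squared of each measure against DVR.
#'
#' @param outcomes long outcome table from [quantifyCohort()].
#' @param bonferroniFamily Bonferroni family size for the bias contrasts.
#' @param positiveIsLower ROC orientation (cases have lower uptake).
#' @param ciLevel confidence level for the AUC interval.
#' @return list of data.frames: `bias`, `biasTests`, `cv`, `effectSize`,
#'   `auc`, `agreement` (LCC, slope, r2), `blandAltman`.
#' @export
runCrossSectionalArm <- function(outcomes, bonferroniFamily = 3L,
                                 positiveIsLower = TRUE, ciLevel = 0.95) {
  .checkMeasures(outcomes)
  if (length(unique(outcomes$group)) < 2L)
    stop("cross-sectional arm needs both groups")
  regions <- unique(outcomes$region)
  suvrMeasures <- setdiff(.MEASURES, "DVR")
  bias <- list(); biasTests <- list(); cv <- list(); es <- list()
  aucTab <- list(); agree <- list(); ba <- list()
  for (rg in regions) {
    wide <- .measureWide(outcomes, rg)
    for (g in unique(wide$group)) {
      sub <- wide[wide$group == g, ]
      b <- lapply(suvrMeasures, function(m) percentBias(sub[[m]], sub$DVR))
      names(b) <- suvrMeasures
      for (m in suvrMeasures)
        bias[[length(bias) + 1L]] <- data.frame(
          region = rg, group = g, measure = m,
          meanBias = mean(b[[m]]), sdBias = sd(b[[m]]))
      contrasts <- list(
        SUVR_vs_SUVRc = b$SUVR_50_80 - b$SUVRc_50_80,
        SUVR_vs_early = b$SUVR_50_80 - b$SUVR_15_45,
        SUVRc_vs_early = b$SUVRc_50_80 - b$SUVR_15_45)
      # degenerate contrasts (identical biases) are reported as NA rather
      # than aborting the whole report
      tt <- do.call(rbind, lapply(names(contrasts), function(nm) {
        tryCatch(pairedTBonferroni(contrasts[nm], bonferroniFamily),
                 error = function(e) data.frame(
                   comparison = nm, t = NA_real_, p = NA_real_,
                   significant = NA))
      }))
      tt$region <- rg; tt$group <- g
      biasTests[[length(biasTests) + 1L]] <- tt
      for (m in .MEASURES)
        cv[[length(cv) + 1L]] <- data.frame(
          region = rg, group = g, measure = m,
          cvPct = coefficientOfVariation(sub[[m]]))
    }
    hc <- wide[wide$group == "HC", ]; pd <- wide[wide$group == "PD", ]
    for (m in .MEASURES) {
      es[[length(es) + 1L]] <- data.frame(
        region = rg, measure = m, d = cohensD(hc[[m]], pd[[m]]))
      a <- rocAuc(hc[[m]], pd[[m]], positiveIsLower = positiveIsLower,
                  ciLevel = ciLevel)
      aucTab[[length(aucTab) + 1L]] <- data.frame(
        region = rg, measure = m, auc = a$auc,
        ciLow = a$ciLow, ciHigh = a$ciHigh)
    }
    for (m in suvrMeasures) {
      fitlm <- stats::lm(wide[[m]] ~ wide$DVR)
      bam <- blandAltman(wide$DVR, wide[[m]])
      agree[[length(agree) + 1L]] <- data.frame(
        region = rg, measure = m,
        lcc = linCcc(wide$DVR, wide[[m]]),
        slope = unname(stats::coef(fitlm)[2L]),
        r2 = suppressWarnings(summary(fitlm)$r.squared))
      ba[[length(ba) + 1L]] <- data.frame(
        region = rg, measure = m, meanDiff = bam$meanDiff,
        sdDiff = bam$sdDiff, loaLow = bam$loaLow, loaHigh = bam$loaHigh)
    }
  }
  list(bias = do.call(rbind, bias),
       biasTests = do.call(rbind, biasTests),
       cv = do.call(rbind, cv),
       effectSize = do.call(rbind, es),
       auc = do.call(rbind, aucTab),
       agreement = do.call(rbind, agree),
       blandAltman = do.call(rbind, ba))
}

#' Test-retest validation report
#'
#' Per-subject test-retest variability of every measure and region,
#' summarized as cohort mean +- SD, plus the per-subject composite
#' clearance-rate table (test, retest, absolute difference, TRV).
#'
#' @param outcomes long outcome table with visits `test` and `retest`.
#' @return list with `trv` (per subject), `trvSummary` (per region and
#'   measure) and `betaComposite` (per subject).
#' @export
runTestRetestArm <- function(outcomes) {
  .checkMeasures(outcomes)
  vis <- unique(outcomes$visit)
  if (!all(c("test", "retest") %in% vis))
    stop("test-retest arm needs visits 'test' and 'retest'")
  subjects <- unique(outcomes$subject)
  unpaired <- subjects[vapply(subjects, function(s) {
    v <- unique(outcomes$visit[outcomes$subject == s])
    !all(c("test", "retest") %in% v)
  }, logical(1))]
  if (length(unpaired) > 0L)
    stop("unpaired subjects: ", paste(unpaired, collapse = ", "))
  rows <- list(); brow <- list()
  for (s in subjects) {
    sub <- outcomes[outcomes$subject == s, ]
    for (rg in unique(sub$region)) {
      for (m in unique(sub$measure)) {
        v1 <- sub$value[sub$region == rg & sub$measure == m &
                        sub$visit == "test"]
        v2 <- sub$value[sub$region == rg & sub$measure == m &
                        sub$visit == "retest"]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, region = rg, measure = m, trvPct = trv(v1, v2))
      }
    }
    b1 <- unique(sub$beta_composite[sub$visit == "test"])
    b2 <- unique(sub$beta_composite[sub$visit == "retest"])
    brow[[length(brow) + 1L]] <- data.frame(
      subject = s, test = b1, retest = b2,
      difference = abs(b1 - b2), trvPct = trv(b1, b2))
  }
  trvDf <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(trvDf, trvDf[c("region", "measure")]),
    function(d) data.frame(region = d$region[1L], measure = d$measure[1L],
                           meanTrv = mean(d$trvPct), sdTrv = sd(d$trvPct))))
  rownames(summ) <- NULL
  list(trv = trvDf, trvSummary = summ,
       betaComposite = do.call(rbind, brow))
}

#' Longitudinal validation report
#'
#' Annualized percent change of every measure per subject and region
#' (cohort mean +- SD), the baseline/follow-up composite clearance
#' summary, and the fraction of subjects whose target clearance rate
#' increased at follow-up.
#'
#' @param outcomes long outcome table with visits `baseline` and
#'   `followup` and per-subject `interval_years`.
#' @return list with `alc`, `alcSummary`, `betaComposite` and
#'   `betaIncrease` data.frames.
#' @export
runLongitudinalArm <- function(outcomes) {
  .checkMeasures(outcomes)
  if (!all(c("baseline", "followup") %in% unique(outcomes$visit)))
    stop("longitudinal arm needs visits 'baseline' and 'followup'")
  subjects <- unique(outcomes$subject)
  rows <- list(); brow <- list(); binc <- list()
  for (s in subjects) {
    sub <- outcomes[outcomes$subject == s, ]
    iv <- unique(sub$interval_years[sub$visit == "followup"])
    iv <- iv[is.finite(iv)]
    if (length(iv) != 1L)
      stop("missing or ambiguous scan interval for subject ", s)
    for (rg in unique(sub$region)) {
      for (m in unique(sub$measure)) {
        v1 <- sub$value[sub$region == rg & sub$measure == m &
                        sub$visit == "baseline"]
        v2 <- sub$value[sub$region == rg & sub$measure == m &
                        sub$visit == "followup"]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, region = rg, measure = m,
          alcPct = alc(v1, v2, iv))
      }
      bt1 <- unique(sub$beta_tar[sub$region == rg & sub$visit == "baseline"])
      bt2 <- unique(sub$beta_tar[sub$region == rg & sub$visit == "followup"])
      binc[[length(binc) + 1L]] <- data.frame(
        subject = s, region = rg, increased = bt2 > bt1)
    }
    b1 <- unique(sub$beta_composite[sub$visit == "baseline"])
    b2 <- unique(sub$beta_composite[sub$visit == "followup"])
    brow[[length(brow) + 1L]] <- data.frame(
      subject = s, baseline = b1, followup = b2,
      difference = b2 - b1, alcPct = alc(b1, b2, iv))
  }
  alcDf <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(alcDf, alcDf[c("region", "measure")]),
    function(d) data.frame(region = d$region[1L], measure = d$measure[1L],
                           meanAlc = mean(d$alcPct), sdAlc = sd(d$alcPct))))
  rownames(summ) <- NULL
  bincDf <- do.call(rbind, binc)
  fracInc <- do.call(rbind, lapply(split(bincDf, bincDf$region),
    function(d) data.frame(region = d$region[1L],
                           fractionIncreased = mean(d$increased),
                           n = nrow(d))))
  rownames(fracInc) <- NULL
  list(alc = alcDf, alcSummary = summ,
       betaComposite = do.call(rbind, brow),
       betaIncrease = fracInc)
}
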