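# Validation statistics: pure functions over paired or grouped outcome
# values. Sample (n-1) standard deviations are used for CV, Cohen's d
# pooling and Bland-Altman; Lin's concordance uses population (n) moments
# consistently in numerator and denominator so identity input scores
# exactly 1.

#' Percent bias of a parameter against DVR
#'
#' `100 * (parameter - dvr) / dvr`. Vectorised.
#'
#' @param parameter measured value(s).
#' @param dvr gold-standard value(s), > 0.
#' @return percent bias.
#' @export
percentBias <- function(parameter, dvr) {
  if (any(dvr <= 0)) stop("dvr must be > 0")
  100 * (parameter - dvr) / dvr
}

#' Coefficient of variation (percent)
#'
#' `100 * SD / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric, n >= 2, positive mean.
#' @return CV in percent.
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be > 0")
  100 * sd(values) / m
}

#' Lin's concordance correlation coefficient
#'
#' `LCC = 2*rho*sx*sy / (sx^2 + sy^2 + (mx - my)^2)` with population (n
#' denominator) moments used consistently, so `x == y` gives exactly 1 and
#' `|LCC| <= |rho|` always.
#'
#' @param x,y paired numeric vectors, equal length >= 2.
#' @return concordance coefficient in `[-1, 1]`.
#' @export
linCcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired with length >= 2")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) stop("LCC undefined: both variances and mean shift are zero")
  2 * sxy / den
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / sqrt(((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2))`.
#' Convention here: `x` = healthy controls, `y` = patients, so reduced
#' uptake in patients yields positive d.
#'
#' @param x,y numeric group values, each n >= 2.
#' @return effect size d.
#' @export
cohensD <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group")
  pooled <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled standard deviation is zero")
  (mean(x) - mean(y)) / pooled
}

#' ROC area under the curve with DeLong confidence interval
#'
#' Mann-Whitney AUC (midrank tie handling) for discriminating two groups,
#' with a DeLong confidence interval. With `positiveIsLower = TRUE` the
#' orientation assumes cases (e.g. patients) have *lower* values than
#' controls, matching reduced tracer uptake in disease.
#'
#' @param control,case numeric values of the two groups (both non-empty).
#' @param positiveIsLower logical orientation flag.
#' @param ciLevel confidence level (default 0.95).
#' @return list with `auc`, `ciLow`, `ciHigh`.
#' @export
rocAuc <- function(control, case, positiveIsLower = TRUE, ciLevel = 0.95) {
  if (length(control) == 0L || length(case) == 0L)
    stop("both groups must be non-empty")
  resp <- factor(c(rep("control", length(control)),
                   rep("case", length(case))),
                 levels = c("control", "case"))
  direction <- if (positiveIsLower) ">" else "<"
  r <- pROC::roc(response = resp, predictor = c(control, case),
                 levels = c("control", "case"), direction = direction,
                 quiet = TRUE)
  ci <- tryCatch(
    suppressWarnings(
      as.numeric(pROC::ci.auc(r, conf.level = ciLevel, method = "delong"))),
    error = function(e) rep(as.numeric(pROC::auc(r)), 3))
  list(auc = as.numeric(pROC::auc(r)), ciLow = ci[1L], ciHigh = ci[3L])
}

#' Bland-Altman agreement summary
#'
#' Mean difference `x - y`, its sample SD, and 95% limits of agreement
#' `mean +- 1.96 SD`, plus the per-pair means and differences for plotting.
#'
#' @param x,y paired numeric vectors, length >= 2.
#' @return list with `meanDiff`, `sdDiff`, `loaLow`, `loaHigh`, `means`,
#'   `diffs`.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired with length >= 2")
  d <- x - y
  md <- mean(d); sdd <- sd(d)
  list(meanDiff = md, sdDiff = sdd,
       loaLow = md - 1.96 * sdd, loaHigh = md + 1.96 * sdd,
       means = (x + y) / 2, diffs = d)
}

#' Test-retest variability (percent)
#'
#' `100 * |test - retest| / ((test + retest)/2)`; absolute, symmetric, and
#' invariant to common rescaling. Vectorised.
#'
#' @param test,retest paired measurements with positive pair means.
#' @return TRV in percent.
#' @export
trv <- function(test, retest) {
  m <- (test + retest) / 2
  if (any(m <= 0)) stop("pair mean must be > 0")
  100 * abs(test - retest) / m
}

#' Annual longitudinal percent change
#'
#' `100 * (baseline - followup) / baseline / intervalYears`; positive values
#' indicate decline. Vectorised.
#'
#' @param baseline,followup paired measurements; baseline > 0.
#' @param intervalYears scan interval in years, > 0.
#' @return signed annualized percent change.
#' @export
alc <- function(baseline, followup, intervalYears) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  if (any(intervalYears <= 0)) stop("interval must be > 0")
  100 * (baseline - followup) / baseline / intervalYears
}

#' Paired t-tests with Bonferroni-corrected significance
#'
#' Two-sided paired t-test on each difference sequence; a comparison is
#' flagged significant when `p < 0.05 / nComparisons` (with 3 comparisons
#' the threshold is 0.0167).
#'
#' @param differences list of numeric difference vectors (each n >= 2).
#' @param nComparisons size of the Bonferroni family (>= 1).
#' @return data.frame with columns `comparison`, `t`, `p`, `significant`.
#' @export
pairedTBonferroni <- function(differences, nComparisons = length(differences)) {
  if (!is.list(differences) || length(differences) < 1L)
    stop("differences must be a non-empty list")
  if (nComparisons < 1L) stop("nComparisons must be >= 1")
  thr <- 0.05 / nComparisons
  nms <- names(differences)
  if (is.null(nms)) nms <- paste0("comparison", seq_along(differences))
  rows <- lapply(seq_along(differences), function(i) {
    d <- differences[[i]]
    if (length(d) < 2L) stop("each difference sequence needs n >= 2")
    if (var(d) == 0)
      stop(sprintf("degenerate test for '%s': zero variance of differences",
                   nms[i]))
    tt <- t.test(d)
    data.frame(comparison = nms[i], t = unname(tt$statistic),
               p = tt$p.value, significant = tt$p.value < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
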