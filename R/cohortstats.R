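## Cohort-level statistics for paired-eye designs: burnout classification,
## treated-vs-fellow comparisons by patient-clustered bootstrap (eyes of one
## patient are correlated, so patients — not eyes — are resampled), Spearman
## rank correlation, and ROC analysis for burnout prediction.

#' Classify an eye as burnout from its vessel map
#'
#' Computes the nonperfused area inside the 3-mm disc after a morphological
#' closing of the vessel map (so normal inter-capillary spacing does not
#' count as nonperfusion) and flags the eye when it exceeds
#' \code{thresholdMm2}. Burnout eyes show vasculature so attenuated that
#' capillary detail is undetectable.
#'
#' @param vesselMap a [VesselMap-class] or binary matrix.
#' @param scanWidthMm scan width (taken from the map when available).
#' @param thresholdMm2 nonperfused-area threshold in mm^2 (default 6.0
#'   within the ~7.07 mm^2 3-mm disc).
#' @param closingPx side of the square closing element.
#' @return logical; attribute \code{"nonperfusedMm2"} carries the area.
#' @export
classifyBurnout <- function(vesselMap, scanWidthMm = NULL, thresholdMm2 = 6.0,
                            closingPx = 5L) {
  if (is(vesselMap, "BinaryMap")) {
    if (is.null(scanWidthMm)) scanWidthMm <- vesselMap@scanWidthMm
    vm <- vesselMap@pixels
  } else vm <- (asMatrix(vesselMap) > 0) + 0
  if (is.null(scanWidthMm)) scanWidthMm <- 3
  n <- nrow(vm)
  mmPerPx <- scanWidthMm / n
  closed <- if (any(vm > 0))
    (asMatrix(EBImage::closing(asImage(vm), matrix(1, closingPx, closingPx))) > 0) + 0
  else vm
  disc3 <- centralDiscMask(n, (1.5 / mmPerPx))
  nonperf <- sum(disc3 & closed == 0) * mmPerPx^2
  out <- nonperf > thresholdMm2
  attr(out, "nonperfusedMm2") <- nonperf
  out
}

#' Compare a metric between two groups with a patient-clustered bootstrap
#'
#' Difference of group means with a 95% percentile confidence interval and a
#' two-sided p-value obtained by resampling patients (clusters) with
#' replacement, preserving the inter-eye correlation of the paired design.
#'
#' @param table cohort data.frame with columns \code{patientId},
#'   \code{group} and the metric.
#' @param metric column name to compare.
#' @param groupA,groupB character vectors of \code{group} values defining
#'   the two arms.
#' @param nBoot number of bootstrap replicates (>= 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return list of class \code{GroupComparison}: metric, group means and
#'   sds, \code{difference} (A - B), \code{ci95}, \code{pValue},
#'   \code{nBoot}.
#' @export
compareGroups <- function(table, metric, groupA, groupB, nBoot = 2000L,
                          seed = 1L) {
  stopifnot(metric %in% names(table), nBoot >= 1000L)
  table <- table[!is.na(table[[metric]]), , drop = FALSE]
  inA <- table$group %in% groupA
  inB <- table$group %in% groupB
  if (length(unique(table$patientId[inA])) < 2 ||
      length(unique(table$patientId[inB])) < 2)
    stop("compareGroups: each group needs at least 2 patients")
  pats <- unique(table$patientId)
  nP <- length(pats)
  ## per-patient sums and counts per arm -> fast resampled means
  x <- table[[metric]]
  sumA <- tapply(ifelse(inA, x, 0), factor(table$patientId, levels = pats), sum)
  cntA <- tapply(inA + 0, factor(table$patientId, levels = pats), sum)
  sumB <- tapply(ifelse(inB, x, 0), factor(table$patientId, levels = pats), sum)
  cntB <- tapply(inB + 0, factor(table$patientId, levels = pats), sum)
  meanA <- sum(sumA) / sum(cntA)
  meanB <- sum(sumB) / sum(cntB)
  diffObs <- meanA - meanB
  boots <- withLocalSeed(seed, {
    idx <- matrix(sample.int(nP, nP * nBoot, replace = TRUE), nrow = nP)
    sA <- matrix(sumA[idx], nrow = nP); cA <- matrix(cntA[idx], nrow = nP)
    sB <- matrix(sumB[idx], nrow = nP); cB <- matrix(cntB[idx], nrow = nP)
    colSums(sA) / pmax(colSums(cA), 1) - colSums(sB) / pmax(colSums(cB), 1)
  })
  ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
  pLo <- (sum(boots <= 0) + 1) / (nBoot + 1)
  pHi <- (sum(boots >= 0) + 1) / (nBoot + 1)
  p <- min(1, 2 * min(pLo, pHi))
  structure(list(metric = metric,
                 meanA = meanA, sdA = sd(x[inA]),
                 meanB = meanB, sdB = sd(x[inB]),
                 difference = diffObs, ci95 = ci, pValue = p,
                 nBoot = nBoot),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s: %.4f +/- %.4f vs %.4f +/- %.4f; diff %.4f (CI95 %.4f to %.4f), p = %.4g\n",
              x$metric, x$meanA, x$sdA, x$meanB, x$sdB, x$difference,
              x$ci95[1], x$ci95[2], x$pValue))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' obtained by random permutation (\code{nPerm} draws) for n < 30 and from
#' the asymptotic t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param nPerm number of permutations for the small-sample p-value.
#' @param seed integer seed for the permutation draw.
#' @return list with \code{rho} and \code{pValue}.
#' @export
spearmanCorr <- function(x, y, nPerm = 10000L, seed = 1L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearmanCorr: need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("spearmanCorr: rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 30) {
    p <- withLocalSeed(seed, {
      hits <- 0L
      for (i in seq_len(nPerm)) {
        r <- cor(rx, sample(ry))
        if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (nPerm + 1)
    })
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, pValue = min(p, 1))
}

#' ROC curve and AUC for a binary outcome
#'
#' AUC is the Mann-Whitney U statistic normalized by n1 * n0 (ties count
#' one half), computed from average ranks; the full sensitivity/specificity
#' grid over the unique score thresholds is returned.
#'
#' @param labels binary vector (1/TRUE = positive class).
#' @param scores numeric predictor values.
#' @param predictor name stored in the result.
#' @return list of class \code{RocResult}: \code{predictor}, \code{auc},
#'   and \code{grid} (threshold, sensitivity, specificity).
#' @export
rocAuc <- function(labels, scores, predictor = deparse(substitute(scores))) {
  lab <- as.integer(as.logical(labels))
  stopifnot(length(lab) == length(scores))
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0)
    stop("rocAuc: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  grid <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[lab == 1] >= t), 0),
    specificity = vapply(thr, function(t) mean(scores[lab == 0] < t), 0))
  structure(list(predictor = predictor, auc = auc, grid = grid),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC for '%s': AUC = %.3f (%d thresholds)\n",
              x$predictor, x$auc, nrow(x$grid)))
  invisible(x)
}

#' Run the full cohort analysis
#'
#' Emits treated-vs-fellow comparisons for every density/FAZ metric,
#' maculopathy-vs-no-maculopathy subgroup comparisons among treated eyes,
#' the Spearman correlation matrix of doses, FAZ areas, visual acuity and
#' densities, and per-predictor ROC for the burnout outcome.
#'
#' @param table cohort data.frame as produced by [generateCohort()] (or a
#'   measured equivalent with the same columns).
#' @param nBoot bootstrap replicates per comparison.
#' @param seed integer seed.
#' @return list with data.frames \code{treatedVsFellow}, \code{rmVsNoRm},
#'   \code{spearman}, \code{roc}.
#' @export
runCohortAnalysis <- function(table, nBoot = 2000L, seed = 1L) {
  metrics <- intersect(c(names(cohortBaselines()), "fazScpMm2", "fazDcpMm2"),
                       names(table))
  cmpRow <- function(cmp) data.frame(
    metric = cmp$metric, meanA = cmp$meanA, sdA = cmp$sdA, meanB = cmp$meanB,
    sdB = cmp$sdB, difference = cmp$difference, ciLow = cmp$ci95[1],
    ciHigh = cmp$ci95[2], pValue = cmp$pValue, stringsAsFactors = FALSE)
  tf <- do.call(rbind, lapply(seq_along(metrics), function(i)
    tryCatch(cmpRow(compareGroups(table, metrics[i],
                                  groupA = c("treated_RM", "treated_noRM"),
                                  groupB = "fellow_control", nBoot = nBoot,
                                  seed = seed + i)),
             error = function(e) NULL)))
  rm <- NULL
  if (sum(table$group == "treated_RM") >= 2 &&
      sum(table$group == "treated_noRM") >= 2 &&
      length(unique(table$patientId[table$group == "treated_RM"])) >= 2 &&
      length(unique(table$patientId[table$group == "treated_noRM"])) >= 2)
    rm <- do.call(rbind, lapply(seq_along(metrics), function(i)
      tryCatch(cmpRow(compareGroups(table, metrics[i], groupA = "treated_RM",
                                    groupB = "treated_noRM", nBoot = nBoot,
                                    seed = seed + 1000L + i)),
               error = function(e) NULL)))
  treated <- table[table$treated, , drop = FALSE]
  corVars <- intersect(c("fovealDoseGy", "discDoseGy", "intervalMonths",
                         "bcvaLogmar", "fazScpMm2", "fazDcpMm2", metrics),
                       names(treated))
  pairs <- utils::combn(corVars, 2)
  sp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    res <- tryCatch(spearmanCorr(treated[[a]], treated[[b]],
                                 seed = seed + 2000L + k),
                    error = function(e) list(rho = NA_real_, pValue = NA_real_))
    data.frame(varA = a, varB = b, rho = res$rho, pValue = res$pValue,
               stringsAsFactors = FALSE)
  }))
  roc <- NULL
  if ("burnout" %in% names(treated) && length(unique(treated$burnout)) == 2) {
    preds <- intersect(c("fovealDoseGy", "discDoseGy", "intervalMonths"),
                       names(treated))
    roc <- do.call(rbind, lapply(preds, function(p) {
      r <- rocAuc(treated$burnout, treated[[p]], predictor = p)
      data.frame(predictor = p, auc = r$auc, stringsAsFactors = FALSE)
    }))
  }
  list(treatedVsFellow = tf, rmVsNoRm = rm, spearman = sp, roc = roc)
}
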