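#' @include abmlm-package.R
NULL

#' Binary classification metrics
#'
#' Accuracy, AUC, AUPR, F1 and Matthews correlation coefficient for a
#' vector of scores against binary labels. AUC uses the rank statistic
#' with tie midranks; AUPR uses step-interpolated precision-recall
#' integration (average precision) by default, with a trapezoid variant
#' behind a flag; accuracy, F1 and MCC threshold scores at 0.5. When only
#' one class is present, AUC and AUPR are `NA` and the rest are computed.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or a two-level factor whose
#'   second level is positive).
#' @param trapezoid use trapezoidal PR integration instead of steps.
#' @return named list with `accuracy`, `auc`, `aupr`, `f1`, `mcc`.
#' @examples
#' binaryMetrics(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
#' @export
binaryMetrics <- function(scores, labels, trapezoid = FALSE) {
  stopifnot2(length(scores) == length(labels),
             "scores and labels must have equal length")
  y <- if (is.factor(labels)) as.integer(labels) - 1L else
    as.integer(as.logical(labels) | labels == 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  accuracy <- (tp + tn) / length(y)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  if (n1 == 0 || n0 == 0) {
    auc <- NA_real_; aupr <- NA_real_
  } else {
    r <- rank(scores)  # midranks handle ties
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(-scores)
    ys <- y[ord]; ss <- scores[ord]
    grp <- cumsum(!duplicated(ss))  # tie groups share a threshold
    tpc <- tapply(ys, grp, sum)
    npc <- tapply(ys, grp, length)
    cumTP <- cumsum(tpc); cumN <- cumsum(npc)
    precision <- cumTP / cumN
    recall <- cumTP / n1
    if (trapezoid) {
      rPrev <- c(0, head(recall, -1)); pPrev <- c(1, head(precision, -1))
      aupr <- sum((recall - rPrev) * (precision + pPrev) / 2)
    } else {
      dRecall <- diff(c(0, recall))
      aupr <- sum(dRecall * precision)
    }
  }
  list(accuracy = accuracy, auc = auc, aupr = aupr, f1 = f1, mcc = mcc)
}

#' Fold-averaged metrics with standard errors
#'
#' Computes [binaryMetrics()] per fold and reports the across-fold mean
#' and standard error of each metric (fold metrics are averaged, not
#' pooled).
#'
#' @param scoreList,labelList lists of per-fold scores and labels.
#' @return data.frame with `metric`, `mean`, `se`.
#' @export
binaryMetricsAcrossFolds <- function(scoreList, labelList) {
  per <- Map(binaryMetrics, scoreList, labelList)
  mat <- do.call(rbind, lapply(per, function(x) unlist(x)))
  data.frame(metric = colnames(mat),
             mean = colMeans(mat, na.rm = TRUE),
             se = apply(mat, 2, function(v)
               sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Region-wise paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-test per region between matched per-sequence
#' accuracy tables from two models, with p-values multiplied by the
#' number of regions tested and capped at 1. Zero-variance differences
#' yield p = 1 when the mean difference is 0 and the degenerate limit
#' p = 0 (with a warning) otherwise.
#'
#' @param accA,accB numeric matrices (sequences x regions) of paired
#'   per-sequence accuracies under models A and B; columns must match.
#' @param m number of comparisons for the correction (default: the
#'   number of region columns; the full per-position analysis uses 14).
#' @return data.frame with `region`, `meanDiff`, `t`, `pRaw`, `pAdj`.
#' @export
pairedTBonferroni <- function(accA, accB, m = ncol(accA)) {
  stopifnot2(identical(dim(accA), dim(accB)),
             "accuracy tables must have identical shape")
  regions <- colnames(accA)
  if (is.null(regions)) regions <- paste0("region", seq_len(ncol(accA)))
  out <- lapply(seq_len(ncol(accA)), function(j) {
    d <- accA[, j] - accB[, j]
    d <- d[!is.na(d)]
    n <- length(d)
    stopifnot2(n >= 2, "need at least two paired observations per region")
    md <- mean(d)
    sdd <- sd(d)
    if (sdd == 0) {
      if (md == 0) {
        tStat <- 0; pRaw <- 1
      } else {
        warning(sprintf(
          "region %s: zero-variance non-zero differences; p -> 0",
          regions[j]))
        tStat <- Inf * sign(md); pRaw <- 0
      }
    } else {
      tStat <- md / (sdd / sqrt(n))
      pRaw <- 2 * pt(-abs(tStat), df = n - 1)
    }
    data.frame(region = regions[j], meanDiff = md, t = tStat, pRaw = pRaw,
               pAdj = min(1, pRaw * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
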