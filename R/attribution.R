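#' @include classifier.R
NULL

#' Standard-scale a score vector
#'
#' Subtracts the mean and divides by the population standard deviation
#' (denominator n), so `c(1, 3)` scales to `c(-1, 1)`. A zero-variance
#' input yields an all-zero vector with a warning.
#'
#' @param x numeric vector of length >= 2.
#' @return scaled numeric vector with mean 0 and unit variance.
#' @export
standardScale <- function(x) {
  stopifnot2(length(x) >= 2, "need at least two values")
  mu <- mean(x)
  sdp <- sqrt(mean((x - mu)^2))
  if (sdp == 0) {
    warning("zero-variance scores; returning zeros")
    return(rep(0, length(x)))
  }
  (x - mu) / sdp
}

#' AttCAT token impact scores
#'
#' Gradient-based attribution for a frozen-base classifier: for every
#' layer l and token i, the class-activation term is the inner product of
#' the post-block hidden state with the gradient of the target-class
#' logit with respect to that hidden state, and the attention term is the
#' attention received by token i in layer l, averaged over heads and
#' query positions (or over heads of the classifier-token row with
#' `attention = "cls"`). The impact score of token i is the sum over
#' layers of the attention-weighted class-activation terms. Pads are
#' excluded; scores are additionally standard-scaled per sequence.
#'
#' Standard scaling uses the residue (non-special) positions only: the
#' classifier token receives the pooled logit gradient directly, so its
#' raw impact exceeds every residue impact by orders of magnitude, and
#' including it in the scaling statistics would compress all residue
#' scores toward a common constant. Special positions carry `NA` in the
#' normalized vector; raw scores are reported for every position.
#'
#' @param model the frozen [AbEncoder-class] base.
#' @param head a [ClassifierHead-class] trained on `model`.
#' @param record one record from [prepareMLMData()] (trimmed ids plus
#'   region/chain labels).
#' @param targetClass 1 or 2, indexing `head@levels`.
#' @param attention "received" (mean over heads and queries) or "cls"
#'   (classifier-token row only).
#' @return An [AttributionResult-class].
#' @export
attcatScores <- function(model, head, record, targetClass = 2L,
                         attention = c("received", "cls")) {
  attention <- match.arg(attention)
  stopifnot2(targetClass %in% c(1L, 2L), "targetClass must be 1 or 2")
  stopifnot2(head@pooling == "cls",
             "AttCAT requires the cls-pooled classifier head")
  fw <- .encoderForward(model, record$ids, cache = TRUE)
  n <- length(record$ids)
  # gradient of the target-class logit with respect to the final-LN output
  dXf <- matrix(0, n, model@config@hiddenSize)
  dXf[1, ] <- head@W[, targetClass]
  bw <- .encoderBackward(model, fw, dXf)
  impact <- numeric(n)
  for (l in seq_len(model@config@nLayers)) {
    cat_l <- rowSums(fw$hiddenStates[[l]] * bw$dHidden[[l]])
    a_l <- if (attention == "received") fw$attnRecv[[l]] else
      Reduce(`+`, lapply(fw$caches[[l]]$heads,
                         function(h) h$Pm[1, ])) / model@config@nHeads
    impact <- impact + a_l * cat_l
  }
  real <- record$chains != "special"
  normalized <- rep(NA_real_, n)
  normalized[real] <- standardScale(impact[real])
  summ <- data.frame(
    chain = record$chains[real], region = record$regions[real],
    score = abs(normalized[real]), stringsAsFactors = FALSE)
  agg <- aggregate(score ~ chain + region, summ, mean)
  names(agg)[names(agg) == "score"] <- "meanAbsScore"
  new("AttributionResult", rawScores = impact,
      normalizedScores = normalized, targetClass = as.integer(targetClass),
      perRegionSummary = agg,
      tokens = tokenOf(model@vocab, record$ids))
}

#' Mean absolute attribution by region across sequences
#'
#' Pools the per-region summaries of several [attcatScores()] results
#' into one mean |score| per (chain, region).
#'
#' @param results list of [AttributionResult-class] objects.
#' @return data.frame with `chain`, `region`, `meanAbsScore`.
#' @export
poolRegionAttribution <- function(results) {
  all <- do.call(rbind, lapply(results, slot, "perRegionSummary"))
  agg <- aggregate(meanAbsScore ~ chain + region, all, mean)
  agg[order(-agg$meanAbsScore), , drop = FALSE]
}

#' Confidence-stratified, probability-ordered sequence selection
#'
#' Averages predicted probabilities per sequence across one or more
#' classifiers, samples an (approximately) equal quota from each
#' confidence decile — each decile contributes `ceiling(n/10)` or
#' `floor(n/10)` sequences — and returns the selection sorted in
#' ascending order of the average probability.
#'
#' @param probMatrix numeric matrix, sequences x classifiers, of
#'   positive-class probabilities.
#' @param n number of sequences to select.
#' @param seed seed for the within-decile draws.
#' @return data.frame with `index` (into `probMatrix` rows) and
#'   `avgProb`, sorted ascending by `avgProb`.
#' @export
selectOrderedSequences <- function(probMatrix, n = 50L, seed = 1L) {
  probMatrix <- as.matrix(probMatrix)
  avg <- rowMeans(probMatrix)
  total <- length(avg)
  if (n >= total) {
    ord <- order(avg)
    return(data.frame(index = ord, avgProb = avg[ord]))
  }
  ord <- order(avg)
  binSizes <- diff(round(seq(0, total, length.out = 11)))
  bins <- split(ord, rep.int(seq_len(10), binSizes))
  base <- n %/% 10L
  extra <- n %% 10L
  quota <- rep.int(base, 10L)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  picked <- withSeed(deriveSeed(seed, 97L), unlist(Map(function(b, q) {
    q <- min(q, length(b))
    b[sample.int(length(b), q)]
  }, bins, quota)))
  picked <- picked[order(avg[picked])]
  data.frame(index = picked, avgProb = avg[picked], row.names = NULL)
}
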