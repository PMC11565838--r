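#' @include tokenization.R
NULL

#' Compute the per-token masking-probability matrix
#'
#' For the uniform strategy every residue position receives the base rate.
#' For the preferential strategy CDR3 positions of both chains receive the
#' elevated CDR3 rate and all other residue positions receive the
#' compensated rate `(base - cdr3 * p) / (1 - p)`, where `p` is the
#' fraction of residue tokens lying in CDR3 — so the mean over residue
#' positions stays exactly at the base rate whenever `p < base / cdr3`.
#' Special and pad positions always receive probability 0: the average is
#' taken over real residue tokens, since padding length is arbitrary and
#' carries no training signal.
#'
#' If `p` exceeds `base / cdr3` the compensated rate is clamped to 0 with
#' a warning (mean preservation then fails by construction); `p = 1` is
#' rejected as degenerate.
#'
#' @param tok a [TokenizedPair-class] with populated region labels.
#' @param params a [maskingParams()] object.
#' @return A [MaskingProbs-class].
#' @examples
#' tok <- encodePair("QVQ", "DIQ", aaVocabulary(), maxLen = 16)
#' maskingProbs(tok, maskingParams("uniform"))
#' @export
maskingProbs <- function(tok, params) {
  residue <- tok@chainOfToken != "special"
  nRes <- sum(residue)
  stopifnot2(nRes > 0, "no residue positions")
  probs <- numeric(length(tok@tokenIds))
  cdr3 <- residue & tok@tokenRegions == "CDR3"
  pHat <- sum(cdr3) / nRes
  if (params@strategy == "uniform") {
    probs[residue] <- params@baseRate
  } else {
    if (pHat >= 1)
      stop("degenerate input: every residue lies in CDR3", call. = FALSE)
    comp <- (params@baseRate - params@cdr3Rate * pHat) / (1 - pHat)
    if (comp < 0) {
      warning(sprintf(
        "CDR3 fraction %.3f exceeds base/cdr3 rate ratio; clamping the %s",
        pHat, "non-CDR3 rate to 0 (mean preservation fails)"))
      comp <- 0
    }
    probs[cdr3] <- params@cdr3Rate
    probs[residue & !cdr3] <- comp
  }
  new("MaskingProbs", probs = probs, cdr3Fraction = pHat,
      strategy = params@strategy)
}

#' Precompute masking-probability matrices for a dataset
#'
#' One matrix per record, computed in a single pass and optionally
#' persisted so the collator never recomputes them during training.
#'
#' @param toks list of [TokenizedPair-class] objects.
#' @param params a [maskingParams()] object.
#' @param path optional file path; when given, the matrices are saved as a
#'   container with a parameter header and can be reloaded byte-identical
#'   with [loadProbs()].
#' @return list of [MaskingProbs-class] objects (invisibly also saved).
#' @export
precomputeProbs <- function(toks, params, path = NULL) {
  out <- lapply(toks, maskingProbs, params = params)
  names(out) <- names(toks)
  if (!is.null(path)) {
    header <- list(strategy = params@strategy, baseRate = params@baseRate,
                   cdr3Rate = params@cdr3Rate, n = length(out))
    saveRDS(list(header = header, matrices = out), path)
  }
  out
}

#' @rdname precomputeProbs
#' @export
loadProbs <- function(path) readRDS(path)$matrices

#' Draw a dynamic masking selection
#'
#' Independent Bernoulli trial per position with that position's stored
#' probability; a fresh draw on every call, so each epoch sees a different
#' mask over the same precomputed matrix.
#'
#' @param probs a [MaskingProbs-class].
#' @return integer 0/1 vector of selected positions.
#' @export
drawSelection <- function(probs) {
  as.integer(runif(length(probs@probs)) < probs@probs)
}

#' Corrupt selected tokens 80/10/10
#'
#' Of the selected positions, independently: a `maskFrac` share is
#' replaced by `<mask>`, a `randomFrac` share by a random residue token
#' (specials are excluded so the layout cannot be corrupted; set
#' `wholeVocab = TRUE` to emulate whole-vocabulary sampling), and the
#' remaining `keepFrac` share is left unchanged but still predicted.
#' Labels carry the original id at every selected position and the `NA`
#' ignore sentinel elsewhere.
#'
#' @param tok a [TokenizedPair-class].
#' @param selection integer 0/1 vector from [drawSelection()].
#' @param params a [maskingParams()] object.
#' @param vocab a [Vocabulary-class].
#' @param wholeVocab sample random replacements from the full vocabulary.
#' @return An [MLMBatch-class] with one row.
#' @export
corruptTokens <- function(tok, selection, params, vocab = aaVocabulary(),
                          wholeVocab = FALSE) {
  ids <- tok@tokenIds
  sel <- which(selection == 1L)
  labels <- rep.int(NA_integer_, length(ids))
  labels[sel] <- ids[sel]
  out <- ids
  if (length(sel)) {
    u <- runif(length(sel))
    maskIdx <- sel[u < params@maskFrac]
    randIdx <- sel[u >= params@maskFrac &
                     u < params@maskFrac + params@randomFrac]
    out[maskIdx] <- .specialIds(vocab)["mask"]
    if (length(randIdx)) {
      pool <- if (wholeVocab) seq_along(vocab@tokens) else
        residueTokenIds(vocab)
      out[randIdx] <- pool[sample.int(length(pool), length(randIdx),
                                      replace = TRUE)]
    }
  }
  new("MLMBatch", corruptedIds = matrix(out, nrow = 1),
      labels = matrix(labels, nrow = 1),
      selection = matrix(as.integer(selection), nrow = 1))
}

#' Dynamic-masking collator
#'
#' Returns a closure that, for a list of tokenized pairs with precomputed
#' probability matrices, draws a fresh selection and corruption for every
#' `(epoch, batch)` call. All randomness derives from the collator seed
#' plus the epoch and batch indices, so any batch is reproducible in
#' isolation while masks still differ across epochs.
#'
#' @param params a [maskingParams()] object.
#' @param vocab a [Vocabulary-class].
#' @param seed integer collator seed.
#' @return `function(toks, probsList, epoch, batch)` returning an
#'   [MLMBatch-class] whose rows follow `toks`.
#' @export
mlmCollator <- function(params, vocab = aaVocabulary(), seed = 1L) {
  force(params); force(vocab); force(seed)
  function(toks, probsList, epoch = 1L, batch = 1L) {
    withSeed(deriveSeed(seed, epoch, batch), {
      rows <- Map(function(tok, pr)
        corruptTokens(tok, drawSelection(pr), params, vocab),
        toks, probsList)
      new("MLMBatch",
          corruptedIds = do.call(rbind, lapply(rows, slot, "corruptedIds")),
          labels = do.call(rbind, lapply(rows, slot, "labels")),
          selection = do.call(rbind, lapply(rows, slot, "selection")))
    })
  }
}

#' Expected per-region masking rates
#'
#' Summarizes a set of probability matrices into the expected masking rate
#' per region label, pooled over records — the report behind the
#' mask-stats interface.
#'
#' @param toks list of [TokenizedPair-class] objects.
#' @param probsList matching list of [MaskingProbs-class] objects.
#' @return data.frame of region, expected rate and token count.
#' @export
maskRateReport <- function(toks, probsList) {
  regions <- unlist(lapply(toks, slot, "tokenRegions"))
  probs <- unlist(lapply(probsList, slot, "probs"))
  keep <- regions != "NONE"
  agg <- tapply(probs[keep], regions[keep], mean)
  data.frame(region = names(agg), expectedRate = as.numeric(agg),
             nTokens = as.integer(table(regions[keep])[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
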