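#' @include training.R
NULL

#' Sequence classification head
#'
#' A single feedforward layer over a pooled hidden state of a frozen base
#' encoder.
#'
#' @slot W,b linear layer parameters (hidden x 2, and length-2 bias).
#' @slot pooling "cls" (first classifier token) or "mean".
#' @slot levels the two class labels, second level = positive class.
#' @slot baseChecksum checksum of the frozen base at training time.
#' @exportClass ClassifierHead
setClass("ClassifierHead",
  representation(W = "matrix", b = "numeric", pooling = "character",
                 levels = "character", baseChecksum = "numeric"))

setMethod("show", "ClassifierHead", function(object) {
  cat("ClassifierHead (", object@pooling, " pooling): ",
      paste(object@levels, collapse = " vs "), "\n", sep = "")
})

.poolFeature <- function(model, ids, pooling) {
  fw <- .encoderForward(model, ids)
  if (pooling == "cls") fw$hidden[1, ] else colMeans(fw$hidden)
}

#' Pooled base-model features for a record list
#'
#' @param model an [AbEncoder-class].
#' @param records list from [prepareMLMData()].
#' @param pooling "cls" or "mean".
#' @return numeric matrix, records x hidden size.
#' @export
baseFeatures <- function(model, records, pooling = c("cls", "mean")) {
  pooling <- match.arg(pooling)
  t(vapply(records, function(rec) .poolFeature(model, rec$ids, pooling),
           numeric(model@config@hiddenSize)))
}

#' Train a linear softmax head on fixed features
#'
#' Minibatch Adam over a single feedforward layer with the linear
#' warmup/decay schedule; the building block behind
#' [trainClassifierHead()].
#'
#' @param features numeric matrix (records x dims).
#' @param labels factor or character with exactly two levels.
#' @param config list of `epochs`, `batchSize`, `peakLR`, `warmupRatio`,
#'   `seed`.
#' @return list with `W`, `b`, `levels`, `history` (epoch losses).
#' @export
trainLinearHead <- function(features, labels,
                            config = list(epochs = 50L, batchSize = 256L,
                                          peakLR = 1e-5, warmupRatio = 0.1,
                                          seed = 1L)) {
  y <- as.integer(factor(labels))
  lv <- levels(factor(labels))
  stopifnot2(length(lv) == 2, "labels must have exactly two classes")
  n <- nrow(features); d <- ncol(features)
  params <- withSeed(deriveSeed(config$seed, 83L),
                     list(W = .initMatrix(d, 2), b = rep(0, 2)))
  state <- .adamInit(params)
  stepsPerEpoch <- ceiling(n / config$batchSize)
  totalSteps <- config$epochs * stepsPerEpoch
  warmupSteps <- max(1L, round(config$warmupRatio * totalSteps))
  history <- numeric(config$epochs)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    perm <- withSeed(deriveSeed(config$seed, 89L, ep), sample.int(n))
    epLoss <- 0; epN <- 0
    for (bi in seq_len(stepsPerEpoch)) {
      step <- step + 1L
      idx <- perm[((bi - 1L) * config$batchSize + 1L):
                    min(bi * config$batchSize, n)]
      X <- features[idx, , drop = FALSE]
      logits <- X %*% params$W + matrix(params$b, length(idx), 2,
                                        byrow = TRUE)
      ce <- .softmaxXent(logits, y[idx])
      grads <- list(W = t(X) %*% ce$dlogits / length(idx),
                    b = colSums(ce$dlogits) / length(idx))
      lr <- lrSchedule(step, config$peakLR, warmupSteps, totalSteps)
      upd <- .adamStep(params, grads, state, lr, weightDecay = 0)
      params <- upd$params
      state <- upd$state
      epLoss <- epLoss + ce$lossSum
      epN <- epN + ce$n
    }
    history[ep] <- epLoss / epN
  }
  list(W = params$W, b = params$b, levels = lv, history = history)
}

#' Train a frozen-base sequence classification head
#'
#' Pools each record's final hidden states (first classifier token by
#' default) through the frozen base encoder, then trains a single
#' feedforward layer to two logits. Only head parameters receive updates;
#' the base checksum is recorded so freezing can be asserted.
#'
#' @param model the frozen [AbEncoder-class] base.
#' @param records list from [prepareMLMData()].
#' @param labels two-class labels aligned to `records`.
#' @param config see [trainLinearHead()]; full-scale defaults are 50
#'   epochs, batch 256, peak learning rate 1e-5, warmup ratio 0.1.
#' @param pooling "cls" or "mean".
#' @return A [ClassifierHead-class].
#' @export
trainClassifierHead <- function(model, records, labels,
                                config = list(epochs = 50L,
                                              batchSize = 256L,
                                              peakLR = 1e-5,
                                              warmupRatio = 0.1, seed = 1L),
                                pooling = c("cls", "mean")) {
  pooling <- match.arg(pooling)
  checksumBefore <- parameterChecksum(model)
  features <- baseFeatures(model, records, pooling)
  fit <- trainLinearHead(features, labels, config)
  stopifnot2(identical(parameterChecksum(model), checksumBefore),
             "protocol error: frozen base was modified during head training")
  new("ClassifierHead", W = fit$W, b = fit$b, pooling = pooling,
      levels = fit$levels, baseChecksum = checksumBefore)
}

#' Fine-tune the encoder end to end for sequence classification
#'
#' Attaches a freshly initialized cls-pooled linear head and updates the
#' head *and every encoder parameter* jointly with Adam (decoupled weight
#' decay, linear warmup/decay schedule) on the two-class cross-entropy.
#' This is the alternative to the frozen-base protocol of
#' [trainClassifierHead()]: with a frozen base the pooled feature is a
#' fixed function of sequence composition, so gradient attributions
#' spread over whatever tokens happen to project onto the head weights;
#' only when the encoder itself is trained on the classification signal
#' does its computation — and therefore the attribution — concentrate on
#' the discriminative positions.
#'
#' @param model an [AbEncoder-class] starting point (typically MLM
#'   pre-trained).
#' @param records list from [prepareMLMData()].
#' @param labels two-class labels aligned to `records`.
#' @param config list of `totalSteps`, `batchSize`, `peakLR`,
#'   `warmupSteps`, `seed`.
#' @return list with the fine-tuned `model`, a cls-pooled
#'   [ClassifierHead-class] whose checksum matches the fine-tuned model,
#'   and `history` (mean batch loss per step).
#' @export
fineTuneClassifier <- function(model, records, labels,
                               config = list(totalSteps = 150L,
                                             batchSize = 8L,
                                             peakLR = 5e-4,
                                             warmupSteps = 15L,
                                             seed = 1L)) {
  y <- as.integer(factor(labels))
  lv <- levels(factor(labels))
  stopifnot2(length(lv) == 2, "labels must have exactly two classes")
  stopifnot2(length(records) == length(y),
             "records and labels must align")
  d <- model@config@hiddenSize
  head <- withSeed(deriveSeed(config$seed, 83L),
                   list(`head.W` = .initMatrix(d, 2), `head.b` = rep(0, 2)))
  allParams <- c(model@params, head)
  nBase <- length(model@params)
  state <- .adamInit(allParams)
  n <- length(records)
  history <- numeric(config$totalSteps)
  for (step in seq_len(config$totalSteps)) {
    idx <- withSeed(deriveSeed(config$seed, 101L, step),
                    sample.int(n, min(config$batchSize, n)))
    grads <- NULL
    lossSum <- 0
    model@params <- allParams[seq_len(nBase)]
    for (i in idx) {
      rec <- records[[i]]
      len <- length(rec$ids)
      fw <- .encoderForward(model, rec$ids, cache = TRUE)
      f <- fw$hidden[1, ]
      logits <- matrix(f %*% allParams$`head.W` + allParams$`head.b`, 1, 2)
      ce <- .softmaxXent(logits, y[i])
      lossSum <- lossSum + ce$lossSum
      dXf <- matrix(0, len, d)
      dXf[1, ] <- drop(ce$dlogits %*% t(allParams$`head.W`))
      bw <- .encoderBackward(model, fw, dXf)
      g <- bw$grads
      g$emb <- matrix(0, nrow(allParams$emb), d)
      for (k in seq_len(len))
        g$emb[rec$ids[k], ] <- g$emb[rec$ids[k], ] + bw$dX0[k, ]
      g$`head.W` <- outer(f, drop(ce$dlogits))
      g$`head.b` <- drop(ce$dlogits)
      grads <- .accumulate(grads, g)
    }
    grads <- lapply(grads, `/`, length(idx))
    lr <- lrSchedule(step, config$peakLR, config$warmupSteps,
                     config$totalSteps)
    upd <- .adamStep(allParams, grads, state, lr)
    allParams <- upd$params
    state <- upd$state
    history[step] <- lossSum / length(idx)
  }
  model@params <- allParams[seq_len(nBase)]
  list(model = model,
       head = new("ClassifierHead", W = allParams$`head.W`,
                  b = allParams$`head.b`, pooling = "cls", levels = lv,
                  baseChecksum = parameterChecksum(model)),
       history = history)
}

#' Predict class probabilities with a trained head
#'
#' @param head a [ClassifierHead-class].
#' @param model the frozen base used at training time.
#' @param records list from [prepareMLMData()].
#' @return matrix of class probabilities (records x 2, columns named by
#'   the class levels).
#' @export
predictClassifierHead <- function(head, model, records) {
  features <- baseFeatures(model, records, head@pooling)
  logits <- features %*% head@W + matrix(head@b, nrow(features), 2,
                                         byrow = TRUE)
  probs <- .softmaxRows(logits)
  colnames(probs) <- head@levels
  probs
}
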