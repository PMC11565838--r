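#' @include backprop.R
NULL

#' Prepare tokenized records for training
#'
#' Trims pads, attaches region/chain labels and the precomputed masking
#' probabilities for each record — the in-memory form consumed by
#' [trainMLM()].
#'
#' @param toks list of [TokenizedPair-class] objects.
#' @param params a [maskingParams()] object.
#' @return list of records with elements `ids`, `regions`, `chains`,
#'   `probs` (all trimmed to real tokens).
#' @export
prepareMLMData <- function(toks, params) {
  probsList <- precomputeProbs(toks, params)
  Map(function(tok, pr) {
    real <- which(tok@attentionFlags == 1L)
    list(ids = tok@tokenIds[real], regions = tok@tokenRegions[real],
         chains = tok@chainOfToken[real], probs = pr@probs[real])
  }, toks, probsList)
}

.drawRecordBatch <- function(rec, vocab, params) {
  sel <- which(runif(length(rec$probs)) < rec$probs)
  labels <- rep.int(NA_integer_, length(rec$ids))
  labels[sel] <- rec$ids[sel]
  ids <- rec$ids
  if (length(sel)) {
    u <- runif(length(sel))
    maskIdx <- sel[u < params@maskFrac]
    randIdx <- sel[u >= params@maskFrac &
                     u < params@maskFrac + params@randomFrac]
    ids[maskIdx] <- .specialIds(vocab)["mask"]
    if (length(randIdx)) {
      pool <- residueTokenIds(vocab)
      ids[randIdx] <- pool[sample.int(length(pool), length(randIdx),
                                      replace = TRUE)]
    }
  }
  list(ids = ids, labels = labels)
}

#' Region-stratified cross-entropy loss
#'
#' Partitions per-token cross-entropy into non-CDR, CDR1, CDR2 and CDR3
#' components (chains pooled). Each component is the mean loss over
#' predicted tokens of that region; regions with no predicted tokens are
#' reported as `NA`, and the overall loss equals the count-weighted mean
#' of the components.
#'
#' @param logits matrix of logits (positions x vocabulary).
#' @param labels integer labels with `NA` at unpredicted positions.
#' @param regions character region labels per position.
#' @return list with `overall`, `nonCDR`, `CDR1`, `CDR2`, `CDR3` and
#'   `counts`.
#' @export
regionStratifiedLoss <- function(logits, labels, regions) {
  stopifnot2(nrow(logits) == length(labels) &&
               length(labels) == length(regions), "shape mismatch")
  ce <- .softmaxXent(logits, labels)
  grp <- regions[ce$sel]
  grp[grp %in% c("FR1", "FR2", "FR3", "FR4")] <- "nonCDR"
  comp <- c(nonCDR = NA_real_, CDR1 = NA_real_, CDR2 = NA_real_,
            CDR3 = NA_real_)
  counts <- c(nonCDR = 0L, CDR1 = 0L, CDR2 = 0L, CDR3 = 0L)
  for (g in names(comp)) {
    k <- grp == g
    if (any(k)) {
      comp[g] <- mean(ce$lossPos[k])
      counts[g] <- sum(k)
    }
  }
  overall <- if (ce$n > 0) ce$lossSum / ce$n else NA_real_
  c(list(overall = overall), as.list(comp), list(counts = counts))
}

.evalRegionLoss <- function(model, valCorrupted) {
  sums <- c(overall = 0, nonCDR = 0, CDR1 = 0, CDR2 = 0, CDR3 = 0)
  ns <- c(overall = 0, nonCDR = 0, CDR1 = 0, CDR2 = 0, CDR3 = 0)
  for (vb in valCorrupted) {
    logits <- mlmLogits(model, vb$ids)
    rl <- regionStratifiedLoss(logits, vb$labels, vb$regions)
    for (g in names(sums)) {
      if (!is.na(rl[[g]]) && (g == "overall" || rl$counts[g] > 0)) {
        w <- if (g == "overall") sum(rl$counts) else rl$counts[g]
        sums[g] <- sums[g] + rl[[g]] * w
        ns[g] <- ns[g] + w
      }
    }
  }
  out <- sums / ns
  out[ns == 0] <- NA_real_
  out
}

#' Train a masked language model
#'
#' Minibatch Adam training with dynamic masking: every record gets a fresh
#' Bernoulli selection from its precomputed probability matrix at every
#' visit, followed by 80/10/10 corruption. The learning rate follows a
#' linear warmup/decay schedule. Validation loss is always computed under
#' fixed-seed uniform masking regardless of the training strategy, because
#' the preferential objective is harder by construction and training
#' losses are not comparable across strategies; the fixed evaluation seed
#' makes validation masks identical across strategies and steps.
#'
#' @param model an [AbEncoder-class].
#' @param trainData,valData record lists from [prepareMLMData()]
#'   (`valData` probabilities are replaced by the uniform protocol).
#' @param params the training [maskingParams()].
#' @param config list of `batchSize`, `totalSteps`, `peakLR`,
#'   `warmupSteps`, `evalEvery`, `seed`, `evalSeed`.
#' @return list with the trained `model`, a `history` data.frame (step,
#'   training loss, overall and per-region validation losses) and
#'   `bestStep` (minimum overall validation loss).
#' @export
trainMLM <- function(model, trainData, valData, params,
                     config = list(batchSize = 8L, totalSteps = 100L,
                                   peakLR = 1e-3, warmupSteps = 10L,
                                   evalEvery = 10L, seed = 1L,
                                   evalSeed = 999L)) {
  vocab <- model@vocab
  uniformParams <- maskingParams("uniform", baseRate = params@baseRate,
                                 maskFrac = params@maskFrac,
                                 randomFrac = params@randomFrac,
                                 keepFrac = params@keepFrac)
  # fixed-seed uniform validation corruption, precomputed once
  valCorrupted <- lapply(seq_along(valData), function(j) {
    rec <- valData[[j]]
    recU <- rec
    recU$probs <- ifelse(rec$chains == "special", 0, uniformParams@baseRate)
    cb <- withSeed(deriveSeed(config$evalSeed, j),
                   .drawRecordBatch(recU, vocab, uniformParams))
    list(ids = cb$ids, labels = cb$labels, regions = rec$regions)
  })
  state <- .adamInit(model@params)
  history <- NULL
  nTrain <- length(trainData)
  for (step in seq_len(config$totalSteps)) {
    idx <- withSeed(deriveSeed(config$seed, 2L, step),
                    sample.int(nTrain, config$batchSize, replace = TRUE))
    total <- NULL; lossSum <- 0; tokSum <- 0
    for (j in seq_along(idx)) {
      rec <- trainData[[idx[j]]]
      cb <- withSeed(deriveSeed(config$seed, 3L, step, j),
                     .drawRecordBatch(rec, vocab, params))
      if (all(is.na(cb$labels))) {
        warning(sprintf("empty selection at step %d; record skipped", step))
        next
      }
      lg <- .mlmLossGrad(model, cb$ids, cb$labels)
      total <- .accumulate(total, lg$grads)
      lossSum <- lossSum + lg$lossSum
      tokSum <- tokSum + lg$n
    }
    if (tokSum == 0) next
    total <- lapply(total, `/`, tokSum)
    lr <- lrSchedule(step, config$peakLR, config$warmupSteps,
                     config$totalSteps)
    upd <- .adamStep(model@params, total, state, lr)
    model@params <- upd$params
    state <- upd$state
    if (step %% config$evalEvery == 0 || step == config$totalSteps) {
      vl <- .evalRegionLoss(model, valCorrupted)
      history <- rbind(history, data.frame(
        step = step, trainLoss = lossSum / tokSum,
        valOverall = vl["overall"], valNonCDR = vl["nonCDR"],
        valCDR1 = vl["CDR1"], valCDR2 = vl["CDR2"], valCDR3 = vl["CDR3"],
        row.names = NULL))
    }
  }
  bestStep <- if (is.null(history)) NA_integer_ else
    history$step[which.min(history$valOverall)]
  list(model = model, history = history, bestStep = bestStep)
}

#' Iterative per-position masked prediction accuracy
#'
#' For each residue of each sequence in turn, replaces that single token
#' with `<mask>` (all other tokens intact), predicts it as the argmax of
#' the MLM logits over residue tokens, and scores correct/incorrect.
#' Accuracies are aggregated per sequence and per region-by-chain (14
#' regions); regions absent from a sequence are omitted, not scored zero.
#'
#' @param model an [AbEncoder-class].
#' @param records list from [prepareMLMData()] (any masking params).
#' @return data.frame with columns `sequence`, `chain`, `region`,
#'   `accuracy`, `n`.
#' @export
perPositionAccuracy <- function(model, records) {
  vocab <- model@vocab
  maskId <- .specialIds(vocab)["mask"]
  resIds <- residueTokenIds(vocab)
  out <- list()
  for (s in seq_along(records)) {
    rec <- records[[s]]
    pos <- which(rec$chains != "special")
    correct <- logical(length(pos))
    for (j in seq_along(pos)) {
      ids <- rec$ids
      ids[pos[j]] <- maskId
      logits <- mlmLogits(model, ids)[pos[j], ]
      pred <- resIds[which.max(logits[resIds])]
      correct[j] <- pred == rec$ids[pos[j]]
    }
    key <- paste(rec$chains[pos], rec$regions[pos])
    acc <- tapply(correct, key, mean)
    nn <- tapply(correct, key, length)
    parts <- strsplit(names(acc), " ")
    out[[s]] <- data.frame(
      sequence = s,
      chain = vapply(parts, `[`, character(1), 1),
      region = vapply(parts, `[`, character(1), 2),
      accuracy = as.numeric(acc), n = as.integer(nn),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
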