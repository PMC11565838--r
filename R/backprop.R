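#' @include encoder.R
NULL

# Reverse-mode pass through the encoder given the gradient with respect to
# the final-LN output. Returns parameter gradients (named like params),
# the gradient with respect to each post-block hidden state (dHidden,
# used by AttCAT), and the gradient with respect to the embedding rows.
.encoderBackward <- function(model, fw, dHiddenOut) {
  cfg <- model@config
  P <- model@params
  d <- cfg@hiddenSize; nh <- cfg@nHeads; dh <- d %/% nh
  n <- nrow(dHiddenOut)
  grads <- list()
  addg <- function(name, g) {
    grads[[name]] <<- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  lnfB <- .layerNormB(dHiddenOut, fw$lnf, P$lnf.g)
  addg("lnf.g", lnfB$dg); addg("lnf.b", lnfB$db)
  dX <- lnfB$dX
  dHidden <- vector("list", cfg@nLayers)
  for (l in rev(seq(fw$fromLayer,
                    length.out = cfg@nLayers - fw$fromLayer + 1L))) {
    dHidden[[l]] <- dX  # d(target)/d h^l at the post-block residual sum
    p <- sprintf("L%d.", l)
    cc <- fw$caches[[l]]
    # feedforward sublayer: X2 = X1 + gelu(LN2(X1) W1 + b1) W2 + b2
    dF <- dX
    addg(paste0(p, "W2"), t(cc$Hh) %*% dF)
    addg(paste0(p, "b2"), colSums(dF))
    dH <- dF %*% t(P[[paste0(p, "W2")]])
    dZ <- dH * .geluGrad(cc$Z)
    addg(paste0(p, "W1"), t(cc$B) %*% dZ)
    addg(paste0(p, "b1"), colSums(dZ))
    dB <- dZ %*% t(P[[paste0(p, "W1")]])
    ln2B <- .layerNormB(dB, cc$ln2, P[[paste0(p, "ln2.g")]])
    addg(paste0(p, "ln2.g"), ln2B$dg); addg(paste0(p, "ln2.b"), ln2B$db)
    dX1 <- dX + ln2B$dX
    # attention sublayer: X1 = X + (concat_h P_h V_h) Wo + bo
    dY <- dX1
    addg(paste0(p, "Wo"), t(cc$O) %*% dY)
    addg(paste0(p, "bo"), colSums(dY))
    dO <- dY %*% t(P[[paste0(p, "Wo")]])
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (h in seq_len(nh)) {
      colsH <- (h - 1L) * dh + seq_len(dh)
      hd <- cc$heads[[h]]
      dOh <- dO[, colsH, drop = FALSE]
      dPm <- dOh %*% t(hd$Vh)
      dV[, colsH] <- t(hd$Pm) %*% dOh
      dS <- hd$Pm * (dPm - rowSums(dPm * hd$Pm))
      dQr <- dS %*% hd$Kr / sqrt(dh)
      dKr <- t(dS) %*% hd$Qr / sqrt(dh)
      if (cfg@useRotary) {
        dQ[, colsH] <- .rotaryB(dQr, fw$rot)
        dK[, colsH] <- .rotaryB(dKr, fw$rot)
      } else {
        dQ[, colsH] <- dQr
        dK[, colsH] <- dKr
      }
    }
    addg(paste0(p, "Wq"), t(cc$A) %*% dQ)
    addg(paste0(p, "bq"), colSums(dQ))
    addg(paste0(p, "Wk"), t(cc$A) %*% dK)
    addg(paste0(p, "bk"), colSums(dK))
    addg(paste0(p, "Wv"), t(cc$A) %*% dV)
    addg(paste0(p, "bv"), colSums(dV))
    dA <- dQ %*% t(P[[paste0(p, "Wq")]]) + dK %*% t(P[[paste0(p, "Wk")]]) +
      dV %*% t(P[[paste0(p, "Wv")]])
    ln1B <- .layerNormB(dA, cc$ln1, P[[paste0(p, "ln1.g")]])
    addg(paste0(p, "ln1.g"), ln1B$dg); addg(paste0(p, "ln1.b"), ln1B$db)
    dX <- dX1 + ln1B$dX
  }
  list(grads = grads, dHidden = dHidden, dX0 = dX)
}

# Cross-entropy over positions with non-NA labels. Returns the mean loss,
# per-position losses and the logits gradient (sum convention: divide by
# the caller's token count when averaging across a batch).
.softmaxXent <- function(logits, labels) {
  sel <- which(!is.na(labels))
  probs <- .softmaxRows(logits)
  eps <- 1e-12
  lossPos <- -log(probs[cbind(sel, labels[sel])] + eps)
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[sel, ] <- probs[sel, , drop = FALSE]
  dlogits[cbind(sel, labels[sel])] <- dlogits[cbind(sel, labels[sel])] - 1
  list(lossSum = sum(lossPos), n = length(sel), lossPos = lossPos,
       sel = sel, dlogits = dlogits)
}

# Full loss + gradient for one corrupted sequence (ids and labels trimmed
# to real tokens). Gradients use the sum convention.
.mlmLossGrad <- function(model, ids, labels) {
  fw <- .encoderForward(model, ids, cache = TRUE)
  V <- length(model@vocab@tokens)
  logits <- fw$hidden %*% model@params$mlm.W +
    matrix(model@params$mlm.b, length(ids), V, byrow = TRUE)
  ce <- .softmaxXent(logits, labels)
  if (ce$n == 0) return(list(lossSum = 0, n = 0, grads = NULL))
  dXf <- ce$dlogits %*% t(model@params$mlm.W)
  bw <- .encoderBackward(model, fw, dXf)
  grads <- bw$grads
  grads[["mlm.W"]] <- t(fw$hidden) %*% ce$dlogits
  grads[["mlm.b"]] <- colSums(ce$dlogits)
  grads[["emb"]] <- matrix(0, V, model@config@hiddenSize)
  for (i in seq_along(ids))
    grads[["emb"]][ids[i], ] <- grads[["emb"]][ids[i], ] + bw$dX0[i, ]
  list(lossSum = ce$lossSum, n = ce$n, grads = grads, logits = logits)
}

.accumulate <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

# ---- Adam with linear warmup/decay ----

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0.01) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    decay <- if (grepl("\\.b$|\\.g$|b[qkvo12]$|mlm\\.b$", nm)) 0 else
      weightDecay
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Linear warmup/decay learning-rate schedule
#'
#' Rises linearly from 0 to `peakLR` over `warmupSteps`, then decays
#' linearly to 0 at `totalSteps`.
#'
#' @param step current step (1-based).
#' @param peakLR peak learning rate.
#' @param warmupSteps,totalSteps schedule shape; `warmupSteps` must not
#'   exceed `totalSteps`.
#' @return numeric learning rate.
#' @export
lrSchedule <- function(step, peakLR, warmupSteps, totalSteps) {
  stopifnot2(warmupSteps <= totalSteps,
             "warmupSteps must not exceed totalSteps")
  if (step <= warmupSteps) return(peakLR * step / warmupSteps)
  peakLR * (totalSteps - step) / (totalSteps - warmupSteps)
}
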