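#' @include masking.R
NULL

# ---- primitive layers (forward + cached intermediates) ----

.layerNormF <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  list(Y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(X), length(b),
                                           byrow = TRUE),
       xhat = xhat, sd = sd)
}

.layerNormB <- function(dY, cache, g) {
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  list(dX = dX, dg = dg, db = db)
}

.rotaryAngles <- function(n, dh, base = 10000) {
  hh <- dh %/% 2L
  inv <- base^(-(2 * (seq_len(hh) - 1)) / dh)
  ang <- outer(seq_len(n) - 1, inv)
  list(cosA = cos(ang), sinA = sin(ang), hh = hh)
}

.rotaryF <- function(Xh, rot) {
  hh <- rot$hh
  x1 <- Xh[, seq_len(hh), drop = FALSE]
  x2 <- Xh[, hh + seq_len(hh), drop = FALSE]
  cbind(x1 * rot$cosA - x2 * rot$sinA, x2 * rot$cosA + x1 * rot$sinA)
}

.rotaryB <- function(dY, rot) {
  hh <- rot$hh
  d1 <- dY[, seq_len(hh), drop = FALSE]
  d2 <- dY[, hh + seq_len(hh), drop = FALSE]
  cbind(d1 * rot$cosA + d2 * rot$sinA, d2 * rot$cosA - d1 * rot$sinA)
}

.softmaxRows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  e <- exp(S - mx)
  e / rowSums(e)
}

.geluF <- function(x) x * pnorm(x)
.geluGrad <- function(x) pnorm(x) + x * dnorm(x)

# ---- model construction ----

.initMatrix <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, 0, sd), nr, nc)

#' Build a transformer encoder MLM
#'
#' Pre-layer-norm encoder blocks with multi-head self-attention (rotary
#' position embeddings on queries and keys when enabled), GELU feedforward
#' sublayers, a final layer norm and a linear masked-language-model head
#' over the vocabulary. Initialization is deterministic per seed.
#'
#' @param config an [encoderConfig()].
#' @param vocab a [Vocabulary-class].
#' @param seed initialization seed.
#' @return An [AbEncoder-class].
#' @examples
#' model <- buildEncoder(encoderConfig(nLayers = 1, nHeads = 2,
#'                                     hiddenSize = 16,
#'                                     intermediateSize = 32), seed = 1)
#' model
#' @export
buildEncoder <- function(config, vocab = aaVocabulary(), seed = 1L) {
  d <- config@hiddenSize; di <- config@intermediateSize
  V <- length(vocab@tokens)
  withSeed(deriveSeed(seed, 71L), {
    params <- list(emb = .initMatrix(V, d))
    for (l in seq_len(config@nLayers)) {
      p <- sprintf("L%d.", l)
      params[[paste0(p, "ln1.g")]] <- rep(1, d)
      params[[paste0(p, "ln1.b")]] <- rep(0, d)
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        params[[paste0(p, w)]] <- .initMatrix(d, d)
      for (b in c("bq", "bk", "bv", "bo"))
        params[[paste0(p, b)]] <- rep(0, d)
      params[[paste0(p, "ln2.g")]] <- rep(1, d)
      params[[paste0(p, "ln2.b")]] <- rep(0, d)
      params[[paste0(p, "W1")]] <- .initMatrix(d, di)
      params[[paste0(p, "b1")]] <- rep(0, di)
      params[[paste0(p, "W2")]] <- .initMatrix(di, d)
      params[[paste0(p, "b2")]] <- rep(0, d)
    }
    params[["lnf.g"]] <- rep(1, d)
    params[["lnf.b"]] <- rep(0, d)
    params[["mlm.W"]] <- .initMatrix(d, V)
    params[["mlm.b"]] <- rep(0, V)
    new("AbEncoder", config = config, params = params, vocab = vocab,
        seed = as.integer(seed))
  })
}

#' Number of parameters of an encoder
#' @param model an [AbEncoder-class].
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, numeric(1)))
}

# Deterministic checksum over all parameter arrays; used to assert that a
# frozen base is untouched by head training.
#' @rdname parameterCount
#' @export
parameterChecksum <- function(model) {
  sum(vapply(model@params,
             function(p) sum(as.numeric(p) * seq_along(p)) %% 1e9,
             numeric(1)))
}

# ---- forward ----

# Runs blocks fromLayer..nLayers on ids (fromLayer = 1) or on a supplied
# hidden-state matrix X0 (fromLayer > 1 resumes after block fromLayer-1).
# Returns the final-LN hidden states plus, when cache = TRUE, per-block
# caches, the post-block hidden states and per-layer mean attention
# received by each token.
.encoderForward <- function(model, ids = NULL, cache = FALSE,
                            fromLayer = 1L, X0 = NULL) {
  cfg <- model@config
  P <- model@params
  d <- cfg@hiddenSize; nh <- cfg@nHeads; dh <- d %/% nh
  X <- if (fromLayer == 1L) P$emb[ids, , drop = FALSE] else X0
  n <- nrow(X)
  rot <- if (cfg@useRotary) .rotaryAngles(n, dh) else NULL
  caches <- vector("list", cfg@nLayers)
  hidden <- vector("list", cfg@nLayers)
  attnRecv <- vector("list", cfg@nLayers)
  for (l in seq(fromLayer, length.out = cfg@nLayers - fromLayer + 1L)) {
    p <- sprintf("L%d.", l)
    ln1 <- .layerNormF(X, P[[paste0(p, "ln1.g")]], P[[paste0(p, "ln1.b")]])
    A <- ln1$Y
    Q <- A %*% P[[paste0(p, "Wq")]] + matrix(P[[paste0(p, "bq")]], n, d,
                                             byrow = TRUE)
    K <- A %*% P[[paste0(p, "Wk")]] + matrix(P[[paste0(p, "bk")]], n, d,
                                             byrow = TRUE)
    Vv <- A %*% P[[paste0(p, "Wv")]] + matrix(P[[paste0(p, "bv")]], n, d,
                                              byrow = TRUE)
    O <- matrix(0, n, d)
    heads <- vector("list", nh)
    recv <- numeric(n)
    for (h in seq_len(nh)) {
      colsH <- (h - 1L) * dh + seq_len(dh)
      Qh <- Q[, colsH, drop = FALSE]
      Kh <- K[, colsH, drop = FALSE]
      Vh <- Vv[, colsH, drop = FALSE]
      Qr <- if (cfg@useRotary) .rotaryF(Qh, rot) else Qh
      Kr <- if (cfg@useRotary) .rotaryF(Kh, rot) else Kh
      S <- Qr %*% t(Kr) / sqrt(dh)
      Pm <- .softmaxRows(S)
      O[, colsH] <- Pm %*% Vh
      recv <- recv + colMeans(Pm)
      if (cache) heads[[h]] <- list(Qr = Qr, Kr = Kr, Vh = Vh, Pm = Pm)
    }
    Y <- O %*% P[[paste0(p, "Wo")]] + matrix(P[[paste0(p, "bo")]], n, d,
                                             byrow = TRUE)
    X1 <- X + Y
    ln2 <- .layerNormF(X1, P[[paste0(p, "ln2.g")]], P[[paste0(p, "ln2.b")]])
    B <- ln2$Y
    Z <- B %*% P[[paste0(p, "W1")]] + matrix(P[[paste0(p, "b1")]], n,
                                             cfg@intermediateSize,
                                             byrow = TRUE)
    Hh <- .geluF(Z)
    X2 <- X1 + Hh %*% P[[paste0(p, "W2")]] + matrix(P[[paste0(p, "b2")]],
                                                    n, d, byrow = TRUE)
    if (cache)
      caches[[l]] <- list(X = X, ln1 = ln1, A = A, heads = heads, O = O,
                          X1 = X1, ln2 = ln2, B = B, Z = Z, Hh = Hh)
    hidden[[l]] <- X2
    attnRecv[[l]] <- recv / nh
    X <- X2
  }
  lnf <- .layerNormF(X, P$lnf.g, P$lnf.b)
  out <- list(hidden = lnf$Y, XL = X)
  if (cache) {
    out$caches <- caches
    out$lnf <- lnf
    out$hiddenStates <- hidden
    out$attnRecv <- attnRecv
    out$ids <- ids
    out$rot <- rot
    out$fromLayer <- fromLayer
  }
  out
}

#' MLM logits for one tokenized input
#'
#' Runs the encoder over the real (non-pad) tokens and applies the MLM
#' head.
#'
#' @param model an [AbEncoder-class].
#' @param ids integer token ids (pads should be trimmed by the caller).
#' @return matrix of logits, `length(ids)` x vocabulary size.
#' @export
mlmLogits <- function(model, ids) {
  fw <- .encoderForward(model, ids)
  fw$hidden %*% model@params$mlm.W +
    matrix(model@params$mlm.b, length(ids), length(model@vocab@tokens),
           byrow = TRUE)
}
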