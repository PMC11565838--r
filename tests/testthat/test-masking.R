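# Masking-probability matrices, dynamic selection and 80/10/10 corruption.

test_that("preferential matrices hit the CDR3 rate and preserve the mean", {
  # Identity checked over many synthetic compositions: CDR3 positions get
  # exactly the CDR3 rate and the residue-position mean equals the base
  # rate whenever the CDR3 fraction is below base/cdr3.
  params <- maskingParams("preferential")
  for (tok in smallTokens()[1:20]) {
    pr <- maskingProbs(tok, params)
    residue <- tok@chainOfToken != "special"
    cdr3 <- residue & tok@tokenRegions == "CDR3"
    expect_lt(pr@cdr3Fraction, 0.6)
    expect_true(all(pr@probs[cdr3] == 0.25))
    expect_equal(mean(pr@probs[residue]), 0.15, tolerance = 1e-12)
    expect_true(all(pr@probs[!residue] == 0))
  }
})

test_that("uniform matrices are constant at the base rate", {
  params <- maskingParams("uniform")
  tok <- smallTokens()[[1]]
  pr <- maskingProbs(tok, params)
  residue <- tok@chainOfToken != "special"
  expect_true(all(pr@probs[residue] == 0.15))
  expect_true(all(pr@probs[!residue] == 0))
})

test_that("compensated rate matches the closed form on a hand case", {
  # 4 CDR3 residues out of 10: compensated rate (0.15 - 0.25*0.4)/0.6
  hm <- regionMask(c(rep("FR1", 4), rep("CDR3", 4)), "truth")
  lm <- regionMask(c("FR1", "FR1"), "truth")
  tok <- encodePair("ACDEFGHI", "KL", maxLen = 16, heavyMask = hm,
                    lightMask = lm)
  pr <- maskingProbs(tok, maskingParams("preferential"))
  expect_equal(pr@cdr3Fraction, 0.4)
  comp <- (0.15 - 0.25 * 0.4) / 0.6
  nonCDR3 <- tok@chainOfToken != "special" & tok@tokenRegions != "CDR3"
  expect_equal(unique(pr@probs[nonCDR3]), comp)
})

test_that("excessive CDR3 fraction clamps with a warning; p = 1 errors", {
  # 8 of 10 residues in CDR3: p > 0.6, compensated rate would be negative
  hm <- regionMask(c(rep("FR1", 2), rep("CDR3", 8)), "truth")
  lm <- regionMask(rep("CDR3", 2), "truth")
  tok <- encodePair("ACDEFGHIKL", "MN", maxLen = 20, heavyMask = hm,
                    lightMask = lm)
  expect_warning(pr <- maskingProbs(tok, maskingParams("preferential")),
                 "clamping")
  residue <- tok@chainOfToken != "special"
  expect_true(all(pr@probs[residue & tok@tokenRegions != "CDR3"] == 0))
  # every residue in CDR3 is degenerate
  hm2 <- regionMask(rep("CDR3", 3), "truth")
  lm2 <- regionMask(rep("CDR3", 2), "truth")
  tok2 <- encodePair("ACD", "EF", maxLen = 12, heavyMask = hm2,
                     lightMask = lm2)
  expect_error(maskingProbs(tok2, maskingParams("preferential")),
               "degenerate")
})

test_that("drawSelection follows the probability matrix", {
  # [DERIVED: binomial oracle] pooled selection rate at CDR3 positions
  # within the 99% CI of 0.25 over many draws.
  tok <- smallTokens()[[1]]
  pr <- maskingProbs(tok, maskingParams("preferential"))
  cdr3 <- tok@chainOfToken != "special" & tok@tokenRegions == "CDR3"
  set.seed(77)
  hits <- 0; total <- 0
  for (i in 1:500) {
    sel <- drawSelection(pr)
    hits <- hits + sum(sel[cdr3])
    total <- total + sum(cdr3)
  }
  ci <- qbinom(c(0.005, 0.995), total, 0.25) / total
  expect_gte(hits / total, ci[1])
  expect_lte(hits / total, ci[2])
  # pads are never selected
  pads <- tok@attentionFlags == 0L
  sel <- drawSelection(pr)
  expect_true(all(sel[pads] == 0L))
})

test_that("corruptTokens applies the 80/10/10 split within binomial CIs", {
  # [DERIVED: binomial oracle] over >= 10^4 selected positions.
  v <- aaVocabulary()
  params <- maskingParams("preferential")
  maskId <- 2L
  set.seed(11)
  toks <- smallTokens()
  nMask <- 0; nRand <- 0; nKeep <- 0; nSel <- 0
  while (nSel < 12000) {
    for (tok in toks) {
      pr <- maskingProbs(tok, params)
      sel <- drawSelection(pr)
      batch <- corruptTokens(tok, sel, params, v)
      ids <- batch@corruptedIds[1, ]
      orig <- tok@tokenIds
      s <- which(sel == 1L)
      nSel <- nSel + length(s)
      nMask <- nMask + sum(ids[s] == maskId)
      changed <- ids[s] != orig[s] & ids[s] != maskId
      nRand <- nRand + sum(changed)
      nKeep <- nKeep + sum(ids[s] == orig[s])
    }
  }
  ciMask <- qbinom(c(0.005, 0.995), nSel, 0.8) / nSel
  expect_gte(nMask / nSel, ciMask[1])
  expect_lte(nMask / nSel, ciMask[2])
  # a random replacement can coincide with the original (1/21 of draws),
  # so "visibly random" and "kept" fractions shift by that overlap:
  # P(visible random) = 0.1 * 20/21, P(looks kept) = 0.1 + 0.1/21.
  pRand <- 0.1 * 20 / 21
  ciRand <- qbinom(c(0.005, 0.995), nSel, pRand) / nSel
  expect_gte(nRand / nSel, ciRand[1])
  expect_lte(nRand / nSel, ciRand[2])
  pKeep <- 0.1 + 0.1 / 21
  ciKeep <- qbinom(c(0.005, 0.995), nSel, pKeep) / nSel
  expect_gte(nKeep / nSel, ciKeep[1])
  expect_lte(nKeep / nSel, ciKeep[2])
})

test_that("corruptTokens labels carry originals exactly at selections", {
  v <- aaVocabulary()
  tok <- smallTokens()[[2]]
  pr <- maskingProbs(tok, maskingParams("preferential"))
  set.seed(3)
  sel <- drawSelection(pr)
  batch <- corruptTokens(tok, sel, maskingParams("preferential"), v)
  lab <- batch@labels[1, ]
  s <- which(sel == 1L)
  expect_identical(which(!is.na(lab)), s)
  expect_identical(lab[s], tok@tokenIds[s])
  # unselected positions are untouched
  expect_identical(batch@corruptedIds[1, -s], tok@tokenIds[-s])
})

test_that("random replacements come from residue tokens only by default", {
  v <- aaVocabulary()
  params <- maskingParams("preferential", maskFrac = 0, randomFrac = 1,
                          keepFrac = 0)
  tok <- smallTokens()[[3]]
  sel <- as.integer(tok@chainOfToken != "special")
  set.seed(5)
  batch <- corruptTokens(tok, sel, params, v)
  replaced <- batch@corruptedIds[1, sel == 1L]
  expect_true(all(replaced %in% residueTokenIds(v)))
  # wholeVocab = TRUE eventually samples special ids too
  seen <- integer(0)
  for (i in 1:30) {
    b <- corruptTokens(tok, sel, params, v, wholeVocab = TRUE)
    seen <- union(seen, b@corruptedIds[1, sel == 1L])
  }
  expect_true(any(seen %in% 1:5))
})

test_that("the collator is reproducible per (epoch, batch) and dynamic", {
  v <- aaVocabulary()
  params <- maskingParams("preferential")
  toks <- smallTokens()[1:4]
  probs <- precomputeProbs(toks, params)
  collate <- mlmCollator(params, v, seed = 99)
  b1 <- collate(toks, probs, epoch = 1, batch = 1)
  b1again <- collate(toks, probs, epoch = 1, batch = 1)
  expect_identical(b1@corruptedIds, b1again@corruptedIds)
  expect_identical(b1@labels, b1again@labels)
  b2 <- collate(toks, probs, epoch = 2, batch = 1)
  expect_false(identical(b1@selection, b2@selection))  # dynamic masking
  # the collator leaves the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(collate(toks, probs, 3, 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("precomputed matrices persist and reload byte-identically", {
  params <- maskingParams("preferential")
  toks <- smallTokens()[1:5]
  path <- tempfile(fileext = ".rds")
  probs <- precomputeProbs(toks, params, path = path)
  reloaded <- loadProbs(path)
  expect_identical(lapply(probs, slot, "probs"),
                   lapply(reloaded, slot, "probs"))
  unlink(path)
})

test_that("maskRateReport shows elevated CDR3 and compensated rest", {
  params <- maskingParams("preferential")
  toks <- smallTokens()
  probs <- precomputeProbs(toks, params)
  rpt <- maskRateReport(toks, probs)
  expect_equal(rpt$expectedRate[rpt$region == "CDR3"], 0.25)
  frRows <- grepl("^FR", rpt$region)
  expect_true(all(rpt$expectedRate[frRows] < 0.15))
})

test_that("masking parameter validity is enforced", {
  expect_error(maskingParams(maskFrac = 0.5, randomFrac = 0.1,
                             keepFrac = 0.1), "sum to 1")
  expect_error(maskingParams(baseRate = 1.5), "probabilities")
})
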