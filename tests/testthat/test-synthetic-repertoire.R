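# Generator: germline library, V(D)J recombination, SHM, repertoire I/O.

test_that("germline library is deterministic and structurally valid", {
  libA <- buildGermlineLibrary(seed = 7, nV = 5, nD = 3, nJ = 4)
  libB <- buildGermlineLibrary(seed = 7, nV = 5, nD = 3, nJ = 4)
  expect_identical(libA@heavy, libB@heavy)
  expect_identical(libA@light, libB@light)
  libC <- buildGermlineLibrary(seed = 8, nV = 5, nD = 3, nJ = 4)
  expect_false(identical(libA@heavy, libC@heavy))
  expect_length(libA@heavy$V, 5)
  expect_length(libA@heavy$D, 3)
  expect_length(libA@heavy$J, 4)
  expect_null(libA@light$D)
  # V segments end in the CDR3 left flank, J segments start in CDR3
  v <- libA@heavy$V[[1]]
  expect_identical(names(v$boundaries),
                   c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3"))
  j <- libA@heavy$J[[1]]
  expect_identical(names(j$boundaries), c("CDR3", "FR4"))
  # boundaries are 0-based half-open and tile each segment (validity
  # enforces this; spot-check one segment by hand)
  ends <- vapply(v$boundaries, `[`, numeric(1), 2)
  expect_identical(unname(ends[length(ends)]), as.numeric(nchar(v$residues)))
})

test_that("library frameworks are strongly conserved, D segments random", {
  lib <- buildGermlineLibrary(seed = 3, nV = 8, nD = 3, nJ = 4)
  frSpan <- function(seg) {
    b <- seg$boundaries$FR1
    substr(seg$residues, b[1] + 1, b[2])
  }
  fr1s <- vapply(lib@heavy$V, frSpan, character(1))
  cons <- paste(lib@consensus$heavy$FR1, collapse = "")
  frMatch <- mean(vapply(fr1s, function(s)
    mean(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]]), numeric(1)))
  expect_gt(frMatch, 0.85)  # built with per-position copy probability 0.97
  dLens <- vapply(lib@heavy$D, function(d) nchar(d$residues), numeric(1))
  expect_true(all(dLens >= 3 & dLens <= 5))
})

test_that("applySHM respects rates: binomial oracle at cdrBias = 1", {
  # [DERIVED: binomial oracle] With cdrBias = 1 every residue mutates
  # independently at shmRate, so the pooled mutated fraction over N
  # residues lies in the binomial 99% CI around 0.05.
  lib <- buildGermlineLibrary(seed = 5)
  seg <- lib@heavy$V[[1]]
  mask <- regionMask(unlist(Map(
    function(nm, b) rep(sub("FLANK.*", "CDR3", nm), b[2] - b[1]),
    names(seg$boundaries), seg$boundaries)), "truth")
  n <- nchar(seg$residues)
  rate <- 0.05
  reps <- 300L
  set.seed(42)
  hits <- vapply(seq_len(reps), function(i)
    applySHM(seg$residues, mask, rate, cdrBias = 1)$count, numeric(1))
  total <- n * reps
  ci <- qbinom(c(0.005, 0.995), total, rate) / total
  frac <- sum(hits) / total
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("applySHM concentrates mutations in CDRs by cdrBias", {
  # [DERIVED: binomial ratio oracle] empirical CDR:FR rate ratio converges
  # to cdrBias.
  labels <- c(rep("FR1", 500), rep("CDR1", 500))
  residues <- paste(rep("A", 1000), collapse = "")
  mask <- regionMask(labels, "truth")
  set.seed(9)
  cdrHits <- 0; frHits <- 0
  for (i in 1:200) {
    out <- applySHM(residues, mask, 0.02, cdrBias = 4)
    chars <- strsplit(out$residues, "")[[1]]
    frHits <- frHits + sum(chars[1:500] != "A")
    cdrHits <- cdrHits + sum(chars[501:1000] != "A")
  }
  ratio <- cdrHits / frHits
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("applySHM trivial and error cases", {
  mask <- regionMask(rep("FR1", 5), "truth")
  out <- applySHM("ACDEF", mask, 0)
  expect_identical(out$residues, "ACDEF")  # [TRIVIAL]
  expect_identical(out$count, 0L)
  expect_error(applySHM("ACDEF", mask, 0.5, cdrBias = 3),
               "must not exceed 1")
})

test_that("generated repertoires satisfy the structural invariants", {
  config <- generatorConfig(nPairs = 120, donors = 4, naiveFraction = 0.5,
                            junctionLengthRange = c(2L, 8L), seed = 13)
  rep <- generateRepertoire(config)
  expect_s4_class(rep, "PairedRepertoire")
  expect_identical(nrow(rep), 120L)
  # determinism
  rep2 <- generateRepertoire(config)
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
  # region columns tile each chain (regionMaskOf errors otherwise)
  for (i in c(1, 60, 120)) {
    hm <- regionMaskOf(rep, i, "heavy")
    expect_identical(paste(rle(hm@labels)$values, collapse = "-"),
                     "FR1-CDR1-FR2-CDR2-FR3-CDR3-FR4")
    lm <- regionMaskOf(rep, i, "light")
    expect_identical(length(lm@labels), nchar(rep$light_sequence[i]))
  }
  # naive <=> unmutated (generator convention); memory has >= 1 mutation
  # per chain
  naive <- rep$cell_type == "naive"
  expect_true(all(rep$heavy_mutations[naive] == 0))
  expect_true(all(rep$light_mutations[naive] == 0))
  expect_true(all(rep$heavy_mutations[!naive] >= 1))
  expect_true(all(rep$light_mutations[!naive] >= 1))
  # heavy CDR3 = 3 flank + insertion(2..8) + D(3..5) + 3 flank
  cdr3Len <- nchar(rep$heavy_cdr3)
  expect_true(all(cdr3Len >= 3 + 2 + 3 + 3 & cdr3Len <= 3 + 8 + 5 + 3))
  # light CDR3 has no D segment
  lightLen <- nchar(rep$light_cdr3)
  expect_true(all(lightLen >= 3 + 2 + 3 & lightLen <= 3 + 8 + 3))
  expect_setequal(unique(rep$donor), paste0("donor", 1:4))
})

test_that("naiveFraction is honoured in expectation", {
  # [DERIVED: binomial oracle] naive count within the 99% CI of
  # Binomial(400, 0.3).
  rep <- generateRepertoire(generatorConfig(nPairs = 400,
                                            naiveFraction = 0.3, seed = 21))
  nNaive <- sum(rep$cell_type == "naive")
  ci <- qbinom(c(0.005, 0.995), 400, 0.3)
  expect_gte(nNaive, ci[1])
  expect_lte(nNaive, ci[2])
})

test_that("plantSpecificityMotif plants the motif only in positives", {
  rep <- smallRepertoire()
  planted <- plantSpecificityMotif(rep, motif = "WGDYRA", fraction = 0.5,
                                   seed = 5)
  pos <- planted$specificity_label == "positive"
  expect_identical(sum(pos), as.integer(round(0.5 * nrow(rep))))
  expect_true(all(substr(planted$heavy_cdr3[pos], 4, 9) == "WGDYRA"))
  # negatives untouched
  expect_identical(planted$heavy_sequence[!pos], rep$heavy_sequence[!pos])
  # the full chain agrees with the region columns after planting
  for (i in which(pos)[1:3]) {
    hm <- regionMaskOf(planted, i, "heavy")
    expect_identical(length(hm@labels), nchar(planted$heavy_sequence[i]))
  }
})

test_that("AIRR TSV round trip preserves the repertoire", {
  rep <- smallRepertoire()
  path <- tempfile(fileext = ".tsv")
  writeAIRR(rep, path)
  back <- readAIRR(path)
  expect_identical(as.data.frame(back), as.data.frame(rep))
  unlink(path)
})

test_that("generator configuration rejects invalid parameters", {
  expect_error(generatorConfig(naiveFraction = 1.5), "probability")
  expect_error(generatorConfig(cdrBias = 0.5), ">= 1")
  expect_error(generatorConfig(junctionLengthRange = c(5L, 2L)), "min")
})
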