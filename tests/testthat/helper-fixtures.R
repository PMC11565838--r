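# Shared fixtures, memoised so expensive objects are built at most once
# per test run regardless of which test file asks first.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(build), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# A small clean repertoire plus its tokenized form, reused across files.
smallRepertoire <- function() {
  fixture("smallRep", generateRepertoire(generatorConfig(nPairs = 60,
                                                         seed = 101)))
}

smallTokens <- function() {
  fixture("smallToks", tokenizeRepertoire(smallRepertoire()))
}

# Desk-scale MLM training preset used by the method-property tests: one
# base repertoire, 300 training / 40 validation pairs, 250 Adam steps.
# Models are cached per (strategy, seed) because criteria share them.
.acceptTrainConfig <- function(seed) {
  list(batchSize = 8L, totalSteps = 250L, peakLR = 2e-3, warmupSteps = 25L,
       evalEvery = 25L, seed = seed, evalSeed = 999L)
}

acceptRepertoire <- function() {
  fixture("acceptRep", generateRepertoire(generatorConfig(nPairs = 340,
                                                          seed = 11)))
}

acceptRecords <- function(strategy) {
  fixture(paste0("acceptRecords.", strategy), {
    toks <- tokenizeRepertoire(acceptRepertoire())
    params <- maskingParams(strategy)
    list(train = prepareMLMData(toks[1:300], params),
         val = prepareMLMData(toks[301:340], params),
         params = params)
  })
}

trainedBase <- function(strategy, seed) {
  fixture(sprintf("base.%s.%d", strategy, seed), {
    data <- acceptRecords(strategy)
    model <- buildEncoder(encoderConfig(), seed = 42L + seed)
    trainMLM(model, data$train, data$val, data$params,
             config = .acceptTrainConfig(seed))
  })
}

# Planted-motif specificity task shared by the attribution study. The
# germline background is a single V/D/J allele per chain with no somatic
# mutation, so the junction is the only variable segment and the planted
# heavy-CDR3 motif is the only class-discriminative signal; any
# concentration elsewhere would be an attribution artifact.
specTask <- function() {
  fixture("specTask", {
    lib1 <- buildGermlineLibrary(seed = 77, nV = 1, nD = 1, nJ = 1)
    spec <- generateRepertoire(generatorConfig(nPairs = 360,
                                               naiveFraction = 1,
                                               seed = 77), library = lib1)
    spec <- plantSpecificityMotif(spec, motif = "WGDYRA", seed = 77)
    toks <- tokenizeRepertoire(spec)
    list(records = prepareMLMData(toks, maskingParams("uniform")),
         labels = spec$specificity_label)
  })
}
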