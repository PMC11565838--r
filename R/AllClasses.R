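#' @include abmlm-package.R
NULL

#' Germline segment library
#'
#' Container for a synthetic library of germline V, D and J segments for
#' heavy and light chains. Each segment is a list with elements `name`,
#' `chain` ("heavy"/"light"), `segmentClass` ("V"/"D"/"J"), `residues`
#' (amino-acid string) and `boundaries` (a named list of 0-based, half-open
#' `c(start, end)` spans labelling the regions encoded by the segment).
#' D segments exist only for the heavy chain, mirroring V(D)J biology.
#'
#' @slot heavy list with elements `V`, `D`, `J`, each a list of segments.
#' @slot light list with elements `V`, `J`.
#' @slot consensus list of per-chain consensus profiles used at build time.
#' @slot seed integer seed the library was built from.
#' @exportClass GermlineLibrary
setClass("GermlineLibrary",
  representation(heavy = "list", light = "list",
                 consensus = "list", seed = "integer"))

.validSegment <- function(seg) {
  if (!all(strsplit(seg$residues, "")[[1]] %in% AA20))
    return(sprintf("segment %s contains non-canonical residues", seg$name))
  b <- seg$boundaries
  ends <- vapply(b, `[`, numeric(1), 2)
  starts <- vapply(b, `[`, numeric(1), 1)
  if (starts[1] != 0 || any(starts[-1] != ends[-length(ends)]) ||
      ends[length(ends)] != nchar(seg$residues))
    return(sprintf("segment %s: region boundaries do not tile the segment",
                   seg$name))
  TRUE
}

setValidity("GermlineLibrary", function(object) {
  if (length(object@light$D %||% list()) > 0)
    return("light chain libraries must not contain D segments")
  for (segs in c(object@heavy[c("V", "D", "J")], object@light[c("V", "J")]))
    for (seg in segs) {
      ok <- .validSegment(seg)
      if (!isTRUE(ok)) return(ok)
    }
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "GermlineLibrary", function(object) {
  cat("GermlineLibrary (seed ", object@seed, ")\n",
      "  heavy: ", length(object@heavy$V), " V, ",
      length(object@heavy$D), " D, ", length(object@heavy$J), " J\n",
      "  light: ", length(object@light$V), " V, ",
      length(object@light$J), " J\n", sep = "")
})

#' Per-residue region mask
#'
#' Categorical labels (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4) for every
#' residue of one chain, either emitted by the generator (`source =
#' "truth"`) or reconstructed by semi-global alignment (`source =
#' "aligned"`).
#'
#' @slot labels character vector, one region label per residue.
#' @slot source either "truth" or "aligned".
#' @exportClass RegionMask
setClass("RegionMask",
  representation(labels = "character", source = "character"))

setValidity("RegionMask", function(object) {
  if (!object@source %in% c("truth", "aligned"))
    return("source must be 'truth' or 'aligned'")
  if (!all(object@labels %in% REGION_LEVELS))
    return("labels must be FR1/CDR1/FR2/CDR2/FR3/CDR3/FR4")
  runs <- rle(object@labels)$values
  if (anyDuplicated(runs))
    return("region labels must form contiguous runs in canonical order")
  if (!identical(runs, REGION_LEVELS[REGION_LEVELS %in% runs]))
    return("region labels out of canonical order")
  TRUE
})

#' @rdname RegionMask-class
#' @param labels character vector of region labels.
#' @param source label provenance, "truth" or "aligned".
#' @return A [RegionMask-class] object.
#' @export
regionMask <- function(labels, source = "truth") {
  new("RegionMask", labels = as.character(labels), source = source)
}

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask (", object@source, "), length ", length(object@labels),
      ": ", paste(rle(object@labels)$values, collapse = "-"), "\n", sep = "")
})

#' Paired antibody repertoire
#'
#' A `DataFrame`-backed table of paired heavy/light chains with per-region
#' subsequences, donor and cell-type metadata and per-chain somatic
#' mutation counts. Region masks for each record are recoverable from the
#' region subsequence columns via [regionMaskOf()].
#'
#' @exportClass PairedRepertoire
setClass("PairedRepertoire", contains = "DFrame")

.AIRR_REGION_COLS <- as.vector(outer(c("heavy", "light"),
  c("fwr1", "cdr1", "fwr2", "cdr2", "fwr3", "cdr3", "fwr4"),
  paste, sep = "_"))

.AIRR_COLS <- c("sequence_id", "donor", "cell_type",
                "heavy_sequence", "light_sequence", .AIRR_REGION_COLS,
                "heavy_mutations", "light_mutations",
                "pair_label", "specificity_label")

setValidity("PairedRepertoire", function(object) {
  miss <- setdiff(.AIRR_COLS, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(object$heavy_mutations < 0) || any(object$light_mutations < 0))
    return("mutation counts must be non-negative")
  bad <- !object$cell_type %in% c("naive", "memory")
  if (any(bad)) return("cell_type must be 'naive' or 'memory'")
  TRUE
})

#' @rdname PairedRepertoire-class
#' @param df a `data.frame` or `DataFrame` with the repertoire columns.
#' @return A [PairedRepertoire-class].
#' @export
PairedRepertoire <- function(df) {
  df <- as(as.data.frame(df, stringsAsFactors = FALSE), "DFrame")
  for (col in c("pair_label", "specificity_label"))
    if (!col %in% colnames(df)) df[[col]] <- NA_character_
  new("PairedRepertoire", df[, .AIRR_COLS, drop = FALSE])
}

setMethod("show", "PairedRepertoire", function(object) {
  cat("PairedRepertoire with ", nrow(object), " pairs, ",
      length(unique(object$donor)), " donor(s); ",
      sum(object$cell_type == "naive"), " naive / ",
      sum(object$cell_type == "memory"), " memory\n", sep = "")
})

#' Token vocabulary
#'
#' The 26-token amino-acid vocabulary: five special tokens (`<pad>`,
#' `<mask>`, `<unk>`, `<cls>`, `<eos>`), the 20 canonical amino acids in
#' alphabetical order, and `X` for non-canonical residues.
#'
#' @slot tokens ordered character vector of length 26.
#' @exportClass Vocabulary
setClass("Vocabulary", representation(tokens = "character"))

setValidity("Vocabulary", function(object) {
  if (length(object@tokens) != 26) return("vocabulary must have 26 tokens")
  if (anyDuplicated(object@tokens)) return("tokens must be unique")
  TRUE
})

#' Tokenized paired-chain input
#'
#' Fixed-length token-id encoding of one heavy/light pair in the layout
#' `<cls> HEAVY <cls> <cls> LIGHT <eos>` followed by `<pad>` up to
#' `maxLen`. Ids are 1-based indices into the [Vocabulary-class].
#'
#' @slot tokenIds integer vector of length `maxLen`.
#' @slot attentionFlags integer vector, 1 at real tokens, 0 at pads.
#' @slot tokenRegions character vector over region labels or "NONE".
#' @slot chainOfToken character vector over "heavy", "light", "special".
#' @exportClass TokenizedPair
setClass("TokenizedPair",
  representation(tokenIds = "integer", attentionFlags = "integer",
                 tokenRegions = "character", chainOfToken = "character"))

setValidity("TokenizedPair", function(object) {
  n <- length(object@tokenIds)
  if (length(object@attentionFlags) != n ||
      length(object@tokenRegions) != n ||
      length(object@chainOfToken) != n)
    return("all slots must have equal length")
  if (!all(object@tokenRegions %in% c(REGION_LEVELS, "NONE")))
    return("invalid region label")
  if (!all(object@chainOfToken %in% c("heavy", "light", "special")))
    return("invalid chain label")
  if (any(object@tokenRegions[object@chainOfToken == "special"] != "NONE"))
    return("special and pad positions must carry region NONE")
  TRUE
})

setMethod("show", "TokenizedPair", function(object) {
  cat("TokenizedPair: ", sum(object@attentionFlags), " real tokens / ",
      length(object@tokenIds), " total\n", sep = "")
})

#' Masking parameters
#'
#' Parameters of the masking strategy: the sequence-average masking rate,
#' the elevated CDR3 rate used by preferential masking, and the
#' mask/random/keep corruption split applied to selected tokens.
#'
#' @slot baseRate average per-residue masking probability (default 0.15).
#' @slot cdr3Rate CDR3 masking probability under the preferential
#'   strategy (default 0.25).
#' @slot maskFrac,randomFrac,keepFrac corruption split (0.8/0.1/0.1).
#' @slot strategy "uniform" or "preferential".
#' @exportClass MaskingParams
setClass("MaskingParams",
  representation(baseRate = "numeric", cdr3Rate = "numeric",
                 maskFrac = "numeric", randomFrac = "numeric",
                 keepFrac = "numeric", strategy = "character"))

setValidity("MaskingParams", function(object) {
  p <- c(object@baseRate, object@cdr3Rate, object@maskFrac,
         object@randomFrac, object@keepFrac)
  if (any(p < 0 | p > 1)) return("all probabilities must lie in [0, 1]")
  if (abs(object@maskFrac + object@randomFrac + object@keepFrac - 1) > 1e-12)
    return("mask/random/keep fractions must sum to 1")
  if (!object@strategy %in% c("uniform", "preferential"))
    return("strategy must be 'uniform' or 'preferential'")
  TRUE
})

#' @rdname MaskingParams-class
#' @param baseRate,cdr3Rate,maskFrac,randomFrac,keepFrac,strategy see slots.
#' @return A [MaskingParams-class].
#' @export
maskingParams <- function(strategy = c("preferential", "uniform"),
                          baseRate = 0.15, cdr3Rate = 0.25,
                          maskFrac = 0.8, randomFrac = 0.1,
                          keepFrac = 0.1) {
  new("MaskingParams", baseRate = baseRate, cdr3Rate = cdr3Rate,
      maskFrac = maskFrac, randomFrac = randomFrac, keepFrac = keepFrac,
      strategy = match.arg(strategy))
}

setMethod("show", "MaskingParams", function(object) {
  cat("MaskingParams: ", object@strategy, ", base ", object@baseRate,
      ", CDR3 ", object@cdr3Rate, ", split ", object@maskFrac, "/",
      object@randomFrac, "/", object@keepFrac, "\n", sep = "")
})

#' Per-token masking probabilities
#'
#' The masking-probability vector aligned to one [TokenizedPair-class],
#' together with the CDR3 residue fraction that parameterizes the
#' preferential compensation.
#'
#' @slot probs numeric vector of per-token masking probabilities.
#' @slot cdr3Fraction fraction of residue tokens labelled CDR3.
#' @slot strategy the strategy the matrix was built under.
#' @exportClass MaskingProbs
setClass("MaskingProbs",
  representation(probs = "numeric", cdr3Fraction = "numeric",
                 strategy = "character"))

setValidity("MaskingProbs", function(object) {
  if (any(object@probs < 0 | object@probs > 1))
    return("probabilities must lie in [0, 1]")
  TRUE
})

setMethod("show", "MaskingProbs", function(object) {
  cat("MaskingProbs (", object@strategy, "): p^CDR3 = ",
      round(object@cdr3Fraction, 4), ", residue mean = ",
      round(mean(object@probs[object@probs > 0]), 4), "\n", sep = "")
})

#' Corrupted MLM batch
#'
#' One or more corrupted token-id rows plus prediction labels. Labels hold
#' the original token id at selected positions and `NA` (the ignore
#' sentinel) elsewhere; `corruptedIds` equal the originals wherever
#' `selection` is 0.
#'
#' @slot corruptedIds integer matrix (records x positions).
#' @slot labels integer matrix with `NA` at unselected positions.
#' @slot selection binary integer matrix of predicted positions.
#' @exportClass MLMBatch
setClass("MLMBatch",
  representation(corruptedIds = "matrix", labels = "matrix",
                 selection = "matrix"))

setValidity("MLMBatch", function(object) {
  if (!identical(dim(object@corruptedIds), dim(object@labels)) ||
      !identical(dim(object@labels), dim(object@selection)))
    return("corruptedIds, labels and selection must share dimensions")
  if (!identical(which(!is.na(object@labels)), which(object@selection == 1L)))
    return("labels must be non-NA exactly at selected positions")
  TRUE
})

setMethod("show", "MLMBatch", function(object) {
  cat("MLMBatch: ", nrow(object@corruptedIds), " record(s), ",
      sum(object@selection), " selected positions\n", sep = "")
})

#' Greedy clustering result
#'
#' @slot representativeOf named character vector mapping each record id to
#'   its cluster representative.
#' @slot clusters named list mapping representatives to member ids.
#' @slot threshold identity threshold used.
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  representation(representativeOf = "character", clusters = "list",
                 threshold = "numeric"))

setValidity("ClusteringResult", function(object) {
  reps <- names(object@clusters)
  if (!all(object@representativeOf[reps] == reps))
    return("representatives must map to themselves")
  if (!setequal(unlist(object@clusters), names(object@representativeOf)))
    return("clusters must cover exactly the mapped records")
  TRUE
})

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult: ", length(object@representativeOf), " records in ",
      length(object@clusters), " clusters (threshold ",
      object@threshold, ")\n", sep = "")
})

#' Split or fold assignment
#'
#' @slot assignment character (train/validation/test) or integer (fold
#'   index) vector, named by record id when ids are available.
#' @slot seed integer seed used for the permutation.
#' @exportClass SplitAssignment
setClass("SplitAssignment",
  representation(assignment = "vector", seed = "integer"))

setMethod("show", "SplitAssignment", function(object) {
  tb <- table(object@assignment)
  cat("SplitAssignment (seed ", object@seed, "): ",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
})

#' Transformer encoder configuration
#'
#' @slot nLayers,nHeads,hiddenSize,intermediateSize architecture integers.
#' @slot useRotary use rotary position embeddings.
#' @slot maxLen maximum input length.
#' @exportClass EncoderConfig
setClass("EncoderConfig",
  representation(nLayers = "integer", nHeads = "integer",
                 hiddenSize = "integer", intermediateSize = "integer",
                 useRotary = "logical", maxLen = "integer"))

setValidity("EncoderConfig", function(object) {
  if (object@hiddenSize %% object@nHeads != 0)
    return("hiddenSize must be divisible by nHeads")
  if ((object@hiddenSize / object@nHeads) %% 2 != 0 && object@useRotary)
    return("per-head size must be even for rotary embeddings")
  TRUE
})

#' @rdname EncoderConfig-class
#' @param nLayers,nHeads,hiddenSize,intermediateSize,useRotary,maxLen see
#'   slots. The desk-scale preset is (2, 4, 64, 128); the full-scale preset
#'   (32, 20, 960, 3840) is expressible but not exercised by the tests.
#' @return An [EncoderConfig-class].
#' @export
encoderConfig <- function(nLayers = 2L, nHeads = 4L, hiddenSize = 64L,
                          intermediateSize = 128L, useRotary = TRUE,
                          maxLen = 320L) {
  new("EncoderConfig", nLayers = as.integer(nLayers),
      nHeads = as.integer(nHeads), hiddenSize = as.integer(hiddenSize),
      intermediateSize = as.integer(intermediateSize),
      useRotary = useRotary, maxLen = as.integer(maxLen))
}

setMethod("show", "EncoderConfig", function(object) {
  cat("EncoderConfig: ", object@nLayers, " layers, ", object@nHeads,
      " heads, hidden ", object@hiddenSize, ", intermediate ",
      object@intermediateSize, if (object@useRotary) ", rotary" else "",
      "\n", sep = "")
})

#' Transformer encoder MLM
#'
#' A pre-layer-norm transformer encoder with rotary position embeddings
#' and a masked-language-model head over the 26-token vocabulary.
#' Parameters live in a flat named list of matrices/vectors.
#'
#' @slot config an [EncoderConfig-class].
#' @slot params named list of parameter arrays.
#' @slot vocab the [Vocabulary-class] the model embeds.
#' @slot seed initialization seed.
#' @exportClass AbEncoder
setClass("AbEncoder",
  representation(config = "EncoderConfig", params = "list",
                 vocab = "Vocabulary", seed = "integer"))

setMethod("show", "AbEncoder", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat("AbEncoder: ", object@config@nLayers, " layers, hidden ",
      object@config@hiddenSize, ", ", format(np, big.mark = ","),
      " parameters (seed ", object@seed, ")\n", sep = "")
})

#' AttCAT attribution result
#'
#' @slot rawScores per-token impact scores (pads excluded).
#' @slot normalizedScores standard-scaled scores.
#' @slot targetClass the class the scores explain (1 or 2).
#' @slot perRegionSummary data.frame of mean |score| by region and chain.
#' @slot tokens the token strings the scores align to.
#' @exportClass AttributionResult
setClass("AttributionResult",
  representation(rawScores = "numeric", normalizedScores = "numeric",
                 targetClass = "integer", perRegionSummary = "data.frame",
                 tokens = "character"))

setMethod("show", "AttributionResult", function(object) {
  top <- object@perRegionSummary
  top <- top[order(-top$meanAbsScore), , drop = FALSE]
  cat("AttributionResult (class ", object@targetClass, "), ",
      length(object@rawScores), " tokens; top region: ",
      top$chain[1], " ", top$region[1], "\n", sep = "")
})
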