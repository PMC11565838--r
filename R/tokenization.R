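#' @include AllClasses.R
NULL

#' The 26-token amino-acid vocabulary
#'
#' Five special tokens first, then the 20 canonical amino acids in
#' alphabetical order, then `X` for non-canonical residues. Token ids are
#' 1-based positions in this fixed order.
#'
#' @return A [Vocabulary-class].
#' @examples
#' v <- aaVocabulary()
#' length(v@tokens)  # 26
#' @export
aaVocabulary <- function() {
  new("Vocabulary",
      tokens = c("<pad>", "<mask>", "<unk>", "<cls>", "<eos>", AA20, "X"))
}

#' @rdname aaVocabulary
#' @param vocab a [Vocabulary-class].
#' @param tokens character vector of token strings.
#' @return `tokenId` returns integer ids; unknown strings map to `<unk>`.
#' @export
tokenId <- function(vocab, tokens) {
  id <- match(tokens, vocab@tokens)
  id[is.na(id)] <- match("<unk>", vocab@tokens)
  id
}

#' @rdname aaVocabulary
#' @param ids integer token ids.
#' @export
tokenOf <- function(vocab, ids) vocab@tokens[ids]

.specialIds <- function(vocab) {
  setNames(match(c("<pad>", "<mask>", "<unk>", "<cls>", "<eos>"),
                 vocab@tokens),
           c("pad", "mask", "unk", "cls", "eos"))
}

#' Residue (non-special) token ids
#'
#' The 21 ids available as masked-prediction targets and random
#' replacements: the 20 canonical amino acids plus `X`.
#'
#' @param vocab a [Vocabulary-class].
#' @return integer vector of ids.
#' @export
residueTokenIds <- function(vocab) {
  which(!vocab@tokens %in% c("<pad>", "<mask>", "<unk>", "<cls>", "<eos>"))
}

#' Encode a heavy/light pair as fixed-length token ids
#'
#' Layout: `<cls> HEAVY <cls> <cls> LIGHT <eos>`, then `<pad>` to
#' `maxLen` — a leading classifier token, the two-token chain separator,
#' and one terminal end token. Unknown residues map to `<unk>`. Region
#' labels, when masks are supplied, are projected onto the residue
#' positions; specials and pads carry `NONE`.
#'
#' @param heavy,light amino-acid strings.
#' @param vocab a [Vocabulary-class].
#' @param maxLen fixed padded length (default 320).
#' @param heavyMask,lightMask optional [RegionMask-class] objects.
#' @return A [TokenizedPair-class].
#' @examples
#' tok <- encodePair("QVQ", "DIQ", aaVocabulary())
#' sum(tok@attentionFlags)  # 3 + 3 + 4 specials = 10
#' @export
encodePair <- function(heavy, light, vocab = aaVocabulary(), maxLen = 320L,
                       heavyMask = NULL, lightMask = NULL) {
  stopifnot2(nzchar(heavy) && nzchar(light), "chains must be non-empty")
  nh <- nchar(heavy); nl <- nchar(light)
  nReal <- nh + nl + 4L
  if (nReal > maxLen)
    stop(sprintf("pair of %d tokens exceeds maxLen %d (no truncation)",
                 nReal, maxLen), call. = FALSE)
  sp <- .specialIds(vocab)
  ids <- c(sp["cls"], tokenId(vocab, strsplit(heavy, "")[[1]]),
           sp["cls"], sp["cls"], tokenId(vocab, strsplit(light, "")[[1]]),
           sp["eos"], rep.int(sp["pad"], maxLen - nReal))
  regions <- rep.int("NONE", maxLen)
  chains <- rep.int("special", maxLen)
  hPos <- 1L + seq_len(nh)
  lPos <- nh + 3L + seq_len(nl)
  chains[hPos] <- "heavy"; chains[lPos] <- "light"
  if (!is.null(heavyMask)) {
    stopifnot2(length(heavyMask@labels) == nh, "heavy mask length mismatch")
    regions[hPos] <- heavyMask@labels
  }
  if (!is.null(lightMask)) {
    stopifnot2(length(lightMask@labels) == nl, "light mask length mismatch")
    regions[lPos] <- lightMask@labels
  }
  new("TokenizedPair", tokenIds = as.integer(unname(ids)),
      attentionFlags = as.integer(seq_len(maxLen) <= nReal),
      tokenRegions = regions, chainOfToken = chains)
}

#' Decode a tokenized pair back to its chains
#'
#' Exact inverse of [encodePair()] for sequences without `<unk>`
#' substitutions. The special-token layout is checked and a malformed
#' layout raises an error.
#'
#' @param tok a [TokenizedPair-class].
#' @param vocab a [Vocabulary-class].
#' @return list with `heavy` and `light` strings.
#' @export
decodePair <- function(tok, vocab = aaVocabulary()) {
  sp <- .specialIds(vocab)
  ids <- tok@tokenIds[tok@attentionFlags == 1L]
  n <- length(ids)
  seps <- which(ids == sp["cls"])
  if (length(seps) != 3L || seps[1] != 1L || seps[3] != seps[2] + 1L ||
      ids[n] != sp["eos"])
    stop("malformed special-token layout", call. = FALSE)
  heavyIds <- ids[seq(2L, seps[2] - 1L)]
  lightIds <- ids[seq(seps[3] + 1L, n - 1L)]
  list(heavy = paste(tokenOf(vocab, heavyIds), collapse = ""),
       light = paste(tokenOf(vocab, lightIds), collapse = ""))
}

#' Tokenize every record of a repertoire
#'
#' Encodes each pair with its truth region masks recovered from the region
#' subsequence columns.
#'
#' @param rep a [PairedRepertoire-class].
#' @param vocab a [Vocabulary-class].
#' @param maxLen fixed padded length.
#' @return list of [TokenizedPair-class] objects, named by sequence id.
#' @export
tokenizeRepertoire <- function(rep, vocab = aaVocabulary(), maxLen = 320L) {
  out <- lapply(seq_len(nrow(rep)), function(i)
    encodePair(rep$heavy_sequence[i], rep$light_sequence[i], vocab, maxLen,
               heavyMask = regionMaskOf(rep, i, "heavy"),
               lightMask = regionMaskOf(rep, i, "light")))
  names(out) <- rep$sequence_id
  out
}
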