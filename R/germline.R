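#' @include AllClasses.R
NULL

# Desk-scale canonical region lengths for the germline scaffold. Real
# variable domains are ~110-130 residues; these shorter layouts preserve
# the FR/CDR architecture while keeping paired inputs compact.
.REGION_LAYOUT <- list(
  heavy = c(FR1 = 10L, CDR1 = 6L, FR2 = 8L, CDR2 = 6L, FR3 = 12L,
            VFLANK = 3L, JFLANK = 3L, FR4 = 8L),
  light = c(FR1 = 9L, CDR1 = 5L, FR2 = 7L, CDR2 = 4L, FR3 = 11L,
            VFLANK = 3L, JFLANK = 3L, FR4 = 7L))

# Probability that an allele position copies the chain consensus. FRs are
# strongly conserved across the library, CDR1/2 moderately, CDR3 flanks in
# between: this is what makes frameworks far more predictable than CDR3s.
.CONSERVATION <- c(FR = 0.97, CDR = 0.70, FLANK = 0.85)

.sampleAllelePos <- function(consensus, pCopy) {
  n <- length(consensus)
  keep <- runif(n) < pCopy
  out <- consensus
  if (any(!keep))
    out[!keep] <- vapply(consensus[!keep],
      function(a) sample(setdiff(AA20, a), 1L), character(1))
  out
}

.makeVSegment <- function(name, chain, cons) {
  lay <- .REGION_LAYOUT[[chain]]
  res <- c(.sampleAllelePos(cons$FR1, .CONSERVATION["FR"]),
           .sampleAllelePos(cons$CDR1, .CONSERVATION["CDR"]),
           .sampleAllelePos(cons$FR2, .CONSERVATION["FR"]),
           .sampleAllelePos(cons$CDR2, .CONSERVATION["CDR"]),
           .sampleAllelePos(cons$FR3, .CONSERVATION["FR"]),
           .sampleAllelePos(cons$VFLANK, .CONSERVATION["FLANK"]))
  lens <- lay[c("FR1", "CDR1", "FR2", "CDR2", "FR3", "VFLANK")]
  ends <- cumsum(lens)
  starts <- c(0L, head(ends, -1L))
  bnames <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3")
  boundaries <- Map(function(s, e) c(s, e), starts, ends)
  names(boundaries) <- bnames
  list(name = name, chain = chain, segmentClass = "V",
       residues = paste(res, collapse = ""), boundaries = boundaries)
}

.makeJSegment <- function(name, chain, cons) {
  lay <- .REGION_LAYOUT[[chain]]
  res <- c(.sampleAllelePos(cons$JFLANK, .CONSERVATION["FLANK"]),
           .sampleAllelePos(cons$FR4, .CONSERVATION["FR"]))
  nf <- lay["JFLANK"]
  boundaries <- list(CDR3 = c(0L, nf), FR4 = c(nf, nf + lay["FR4"]))
  list(name = name, chain = chain, segmentClass = "J",
       residues = paste(res, collapse = ""), boundaries = boundaries)
}

.makeDSegment <- function(name) {
  len <- sample(3:5, 1L)
  res <- paste(sample(AA20, len, replace = TRUE), collapse = "")
  list(name = name, chain = "heavy", segmentClass = "D",
       residues = res, boundaries = list(CDR3 = c(0L, len)))
}

#' Build a synthetic germline segment library
#'
#' Draws a per-chain, per-position consensus profile once, then samples
#' `nV` V alleles, `nD` heavy-chain D alleles and `nJ` J alleles around it.
#' Framework positions copy the consensus with high probability so the
#' library's frameworks are strongly conserved, CDR1/2 positions vary more,
#' and D segments are fully random. V segments encode FR1-FR3, CDR1-CDR2
#' and the CDR3 left flank; J segments encode the CDR3 right flank and FR4.
#'
#' @param seed integer seed; the library is deterministic given it.
#' @param nV,nD,nJ allele counts (all >= 1; `nD` heavy chain only).
#' @return A [GermlineLibrary-class].
#' @examples
#' lib <- buildGermlineLibrary(seed = 7, nV = 5, nD = 3, nJ = 4)
#' lib
#' @export
buildGermlineLibrary <- function(seed, nV = 5L, nD = 3L, nJ = 4L) {
  stopifnot2(nV >= 1 && nD >= 1 && nJ >= 1, "allele counts must be >= 1")
  withSeed(deriveSeed(seed, 11L), {
    consensus <- lapply(.REGION_LAYOUT, function(lay)
      lapply(as.list(lay), function(n) sample(AA20, n, replace = TRUE)))
    heavy <- list(
      V = lapply(seq_len(nV), function(i)
        .makeVSegment(sprintf("IGHV%d", i), "heavy", consensus$heavy)),
      D = lapply(seq_len(nD), function(i) .makeDSegment(sprintf("IGHD%d", i))),
      J = lapply(seq_len(nJ), function(i)
        .makeJSegment(sprintf("IGHJ%d", i), "heavy", consensus$heavy)))
    light <- list(
      V = lapply(seq_len(nV), function(i)
        .makeVSegment(sprintf("IGLV%d", i), "light", consensus$light)),
      J = lapply(seq_len(nJ), function(i)
        .makeJSegment(sprintf("IGLJ%d", i), "light", consensus$light)))
    new("GermlineLibrary", heavy = heavy, light = light,
        consensus = consensus, seed = as.integer(seed))
  })
}
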