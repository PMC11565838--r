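#' @include repertoire.R
NULL

annotationError <- function(msg, reason) {
  stop(structure(class = c("AnnotationError", "error", "condition"),
                 list(message = msg, call = NULL, reason = reason)))
}

.checkResidues <- function(s, what) {
  ok <- strsplit(s, "")[[1]] %in% c(AA20, "X")
  if (!all(ok))
    stop(sprintf("%s contains invalid residue characters: %s", what,
                 paste(unique(strsplit(s, "")[[1]][!ok]), collapse = "")),
         call. = FALSE)
}

#' Semi-global alignment of a region fragment to a full chain
#'
#' Exact dynamic-programming optimum for an alignment that is global in the
#' fragment and free of end-gap penalties on the chain: the fragment must
#' be consumed in full, chain overhangs on either side cost nothing, and
#' gaps inside the aligned span are penalized. Ties in score are broken by
#' the smallest chain start, then the smallest end, then by preferring
#' substitution over gap moves.
#'
#' @param fragment amino-acid string (the region subsequence).
#' @param chain amino-acid string (the full chain).
#' @param match,mismatch,gap scoring scheme (defaults +1/-1/-2).
#' @return list with `score`, `queryStart`/`queryEnd` (0-based half-open
#'   span on the chain) and `identity` (matches / aligned columns).
#' @examples
#' semiglobalAlign("CARDY", "MQCARDYWGQG")
#' @export
semiglobalAlign <- function(fragment, chain, match = 1, mismatch = -1,
                            gap = -2) {
  stopifnot2(nzchar(fragment) && nzchar(chain),
             "fragment and chain must be non-empty")
  .checkResidues(fragment, "fragment")
  .checkResidues(chain, "chain")
  f <- strsplit(fragment, "")[[1]]
  c2 <- strsplit(chain, "")[[1]]
  m <- length(f); n <- length(c2)
  # H: score; St: smallest chain start among optimal paths;
  # Mt: matches and Al: aligned columns along the tie-broken path.
  H <- matrix(-Inf, m + 1, n + 1)
  St <- matrix(0L, m + 1, n + 1)
  Mt <- matrix(0L, m + 1, n + 1)
  Al <- matrix(0L, m + 1, n + 1)
  H[1, ] <- 0; St[1, ] <- 0:n
  for (i in seq_len(m)) {
    H[i + 1, 1] <- i * gap
    Al[i + 1, 1] <- i
    for (j in seq_len(n)) {
      sub <- H[i, j] + if (f[i] == c2[j]) match else mismatch
      up <- H[i, j + 1] + gap     # fragment residue against a chain gap
      left <- H[i + 1, j] + gap   # chain residue against a fragment gap
      best <- max(sub, up, left)
      # candidate predecessors at the best score, tie-broken by smallest
      # start, then substitution > up > left
      cand <- list()
      if (sub == best) cand <- c(cand, list(c(St[i, j], Mt[i, j] +
        (f[i] == c2[j]), Al[i, j] + 1L)))
      if (up == best) cand <- c(cand, list(c(St[i, j + 1], Mt[i, j + 1],
        Al[i, j + 1] + 1L)))
      if (left == best) cand <- c(cand, list(c(St[i + 1, j], Mt[i + 1, j],
        Al[i + 1, j] + 1L)))
      starts <- vapply(cand, `[`, numeric(1), 1)
      pick <- cand[[which.min(starts)]]
      H[i + 1, j + 1] <- best
      St[i + 1, j + 1] <- pick[1]
      Mt[i + 1, j + 1] <- pick[2]
      Al[i + 1, j + 1] <- pick[3]
    }
  }
  final <- H[m + 1, ]
  best <- max(final)
  ends <- which(final == best) - 1L
  qs <- St[m + 1, ends + 1L]
  keep <- ends[qs == min(qs)]
  end <- min(keep)
  list(score = best,
       queryStart = as.integer(St[m + 1, end + 1L]),
       queryEnd = as.integer(end),
       identity = Mt[m + 1, end + 1L] / Al[m + 1, end + 1L])
}

#' Build a region mask by sequential fragment alignment
#'
#' Aligns the seven region fragments, in canonical order, each within the
#' chain suffix remaining after the previous fragment's span. The
#' resulting spans must tile the chain without gaps or overlaps and every
#' fragment must align at or above the identity threshold; otherwise an
#' `AnnotationError` condition is signalled (the record is flagged, never
#' silently repaired). When adjacent fragments disagree about a boundary
#' residue, the earlier region keeps it, because later fragments only see
#' the suffix after the earlier span.
#'
#' @param chain full amino-acid chain.
#' @param fragments named character vector of the 7 region subsequences in
#'   canonical order (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4).
#' @param identityThreshold minimum per-fragment alignment identity.
#' @return A [RegionMask-class] with source "aligned".
#' @export
buildRegionMask <- function(chain, fragments, identityThreshold = 0.9) {
  stopifnot2(identical(names(fragments), REGION_LEVELS),
             "fragments must be named FR1..FR4/CDR1..CDR3 in canonical order")
  n <- nchar(chain)
  labels <- character(n)
  offset <- 0L
  for (rg in REGION_LEVELS) {
    frag <- fragments[[rg]]
    if (!nzchar(frag))
      annotationError(sprintf("empty %s fragment", rg), "empty_fragment")
    if (offset >= n)
      annotationError(sprintf("%s extends past the chain end", rg),
                      "overflow")
    aln <- semiglobalAlign(frag, substr(chain, offset + 1L, n))
    if (aln$identity < identityThreshold)
      annotationError(sprintf("%s aligns at identity %.3f < %.3f", rg,
                              aln$identity, identityThreshold),
                      "low_identity")
    if (aln$queryStart > 0)
      annotationError(sprintf("unlabelled residues before %s", rg),
                      "gap_between_regions")
    if (aln$queryEnd == 0)
      annotationError(sprintf("%s aligned to an empty chain span", rg),
                      "empty_span")
    span <- (offset + 1L):(offset + aln$queryEnd)
    labels[span] <- rg
    offset <- offset + aln$queryEnd
  }
  if (offset != n)
    annotationError("unlabelled residues after FR4", "trailing_gap")
  regionMask(labels, "aligned")
}

.regionFragments <- function(rep, i, chain) {
  cols <- paste0(chain, "_", sub("FR", "fwr", sub("CDR", "cdr",
                                                  REGION_LEVELS)))
  setNames(vapply(cols, function(col) rep[[col]][i], character(1)),
           REGION_LEVELS)
}

#' Filter duplicate and unannotatable records
#'
#' Removes exact duplicate (heavy, light) pairs (case/whitespace
#' normalized, first occurrence kept) and records whose region masks
#' cannot be rebuilt by [buildRegionMask()] on both chains. Retained
#' records are returned unaltered.
#'
#' @param rep a [PairedRepertoire-class] with region columns.
#' @param identityThreshold forwarded to [buildRegionMask()].
#' @return list with `clean` (a [PairedRepertoire-class]) and `rejected`
#'   (a `data.frame` of `sequence_id` and `reason`).
#' @export
filterAnnotationErrors <- function(rep, identityThreshold = 0.9) {
  norm <- paste(toupper(trimws(rep$heavy_sequence)),
                toupper(trimws(rep$light_sequence)))
  dup <- duplicated(norm)
  reasons <- character(nrow(rep))
  reasons[dup] <- "duplicate"
  for (i in which(!dup)) {
    for (chain in c("heavy", "light")) {
      res <- tryCatch({
        buildRegionMask(rep[[paste0(chain, "_sequence")]][i],
                        .regionFragments(rep, i, chain),
                        identityThreshold)
        NULL
      }, AnnotationError = function(e) e$reason)
      if (!is.null(res)) {
        reasons[i] <- paste0(chain, ":", res)
        break
      }
    }
  }
  keep <- !nzchar(reasons)
  list(clean = new("PairedRepertoire", rep[keep, , drop = FALSE]),
       rejected = data.frame(sequence_id = rep$sequence_id[!keep],
                             reason = reasons[!keep],
                             stringsAsFactors = FALSE))
}
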