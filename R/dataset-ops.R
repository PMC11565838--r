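#' @include repertoire.R
NULL

.aaSubstMatrix <- function(match = 1, mismatch = -1) {
  ab <- c(AA20, "X")
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match
  m
}

#' Pairwise global-alignment identity
#'
#' Identity (matched columns / alignment length) of a global alignment of
#' two amino-acid strings under a +1/-1 substitution score with a flat gap
#' penalty of 2, computed with Biostrings.
#'
#' @param a,b amino-acid strings.
#' @return numeric identity in `[0, 1]`.
#' @export
globalIdentity <- function(a, b) {
  aln <- pairwiseAlignment(AAStringSet(a), Biostrings::AAString(b),
                           substitutionMatrix = .aaSubstMatrix(),
                           gapOpening = 0, gapExtension = 2,
                           type = "global")
  pid(aln, type = "PID1") / 100
}

#' Greedy identity clustering
#'
#' CD-HIT-style greedy clustering: records are processed in decreasing
#' order of total (heavy + light) length, ties broken by sequence id; each
#' record joins the first existing representative (in founding order)
#' whose concatenated heavy+light global-alignment identity is at or
#' above the threshold, otherwise it founds a new cluster. Only
#' representatives are retained downstream.
#'
#' @param rep a [PairedRepertoire-class].
#' @param identityThreshold identity threshold in `(0, 1]` (the
#'   pre-training pipeline uses 0.96, the classification pipelines 0.95).
#' @return A [ClusteringResult-class].
#' @export
greedyCluster <- function(rep, identityThreshold = 0.96) {
  stopifnot2(identityThreshold > 0 && identityThreshold <= 1,
             "identityThreshold must lie in (0, 1]")
  concat <- paste0(rep$heavy_sequence, rep$light_sequence)
  ids <- rep$sequence_id
  ord <- order(-nchar(concat), ids)
  repIds <- character(0)
  repSeqs <- character(0)
  assignment <- setNames(character(length(ids)), ids)
  subst <- .aaSubstMatrix()
  for (i in ord) {
    joined <- NA_character_
    if (length(repSeqs)) {
      aln <- pairwiseAlignment(AAStringSet(repSeqs),
                               Biostrings::AAString(concat[i]),
                               substitutionMatrix = subst,
                               gapOpening = 0, gapExtension = 2,
                               type = "global")
      idn <- pid(aln, type = "PID1") / 100
      hit <- which(idn >= identityThreshold)
      if (length(hit)) joined <- repIds[hit[1]]
    }
    if (is.na(joined)) {
      repIds <- c(repIds, ids[i])
      repSeqs <- c(repSeqs, concat[i])
      joined <- ids[i]
    }
    assignment[ids[i]] <- joined
  }
  new("ClusteringResult", representativeOf = assignment,
      clusters = split(names(assignment), assignment)[repIds],
      threshold = identityThreshold)
}

#' Random train/validation/test split
#'
#' Uniform random permutation under the seed, then contiguous slicing by
#' the requested ratios (default 92:4:4). Donors are not held out, so all
#' donors may appear in all splits.
#'
#' @param rep a [PairedRepertoire-class] or an integer record count.
#' @param ratios numeric triple summing to 1.
#' @param seed integer seed.
#' @return A [SplitAssignment-class] over "train"/"validation"/"test".
#' @export
splitDataset <- function(rep, ratios = c(0.92, 0.04, 0.04), seed = 1L) {
  stopifnot2(abs(sum(ratios) - 1) < 1e-9, "ratios must sum to 1")
  n <- if (is.numeric(rep)) as.integer(rep) else nrow(rep)
  sizes <- diff(c(0L, round(cumsum(ratios) * n)))
  perm <- withSeed(deriveSeed(seed, 41L), sample.int(n))
  labels <- rep.int(c("train", "validation", "test"), sizes)
  assignment <- character(n)
  assignment[perm] <- labels
  if (!is.numeric(rep)) names(assignment) <- rep$sequence_id
  new("SplitAssignment", assignment = assignment, seed = as.integer(seed))
}

.derangementShuffle <- function(k, maxTries = 100L) {
  for (t in seq_len(maxTries)) {
    p <- sample.int(k)
    if (!any(p == seq_len(k))) return(p)
  }
  p  # duplicated light chains downstream rely on the collision filter
}

#' Generate native vs. shuffled chain pairs
#'
#' Per donor, a random half of the records is selected and their light
#' chains are permuted by a derangement-seeking shuffle (for a selected
#' singleton the light chain of another record of the same donor is used);
#' the untouched half keeps the label "native". Any shuffled pair whose
#' (heavy, light) combination equals a native pair present in the input is
#' removed — light-chain redundancy makes a small fraction of shuffles
#' collide with true pairings. Donors with a single pair are skipped with
#' a warning.
#'
#' @param rep a [PairedRepertoire-class].
#' @param fraction fraction of each donor's records to shuffle.
#' @param seed integer seed.
#' @return A [PairedRepertoire-class] with `pair_label` filled in; light
#'   chain columns (sequence, regions, mutation count) of shuffled records
#'   come from the record that donated the light chain.
#' @export
makeShuffledPairs <- function(rep, fraction = 0.5, seed = 1L) {
  lightCols <- c("light_sequence",
                 grep("^light_(fwr|cdr)", .AIRR_COLS, value = TRUE),
                 "light_mutations")
  df <- as.data.frame(rep)
  df$pair_label <- "native"
  withSeed(deriveSeed(seed, 53L), {
    for (d in unique(df$donor)) {
      idx <- which(df$donor == d)
      if (length(idx) < 2) {
        warning(sprintf("donor %s has a single pair; skipped", d))
        next
      }
      k <- round(fraction * length(idx))
      if (k < 1) next
      sel <- idx[sample.int(length(idx), k)]
      if (k >= 2) {
        donorIdx <- sel[.derangementShuffle(k)]
      } else {
        others <- setdiff(idx, sel)
        donorIdx <- others[sample.int(length(others), 1L)]
      }
      df[sel, lightCols] <- df[donorIdx, lightCols]
      df$pair_label[sel] <- "shuffled"
    }
  })
  nativeKey <- paste(rep$heavy_sequence, rep$light_sequence)
  key <- paste(df$heavy_sequence, df$light_sequence)
  drop <- df$pair_label == "shuffled" & key %in% nativeKey
  PairedRepertoire(df[!drop, , drop = FALSE])
}

#' Stratify pairs by matched mutation status
#'
#' "Same" pairs have both chains mutated or both unmutated; "Different"
#' pairs have exactly one mutated chain. The grouping separates the
#' naive/memory confound from true pairing signal in classifier analyses.
#'
#' @param rep a [PairedRepertoire-class] (or data.frame) with
#'   `heavy_mutations` and `light_mutations`.
#' @return character vector over "Same"/"Different", one per record.
#' @export
stratifySameDifferent <- function(rep) {
  h <- rep$heavy_mutations > 0
  l <- rep$light_mutations > 0
  ifelse(h == l, "Same", "Different")
}

#' Stratified k-fold cross-validation assignment
#'
#' Shuffles each class under the seed and deals its members to folds so
#' that per-fold class counts differ from perfect proportionality by at
#' most one record and fold sizes differ by at most one.
#'
#' @param labels class label vector (each class needs >= k members).
#' @param k number of folds.
#' @param seed integer seed.
#' @return A [SplitAssignment-class] with integer fold indices.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  classes <- unique(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(counts)[which.min(counts)], k), call. = FALSE)
  fold <- integer(length(labels))
  totals <- integer(k)
  withSeed(deriveSeed(seed, 67L), {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      sizes <- rep.int(base, k)
      if (extra > 0) {
        # remainders go to the currently smallest folds, ties by index
        give <- order(totals, seq_len(k))[seq_len(extra)]
        sizes[give] <- sizes[give] + 1L
      }
      totals <- totals + sizes
      fold[idx] <- rep.int(seq_len(k), sizes)
    }
  })
  new("SplitAssignment", assignment = fold, seed = as.integer(seed))
}
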