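#' @include germline.R
NULL

#' Generator configuration
#'
#' Study conditions for the synthetic paired repertoire: number of pairs
#' and donors, the naive (unmutated) fraction, the per-residue somatic
#' hypermutation rate, the multiplicative CDR enrichment of that rate, and
#' the range of non-templated CDR3 junction insertion lengths.
#'
#' @param nPairs number of heavy/light pairs to generate.
#' @param donors number of donors; assignment is uniform.
#' @param naiveFraction probability a pair is naive (unmutated).
#' @param shmRate per-residue framework mutation probability for memory
#'   cells.
#' @param cdrBias multiplicative mutation enrichment inside CDRs (>= 1).
#' @param junctionLengthRange integer `c(min, max)` non-templated insertion
#'   length, uniform on the range.
#' @param seed integer seed.
#' @return A named list with class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(nPairs = 1000L, donors = 4L,
                            naiveFraction = 0.5, shmRate = 0.02,
                            cdrBias = 4, junctionLengthRange = c(2L, 8L),
                            seed = 1L) {
  stopifnot2(naiveFraction >= 0 && naiveFraction <= 1,
             "naiveFraction must be a probability")
  stopifnot2(shmRate >= 0 && shmRate <= 1, "shmRate must be a probability")
  stopifnot2(cdrBias >= 1, "cdrBias must be >= 1")
  stopifnot2(junctionLengthRange[1] <= junctionLengthRange[2],
             "junction length min must be <= max")
  structure(list(nPairs = as.integer(nPairs), donors = as.integer(donors),
                 naiveFraction = naiveFraction, shmRate = shmRate,
                 cdrBias = cdrBias,
                 junctionLengthRange = as.integer(junctionLengthRange),
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Apply somatic hypermutation to one chain
#'
#' Each CDR residue mutates independently with probability
#' `shmRate * cdrBias`, each framework residue with `shmRate`;
#' substitutions are drawn uniformly from the 19 alternative amino acids.
#'
#' @param residues amino-acid string.
#' @param mask a [RegionMask-class] for the chain.
#' @param shmRate per-residue framework mutation probability.
#' @param cdrBias CDR enrichment factor; `shmRate * cdrBias` must be <= 1.
#' @return list with `residues` (mutated string) and `count` (number of
#'   changed positions).
#' @export
applySHM <- function(residues, mask, shmRate, cdrBias = 1) {
  stopifnot2(shmRate * cdrBias <= 1,
             "shmRate * cdrBias must not exceed 1")
  chars <- strsplit(residues, "")[[1]]
  stopifnot2(length(chars) == length(mask@labels),
             "mask length must equal chain length")
  rate <- ifelse(mask@labels %in% CDR_LEVELS, shmRate * cdrBias, shmRate)
  hit <- runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit],
      function(a) sample(setdiff(AA20, a), 1L), character(1))
  list(residues = paste(chars, collapse = ""), count = sum(hit))
}

.expandMask <- function(boundaries) {
  unlist(Map(function(nm, b) rep(nm, b[2] - b[1]),
             names(boundaries), boundaries), use.names = FALSE)
}

.pickSegment <- function(segs) segs[[sample.int(length(segs), 1L)]]

.recombineChain <- function(library, chain, config) {
  sub <- if (chain == "heavy") library@heavy else library@light
  stopifnot2(length(sub$V) > 0 && length(sub$J) > 0 &&
               (chain == "light" || length(sub$D) > 0),
             sprintf("germline library lacks segments for the %s chain", chain))
  v <- .pickSegment(sub$V)
  j <- .pickSegment(sub$J)
  lens <- seq(config$junctionLengthRange[1], config$junctionLengthRange[2])
  insLen <- lens[sample.int(length(lens), 1L)]
  ins <- if (insLen > 0)
    paste(sample(AA20, insLen, replace = TRUE), collapse = "") else ""
  dres <- if (chain == "heavy") .pickSegment(sub$D)$residues else ""
  residues <- paste0(v$residues, ins, dres, j$residues)
  labels <- c(.expandMask(v$boundaries),
              rep("CDR3", nchar(ins) + nchar(dres)),
              .expandMask(j$boundaries))
  list(residues = residues, mask = regionMask(labels, "truth"))
}

#' Recombine one paired sequence
#'
#' Draws V(, D) and J segments per chain, inserts a non-templated junction
#' of uniform random length and composition into the CDR3, assigns a donor
#' and cell type, and applies somatic hypermutation to memory cells (both
#' chains mutated, at least one substitution each; naive cells are
#' unmutated by convention).
#'
#' @param library a [GermlineLibrary-class].
#' @param config a [generatorConfig()] list.
#' @param donor donor identifier to assign.
#' @param id sequence identifier.
#' @return A one-row `data.frame` in the repertoire column layout, with the
#'   truth [RegionMask-class] objects attached as attributes `heavyMask`
#'   and `lightMask`.
#' @export
recombinePair <- function(library, config, donor = "donor1", id = "pair1") {
  h <- .recombineChain(library, "heavy", config)
  l <- .recombineChain(library, "light", config)
  cellType <- if (runif(1) < config$naiveFraction) "naive" else "memory"
  hmut <- 0L; lmut <- 0L
  if (cellType == "memory" && config$shmRate > 0) {
    repeat {
      m <- applySHM(h$residues, h$mask, config$shmRate, config$cdrBias)
      if (m$count > 0) { h$residues <- m$residues; hmut <- m$count; break }
    }
    repeat {
      m <- applySHM(l$residues, l$mask, config$shmRate, config$cdrBias)
      if (m$count > 0) { l$residues <- m$residues; lmut <- m$count; break }
    }
  }
  row <- data.frame(sequence_id = id, donor = donor, cell_type = cellType,
                    heavy_sequence = h$residues, light_sequence = l$residues,
                    stringsAsFactors = FALSE)
  for (chain in c("heavy", "light")) {
    obj <- if (chain == "heavy") h else l
    chars <- strsplit(obj$residues, "")[[1]]
    for (rg in REGION_LEVELS) {
      col <- paste0(chain, "_", sub("FR", "fwr", sub("CDR", "cdr", rg)))
      row[[col]] <- paste(chars[obj$mask@labels == rg], collapse = "")
    }
  }
  row$heavy_mutations <- hmut
  row$light_mutations <- lmut
  row$pair_label <- NA_character_
  row$specificity_label <- NA_character_
  attr(row, "heavyMask") <- h$mask
  attr(row, "lightMask") <- l$mask
  row
}

#' Generate a synthetic paired repertoire
#'
#' Deterministically (per seed) generates `nPairs` paired sequences from a
#' germline library built from the same seed, with uniform donor
#' assignment.
#'
#' @param config a [generatorConfig()] list.
#' @param library optional pre-built [GermlineLibrary-class]; defaults to
#'   `buildGermlineLibrary(config$seed)`.
#' @return A [PairedRepertoire-class].
#' @examples
#' rep <- generateRepertoire(generatorConfig(nPairs = 20, seed = 1))
#' rep
#' @export
generateRepertoire <- function(config, library = NULL) {
  if (is.null(library)) library <- buildGermlineLibrary(config$seed)
  withSeed(deriveSeed(config$seed, 23L), {
    donorOf <- sample(sprintf("donor%d", seq_len(config$donors)),
                      config$nPairs, replace = TRUE)
    rows <- lapply(seq_len(config$nPairs), function(i)
      recombinePair(library, config, donor = donorOf[i],
                    id = sprintf("pair_%05d", i)))
    PairedRepertoire(do.call(rbind, rows))
  })
}

#' Recover a truth region mask from repertoire region columns
#'
#' The per-region subsequence columns written by the generator tile the
#' chain exactly, so the truth mask is their concatenated labels.
#'
#' @param rep a [PairedRepertoire-class].
#' @param i record index.
#' @param chain "heavy" or "light".
#' @return A [RegionMask-class] with source "truth".
#' @export
regionMaskOf <- function(rep, i, chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  labels <- unlist(lapply(REGION_LEVELS, function(rg) {
    col <- paste0(chain, "_", sub("FR", "fwr", sub("CDR", "cdr", rg)))
    rep.int(rg, nchar(rep[[col]][i]))
  }))
  full <- rep[[paste0(chain, "_sequence")]][i]
  stopifnot2(length(labels) == nchar(full),
             "region columns do not tile the chain")
  regionMask(labels, "truth")
}

#' Plant a specificity motif into heavy-chain CDR3s
#'
#' Labels a random half of the repertoire "positive" and overwrites part of
#' each positive record's heavy CDR3 junction with a fixed motif,
#' emulating the convergent CDR3 motifs that drive antigen-specific
#' classification. The remaining records are labelled "negative" and left
#' untouched. Region architecture and mutation counts are unchanged.
#'
#' @param rep a [PairedRepertoire-class] whose heavy CDR3s are at least
#'   `nchar(motif) + 3` residues long.
#' @param motif amino-acid motif string.
#' @param fraction fraction of records to label positive.
#' @param seed integer seed for the positive-set draw.
#' @return The modified [PairedRepertoire-class] with `specificity_label`
#'   filled in.
#' @export
plantSpecificityMotif <- function(rep, motif = "WGDYRA", fraction = 0.5,
                                  seed = 1L) {
  k <- nchar(motif)
  stopifnot2(all(nchar(rep$heavy_cdr3) >= k + 3),
             "heavy CDR3s too short to carry the motif")
  df <- as.data.frame(rep)
  withSeed(deriveSeed(seed, 37L), {
    pos <- sample(nrow(df), round(fraction * nrow(df)))
    df$specificity_label <- "negative"
    df$specificity_label[pos] <- "positive"
    for (i in pos) {
      cdr3 <- df$heavy_cdr3[i]
      # plant right after the 3-residue V flank, inside the junction zone
      substr(cdr3, 4L, 3L + k) <- motif
      full <- df$heavy_sequence[i]
      start <- nchar(df$heavy_fwr1[i]) + nchar(df$heavy_cdr1[i]) +
        nchar(df$heavy_fwr2[i]) + nchar(df$heavy_cdr2[i]) +
        nchar(df$heavy_fwr3[i])
      substr(full, start + 4L, start + 3L + k) <- motif
      df$heavy_cdr3[i] <- cdr3
      df$heavy_sequence[i] <- full
    }
    PairedRepertoire(df)
  })
}

#' Write / read a repertoire as AIRR-style TSV
#'
#' Plain tab-separated text with one row per pair and the standard column
#' set (sequence_id, donor, cell_type, full chains, per-region
#' subsequences, mutation counts, optional labels).
#'
#' @param rep a [PairedRepertoire-class].
#' @param path file path.
#' @return `writeAIRR` returns `path` invisibly; `readAIRR` returns a
#'   [PairedRepertoire-class].
#' @export
writeAIRR <- function(rep, path) {
  df <- as.data.frame(rep)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname writeAIRR
#' @export
readAIRR <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  df$heavy_mutations <- as.integer(df$heavy_mutations)
  df$light_mutations <- as.integer(df$light_mutations)
  for (col in c("pair_label", "specificity_label"))
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  PairedRepertoire(df)
}
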