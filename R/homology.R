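## Candidate-region selection: seed-and-extend local alignment of reference
## exon sequences against the scaffold, then the score/species filter.

#' Default alignment scoring scheme
#'
#' match +2, mismatch -3, gap open -5, gap extend -2 (a gap of length L costs
#' 5 + 2L). The score-over-300 candidate filter is calibrated against this
#' scheme; raw scores from other tools are not comparable.
#'
#' @param match,mismatch,gapOpen,gapExtend Integer scores (penalties <= 0).
#' @return list scoring scheme.
#' @export
scoringScheme <- function(match = 2L, mismatch = -3L, gapOpen = -5L,
                          gapExtend = -2L) {
  stopifnot(match > 0L, mismatch <= 0L, gapOpen <= 0L, gapExtend <= 0L)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend))
}

#' Seed-and-extend local alignment
#'
#' Finds shared k-mers between query and scaffold (both query strands),
#' clusters seeds by diagonal, and scores each clustered region with a full
#' affine-gap local alignment (Smith-Waterman) of the query against the
#' clustered scaffold window. Every reported score is therefore an exact
#' local-alignment score under `scheme`. Hits with score below `minScore`
#' are suppressed.
#'
#' @param query,scaffold DNA sequences (character or DNAString).
#' @param k Seed length (>= 8).
#' @param scheme A [scoringScheme()].
#' @param minScore Minimum reported score (default 0: report all).
#' @return data.frame with columns qStart, qEnd (query, 1-based inclusive,
#'   on the original query), sStart, sEnd (scaffold), strand, score, identity.
#' @export
seedExtendAlign <- function(query, scaffold, k = 11L, scheme = scoringScheme(),
                            minScore = 0L) {
  query <- toupper(dnaToChar(query))
  scaffold <- toupper(dnaToChar(scaffold))
  if (nchar(query) == 0L || nchar(scaffold) == 0L)
    stop("query and scaffold must be non-empty")
  assertDna(query, "query")
  assertDna(scaffold, "scaffold")
  if (k < 8L) stop("seed length k must be >= 8")

  sIndex <- kmerIndex(scaffold, k)
  Lq <- nchar(query)
  hits <- list()
  for (str in c("+", "-")) {
    q <- if (str == "+") query else revComp(query)
    if (nchar(q) < k) next
    seeds <- seedMatches(q, sIndex, k)
    if (nrow(seeds) == 0L) next
    for (cl in clusterSeeds(seeds)) {
      sLo <- max(1L, min(cl$spos) - min(cl$qpos) - 30L)
      sHi <- min(nchar(scaffold),
                 max(cl$spos) + k - 1L + (Lq - max(cl$qpos) - k + 1L) + 30L)
      aln <- .sw_align(q, substr(scaffold, sLo, sHi),
                       scheme$match, scheme$mismatch,
                       scheme$gapOpen, scheme$gapExtend)
      if (aln$score <= 0L || aln$score < minScore) next
      qs <- aln$aStart; qe <- aln$aEnd
      if (str == "-") {   # report on the original query orientation
        tmp <- qs
        qs <- Lq - qe + 1L
        qe <- Lq - tmp + 1L
      }
      hits[[length(hits) + 1L]] <- data.frame(
        qStart = qs, qEnd = qe,
        sStart = sLo + aln$bStart - 1L, sEnd = sLo + aln$bEnd - 1L,
        strand = str, score = aln$score,
        identity = aln$matches / aln$columns,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(qStart = integer(), qEnd = integer(),
                      sStart = integer(), sEnd = integer(),
                      strand = character(), score = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  ## windows of neighbouring clusters can rediscover (parts of) the same
  ## alignment: greedy non-maximum suppression on the scaffold interval
  out <- out[order(-out$score, out$sStart), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(out))) {
    iv <- c(out$sStart[i], out$sEnd[i])
    dup <- FALSE
    for (j in kept) {
      if (out$strand[j] != out$strand[i]) next
      inter <- min(iv[2L], out$sEnd[j]) - max(iv[1L], out$sStart[j]) + 1L
      if (inter > 0.5 * min(iv[2L] - iv[1L] + 1L,
                            out$sEnd[j] - out$sStart[j] + 1L)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  out <- out[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Hash positions of every k-mer of s.
kmerIndex <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(list())
  kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  split(seq_len(n), kmers)
}

seedMatches <- function(q, sIndex, k) {
  n <- nchar(q) - k + 1L
  kmers <- substring(q, seq_len(n), seq_len(n) + k - 1L)
  hit <- sIndex[kmers]
  lens <- lengths(hit)
  keep <- which(lens > 0L & lens <= 50L)   # skip hyper-repetitive seeds
  data.frame(qpos = rep(keep, lens[keep]),
             spos = unlist(hit[keep], use.names = FALSE))
}

## Group seeds into diagonal bands: same cluster when diagonal differs by
## <= 40 and scaffold positions are within 400 bp of the cluster.
clusterSeeds <- function(seeds) {
  d <- seeds$spos - seeds$qpos
  o <- order(d, seeds$spos)
  seeds <- seeds[o, , drop = FALSE]
  d <- d[o]
  clusters <- list()
  cur <- 1L
  for (i in seq_len(nrow(seeds))[-1L]) {
    new <- d[i] - d[i - 1L] > 40L ||
      seeds$spos[i] - max(seeds$spos[cur:(i - 1L)]) > 400L
    if (new) {
      clusters[[length(clusters) + 1L]] <- seeds[cur:(i - 1L), , drop = FALSE]
      cur <- i
    }
  }
  clusters[[length(clusters) + 1L]] <- seeds[cur:nrow(seeds), , drop = FALSE]
  clusters
}

#' Align reference-species exon sequences to a scaffold
#'
#' Convenience wrapper running [seedExtendAlign()] for each reference
#' sequence and tagging hits with the species label (taken from the sequence
#' names, the part before the first underscore or the whole name).
#'
#' @param references Named [Biostrings::DNAStringSet] of reference exon
#'   sequences.
#' @param scaffold Scaffold sequence.
#' @param ... Passed to [seedExtendAlign()].
#' @return Hit data.frame with a leading `species` column.
#' @export
scanReferenceExons <- function(references, scaffold, ...) {
  stopifnot(!is.null(names(references)))
  species <- sub("_.*$", "", names(references))
  out <- lapply(seq_along(references), function(i) {
    h <- seedExtendAlign(references[[i]], scaffold, ...)
    if (nrow(h) > 0L) cbind(species = species[i], query = names(references)[i],
                            h, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(species = character(), query = character(),
                      qStart = integer(), qEnd = integer(),
                      sStart = integer(), sEnd = integer(),
                      strand = character(), score = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Select candidate encoding regions from alignment hits
#'
#' Overlapping hit intervals on the scaffold are merged (simple interval
#' union), then a merged region is kept iff it contains at least one hit
#' with score strictly greater than `minScore` from each of at least
#' `minSpecies` distinct species - the "score over 300, matched at least two
#' reference species" rule.
#'
#' @param hits data.frame with columns species, sStart, sEnd, score (e.g.
#'   from [scanReferenceExons()]).
#' @param minScore Strict score threshold (default 300).
#' @param minSpecies Minimum distinct supporting species (default 2).
#' @return data.frame(start, end, nSpecies, species, maxScore), one row per
#'   candidate region.
#' @export
selectCandidates <- function(hits, minScore = 300L, minSpecies = 2L) {
  stopifnot(minScore >= 0L, minSpecies >= 1L)
  empty <- data.frame(start = integer(), end = integer(),
                      nSpecies = integer(), species = character(),
                      maxScore = integer(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  ir <- IRanges(hits$sStart, hits$sEnd)
  merged <- reduce(ir)
  ov <- findOverlaps(ir, merged)
  out <- lapply(seq_along(merged), function(i) {
    rows <- hits[queryHits(ov)[subjectHits(ov) == i], , drop = FALSE]
    strong <- rows[rows$score > minScore, , drop = FALSE]
    sp <- unique(strong$species)
    if (length(sp) < minSpecies) return(NULL)
    data.frame(start = start(merged)[i], end = end(merged)[i],
               nSpecies = length(sp),
               species = paste(sort(sp), collapse = ","),
               maxScore = max(strong$score), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}
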