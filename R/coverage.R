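## Short-read mapping, normalized depth tracks, and expression-boundary /
## sex-specificity checks.

#' Map reads to a reference by exhaustive best-hit placement
#'
#' Each read is placed at the position minimising its Hamming distance to
#' the reference over every ungapped offset on both strands (the reverse
#' strand maps the reverse-complemented read); ties break to the leftmost
#' position, then the forward strand. Reads whose minimum exceeds
#' `maxMismatch` stay unaligned. Placement is exact - no heuristic seeding -
#' so every read gets its true best hit.
#'
#' @param reads [Biostrings::DNAStringSet], character vector, or path to a
#'   FASTQ file.
#' @param reference Reference sequence (character or DNAString).
#' @param maxMismatch Maximum allowed mismatches (default 2).
#' @return list(placements = data.frame(id, pos, strand, mismatches) for
#'   aligned reads, unaligned = count, readLengths = lengths of aligned
#'   reads).
#' @export
mapReads <- function(reads, reference, maxMismatch = 2L) {
  ref <- toupper(dnaToChar(reference))
  if (nchar(ref) == 0L) stop("empty reference")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- readDNAStringSet(reads, format = "fastq")
  }
  rs <- toupper(as.character(reads))
  ids <- names(reads) %||na% sprintf("read%06d", seq_along(rs))
  if (length(rs) == 0L) {
    return(list(placements = data.frame(id = character(), pos = integer(),
                                        strand = character(),
                                        mismatches = integer()),
                unaligned = 0L, readLengths = integer()))
  }
  hits <- .map_brute(rs, ref, as.integer(maxMismatch))
  ok <- !is.na(hits$pos)
  list(placements = data.frame(id = ids[ok], pos = hits$pos[ok],
                               strand = hits$strand[ok],
                               mismatches = hits$mismatches[ok],
                               stringsAsFactors = FALSE),
       unaligned = sum(!ok),
       readLengths = nchar(rs)[ok])
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Per-position coverage track
#'
#' Depth at each reference position is the number of placements covering it;
#' the normalized track divides raw depth by the total number of aligned
#' reads (the library-size normalization used to compare runs).
#'
#' @param alignments Result of [mapReads()].
#' @param referenceLength Reference length in bp.
#' @return list(depth = integer vector, normalized = numeric vector,
#'   alignedReads = count).
#' @export
coverageTrack <- function(alignments, referenceLength) {
  n <- as.integer(referenceLength)
  delta <- integer(n + 1L)
  pl <- alignments$placements
  lens <- alignments$readLengths
  for (i in seq_len(nrow(pl))) {
    s <- pl$pos[i]
    e <- min(n, s + lens[i] - 1L)
    delta[s] <- delta[s] + 1L
    delta[e + 1L] <- delta[e + 1L] - 1L
  }
  depth <- cumsum(delta[seq_len(n)])
  aligned <- nrow(pl)
  list(depth = depth,
       normalized = if (aligned > 0L) depth / aligned else depth * 0,
       alignedReads = aligned)
}

#' Check expression boundaries and sex specificity of a coverage track
#'
#' On a gene-locus track (flanks + gene span), reports the fraction of
#' aligned bases falling inside exons, whether coverage starts within the
#' TSS call window and ends at the called terminus, whether upstream and
#' downstream flanks are depth-zero, and positions whose depth exceeds five
#' times the exonic median (repeat-ambiguity peaks).
#'
#' @param track Result of [coverageTrack()] on gene-locus coordinates.
#' @param exons IRanges of exons in track coordinates.
#' @param tssWindow Integer c(lo, hi): track interval containing the TSS
#'   calls (default: the first exon start).
#' @param terminus Track coordinate of the called terminus (default: last
#'   exon end).
#' @return list(empty, exonicFraction, coverageStart, coverageEnd,
#'   startsInTssWindow, endsAtTerminus, upstreamZero, downstreamZero,
#'   peakPositions).
#' @export
expressionCheck <- function(track, exons, tssWindow = NULL, terminus = NULL) {
  depth <- track$depth
  n <- length(depth)
  geneLo <- min(start(exons))
  geneHi <- max(end(exons))
  if (is.null(tssWindow)) tssWindow <- c(geneLo, geneLo)
  if (is.null(terminus)) terminus <- geneHi
  covered <- which(depth > 0L)
  if (length(covered) == 0L) {
    return(list(empty = TRUE, exonicFraction = 0, coverageStart = NA_integer_,
                coverageEnd = NA_integer_, startsInTssWindow = FALSE,
                endsAtTerminus = FALSE, upstreamZero = TRUE,
                downstreamZero = TRUE, peakPositions = integer()))
  }
  exonic <- logical(n)
  for (i in seq_along(exons)) {
    exonic[start(exons)[i]:end(exons)[i]] <- TRUE
  }
  totalBases <- sum(as.numeric(depth))
  exonicBases <- sum(as.numeric(depth[exonic]))
  med <- stats::median(depth[exonic & depth > 0L])
  peaks <- which(depth > 5 * med)
  list(empty = FALSE,
       exonicFraction = exonicBases / totalBases,
       coverageStart = covered[1L],
       coverageEnd = covered[length(covered)],
       startsInTssWindow = covered[1L] >= tssWindow[1L] &&
         covered[1L] <= tssWindow[2L],
       endsAtTerminus = covered[length(covered)] == terminus,
       upstreamZero = geneLo == 1L || all(depth[seq_len(geneLo - 1L)] == 0L),
       downstreamZero = geneHi == n ||
         all(depth[(geneHi + 1L):n] == 0L),
       peakPositions = peaks)
}

#' Gene-locus reference of a bundle
#'
#' The transcribed-strand gene-forward frame (upstream flank + gene span +
#' downstream flank, gap filled) with its exon layout, for locus-coordinate
#' read mapping and [expressionCheck()].
#'
#' @param bundle A [ScaffoldBundle-class].
#' @return list(seq = character reference, exons = IRanges, tss, terminus =
#'   track coordinates).
#' @export
locusReference <- function(bundle) {
  tr <- truthTable(bundle)
  list(seq = tr$geneForwardSeq, exons = tr$exonsGene,
       tss = tr$tssGene, terminus = tr$terminusGene)
}
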