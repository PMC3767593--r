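## Transcript-end calling from RACE-style clones, poly-A signal and promoter
## motif scanning, restriction digests.

## Map a clone 5' anchor onto the extended 5' axis (upstream flank +
## spliced transcript). Anchor hits inside tandem repeats can be multiple;
## a placement only counts if the entire clone matches there, which
## disambiguates any clone extending past the repeat. Returns the axis index
## of the clone start or NA.
mapCloneStart <- function(clone, axis, anchorLen = 30L) {
  cl <- dnaToChar(clone)
  if (nchar(cl) < anchorLen) return(NA_integer_)
  m <- matchPattern(substr(cl, 1L, anchorLen), DNAString(axis))
  full <- start(m)[vapply(start(m), function(p)
    substr(axis, p, p + nchar(cl) - 1L) == cl, logical(1L))]
  if (length(full) != 1L) return(NA_integer_)
  full
}

#' Call transcription start sites from 5' clones
#'
#' Each clone's 5' end is mapped uniquely onto the locus (upstream flank plus
#' spliced transcript); every distinct start position supported by at least
#' `minSupport` clones becomes one TSS call, reported as a no-zero promoter
#' offset relative to the reference TSS. Distinct positions are never merged,
#' however close. Unmappable clones are excluded with a warning.
#'
#' @param clones [Biostrings::DNAStringSet] of 5' RACE clone sequences.
#' @param bundle A [ScaffoldBundle-class] (provides locus and reference TSS).
#' @param minSupport Minimum clones per call (default 1).
#' @return list(calls = data.frame(offset, support), referenceTss = scaffold
#'   position, excluded = number of unmappable clones).
#' @export
callTss <- function(clones, bundle, minSupport = 1L) {
  tr <- truthTable(bundle)
  u <- tr$upstreamFlank
  axis <- extendedAxis(bundle)
  idx <- vapply(seq_along(clones), function(i)
    mapCloneStart(clones[[i]], axis), integer(1L))
  excl <- sum(is.na(idx))
  if (excl > 0L)
    warning(sprintf("%d clone(s) could not be mapped uniquely and were excluded",
                    excl))
  idx <- idx[!is.na(idx)]
  offs <- ifelse(idx > u, idx - u, idx - u - 1L)   # no-zero promoter offsets
  tab <- table(offs)
  keep <- tab[tab >= minSupport]
  calls <- data.frame(offset = as.integer(names(keep)),
                      support = as.integer(keep))
  calls <- calls[order(calls$offset), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, referenceTss = tr$tssPos, excluded = excl)
}

#' Call the transcription termination site from 3' clones
#'
#' Poly-A tails (at least `minTailA` terminal adenines) are trimmed at the
#' last base that still matches the transcript - genomic A-runs at the
#' junction are thereby resolved in favour of the longest genomic match. The
#' modal trimmed end is the terminus. The offset from the expected site is
#' reported as an inclusive position count (expected..called spans
#' `offsetInclusive` bases) together with the plain coordinate difference.
#'
#' @param clones [Biostrings::DNAStringSet] of 3' RACE clones.
#' @param bundle A [ScaffoldBundle-class].
#' @param expected Expected terminus as forward-scaffold position (default:
#'   the bundle's homology-expected terminus).
#' @param minTailA Minimum terminal A-run identifying a poly-A tail.
#' @return list(scaffoldPosition, txPosition, offsetInclusive,
#'   offsetDifference, polyASignal = best upstream signal from
#'   [findPolyASignal()], support).
#' @export
callTerminus <- function(clones, bundle, expected = NULL, minTailA = 8L) {
  tr <- truthTable(bundle)
  if (is.null(expected)) expected <- tr$expectedTerminusPos
  tx <- as.character(transcriptSeq(bundle))
  Lt <- nchar(tx)
  ends <- integer(0)
  for (i in seq_along(clones)) {
    cl <- dnaToChar(clones[[i]])
    tailA <- nchar(cl) - nchar(sub("A*$", "", cl))
    if (tailA < minTailA) next
    ## anchor the clone body on the transcript; an anchor inside a tandem
    ## repeat can match several times, so keep the placement that explains
    ## the longest body before an all-A remainder
    m <- matchPattern(substr(cl, 1L, 30L), DNAString(tx))
    bestEnd <- NA_integer_
    bestK <- -1L
    for (tpos in start(m)) {
      k <- 0L
      while (tpos + k <= Lt && k < nchar(cl) &&
             substr(cl, k + 1L, k + 1L) == substr(tx, tpos + k, tpos + k)) {
        k <- k + 1L
      }
      rest <- substr(cl, k + 1L, nchar(cl))
      if ((nchar(rest) == 0L || grepl("^A+$", rest)) && k > bestK) {
        bestK <- k
        bestEnd <- tpos + k - 1L
      }
    }
    if (!is.na(bestEnd)) ends <- c(ends, bestEnd)
  }
  if (length(ends) == 0L)
    stop("no clone carries a mappable body with a poly-A tract")
  tab <- table(ends)
  txEnd <- as.integer(names(tab)[which.max(tab)])
  scaffoldPos <- tr$txMapScaffold[txEnd]
  expectedTx <- match(expected, tr$txMapScaffold)
  diffBp <- if (!is.na(expectedTx)) txEnd - expectedTx else NA_integer_
  incl <- if (!is.na(diffBp)) abs(diffBp) + 1L else NA_integer_
  sig <- findPolyASignal(tx, txEnd)
  list(scaffoldPosition = scaffoldPos, txPosition = txEnd,
       offsetInclusive = incl, offsetDifference = diffBp,
       polyASignal = sig, support = max(tab))
}

#' Find the nearest upstream poly-A signal
#'
#' Scans the `window` bases upstream of the terminus for the given hexamers
#' and returns the occurrence nearest the terminus. The distance convention
#' is `terminus - signal end` (a signal whose last base is 21 positions
#' before the terminus has distance 21).
#'
#' @param transcript Transcript sequence.
#' @param terminus Transcript coordinate of the termination site.
#' @param window Scan width upstream of the terminus (default 50, >= 10).
#' @param patterns Candidate signal hexamers.
#' @return NULL if absent, else list(pattern, start, end, distance) in
#'   transcript coordinates.
#' @export
findPolyASignal <- function(transcript, terminus, window = 50L,
                            patterns = "AATAAA") {
  if (window < 10L) stop("window must be >= 10")
  window <- as.integer(window)
  terminus <- as.integer(terminus)
  tx <- toupper(dnaToChar(transcript))
  lo <- max(1L, terminus - window)
  region <- substr(tx, lo, terminus)
  best <- NULL
  for (p in patterns) {
    occ <- gregexpr(p, region, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) next
    for (o in occ) {
      e <- lo + o - 1L + nchar(p) - 1L
      if (e >= terminus) next
      d <- terminus - e
      if (is.null(best) || d < best$distance) {
        best <- list(pattern = p, start = lo + o - 1L, end = e, distance = d)
      }
    }
  }
  best
}

#' Scan a promoter window for IUPAC motifs
#'
#' Reports every match of each degenerate pattern on both strands of the
#' +/- window around the TSS, in no-zero promoter coordinates (an interval
#' may span the missing zero, e.g. -6..+4 for a 10-mer).
#'
#' @param bundle A [ScaffoldBundle-class], or a character promoter window
#'   sequence of length 2*window (index window+1 = TSS base, transcribed
#'   strand).
#' @param patterns Character vector of IUPAC patterns.
#' @param window Half-width in bp (default 2000).
#' @return data.frame(pattern, start, end, strand, match) in promoter
#'   coordinates.
#' @export
scanMotifs <- function(bundle, patterns, window = 2000L) {
  win <- promoterWindowSeq(bundle, window)
  winD <- DNAString(win)
  out <- list()
  for (p in patterns) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") p else revComp(p)
      m <- matchPattern(DNAString(pat), winD, fixed = FALSE)
      if (length(m) == 0L) next
      for (i in seq_along(m)) {
        s <- start(m)[i]
        e <- end(m)[i]
        out[[length(out) + 1L]] <- data.frame(
          pattern = p,
          start = promoterFromLinear(s - window),
          end = promoterFromLinear(e - window),
          strand = str,
          match = as.character(winD[s:e]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pattern = character(), start = integer(),
                      end = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out[order(promoterLinear(out$start)), , drop = FALSE]
}

#' Extract the transcribed-strand promoter window
#'
#' @param bundle A [ScaffoldBundle-class] or a raw window string.
#' @param window Half-width in bp.
#' @return Character window of length 2*window; index `window` is promoter
#'   position -1 and index `window + 1` is +1 (the TSS base).
#' @export
promoterWindowSeq <- function(bundle, window = 2000L) {
  if (is.character(bundle)) {
    if (nchar(bundle) != 2L * window)
      stop("promoter window sequence must have length 2*window")
    return(toupper(bundle))
  }
  tr <- truthTable(bundle)
  u <- tr$upstreamFlank
  if (u < window) stop("upstream flank shorter than the promoter window")
  substr(tr$geneForwardSeq, u - window + 1L, u + window)
}

#' Simulate a restriction digest
#'
#' Cuts the amplicon at every occurrence of the (possibly degenerate)
#' recognition site, `cutOffset` bases into the site (blunt-cut model), and
#' returns the ordered fragment lengths. Fragment lengths always sum to the
#' amplicon length.
#'
#' @param amplicon DNA sequence.
#' @param enzyme list(name, site, cutOffset): recognition site (IUPAC
#'   allowed) and the cut position within the site (cut after base
#'   `cutOffset`).
#' @return list(enzyme, site, cutPositions = 1-based positions of the last
#'   base before each cut, fragmentLengths).
#' @export
digestAmplicon <- function(amplicon, enzyme = list(name = "DraI",
                                                   site = "TTTAAA",
                                                   cutOffset = 3L)) {
  amp <- toupper(dnaToChar(amplicon))
  assertDna(amp, "amplicon")
  m <- matchPattern(DNAString(enzyme$site), DNAString(amp), fixed = FALSE)
  cuts <- sort(unique(start(m) + enzyme$cutOffset - 1L))
  cuts <- cuts[cuts >= 1L & cuts < nchar(amp)]
  bounds <- c(0L, cuts, nchar(amp))
  list(enzyme = enzyme$name, site = enzyme$site, cutPositions = cuts,
       fragmentLengths = diff(bounds))
}
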