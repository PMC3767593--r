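## Exon-intron model assembly from spliced amplicons, splice-site validation,
## N-gap filling and transcript construction.

#' Infer an exon-intron model from a spliced amplicon
#'
#' Explains the amplicon as an ordered concatenation of substrings (exons) of
#' the genomic region, the skipped intervals being introns of at least
#' `minIntron` bp. Both sequences must be given on the transcribed strand.
#' Chaining is greedy longest-prefix with backtracking (amplicons are treated
#' as error-free); ambiguous junctions - identical bases at both intron ends
#' - are then shifted maximally 5', with a canonical GT/AG-consistent shift
#' preferred when one exists.
#'
#' @param genomicRegion Genomic sequence (transcribed strand).
#' @param amplicon Spliced amplicon sequence.
#' @param minIntron Minimum intron length (default 20).
#' @param donor,acceptor Canonical splice dinucleotides used for junction
#'   placement (default GT/AG).
#' @return An [ExonIntronModel-class] in `genomicRegion` coordinates
#'   (strand "+").
#' @export
inferExons <- function(genomicRegion, amplicon, minIntron = 20L,
                       donor = "GT", acceptor = "AG") {
  G <- toupper(dnaToChar(genomicRegion))
  A <- toupper(dnaToChar(amplicon))
  Lg <- nchar(G)
  La <- nchar(A)
  if (minIntron < 20L) stop("minIntron must be >= 20")
  if (La == 0L || Lg == 0L) stop("empty sequence")

  bestReach <- 0L
  failed <- new.env(hash = TRUE, parent = emptyenv())

  search <- function(gi, ai, exons) {
    key <- paste(gi, ai)
    if (!is.null(failed[[key]])) return(NULL)
    m <- commonPrefixLen(substr(G, gi, Lg), substr(A, ai, La))
    if (m > 0L && ai + m - 1L > bestReach) bestReach <<- ai + m - 1L
    if (m > 0L && ai + m - 1L == La) {
      return(c(exons, list(c(gi, gi + m - 1L))))
    }
    if (m > 0L) {
      for (len in m:1L) {
        restA <- ai + len
        anchorLen <- min(12L, La - restA + 1L)
        anchor <- substr(A, restA, restA + anchorLen - 1L)
        minG <- gi + len + minIntron
        if (minG > Lg) next
        occ <- gregexpr(anchor, substr(G, minG, Lg), fixed = TRUE)[[1L]]
        if (occ[1L] == -1L) next
        for (o in occ) {
          res <- search(minG + o - 1L, restA,
                        c(exons, list(c(gi, gi + len - 1L))))
          if (!is.null(res)) return(res)
        }
      }
    }
    failed[[key]] <- TRUE
    NULL
  }

  ## candidate start positions of the first exon
  anchor0 <- substr(A, 1L, min(12L, La))
  occ0 <- gregexpr(anchor0, G, fixed = TRUE)[[1L]]
  if (occ0[1L] == -1L)
    stop(sprintf(
      "amplicon cannot be explained as spliced substrings (explained 0 of %d bp)",
      La))
  chain <- NULL
  for (o in occ0) {
    chain <- search(o, 1L, list())
    if (!is.null(chain)) break
  }
  if (is.null(chain))
    stop(sprintf(
      "amplicon cannot be explained as spliced substrings (best partial explanation: %d of %d bp)",
      bestReach, La))

  ex <- do.call(rbind, chain)
  ex <- canonicalizeJunctions(ex, G, minIntron, donor, acceptor)
  exons <- IRanges(ex[, 1L], ex[, 2L])
  introns <- if (nrow(ex) > 1L) {
    IRanges(ex[-nrow(ex), 2L] + 1L, ex[-1L, 1L] - 1L)
  } else IRanges()
  ExonIntronModel(exons, introns, "+")
}

## Greedy chaining places every junction maximally 3'. For each junction,
## find how far it can shift 5' without changing the spliced product, and
## prefer the most-5' shift whose intron starts/ends with the canonical
## dinucleotides; otherwise take the maximal 5' shift.
canonicalizeJunctions <- function(ex, G, minIntron, donor, acceptor) {
  if (nrow(ex) < 2L) return(ex)
  getS <- function(i, j) substr(G, i, j)
  for (i in seq_len(nrow(ex) - 1L)) {
    ee <- ex[i, 2L]          # exon i end
    ns <- ex[i + 1L, 1L]     # exon i+1 start
    maxT <- ex[i, 2L] - ex[i, 1L]   # keep exon i non-empty
    tmax <- 0L
    while (tmax < maxT &&
           substr(G, ee - tmax, ee - tmax) ==
           substr(G, ns - tmax - 1L, ns - tmax - 1L)) {
      tmax <- tmax + 1L
    }
    shifts <- 0:tmax
    canonical <- vapply(shifts, function(t) {
      getS(ee - t + 1L, ee - t + 2L) == donor &&
        getS(ns - t - 2L, ns - t - 1L) == acceptor
    }, logical(1L))
    t <- if (any(canonical)) max(shifts[canonical]) else tmax
    ex[i, 2L] <- ee - t
    ex[i + 1L, 1L] <- ns - t
  }
  ex
}

#' Validate splice sites of a model
#'
#' Reads the first and last two intron bases on the transcribed strand;
#' an intron is canonical iff (donor, acceptor) equals ("GT", "AG").
#'
#' @param model An [ExonIntronModel-class] (forward-scaffold coordinates).
#' @param scaffold Scaffold sequence (forward strand).
#' @param donor,acceptor Canonical dinucleotides.
#' @return data.frame(intron, donor, acceptor, canonical).
#' @export
validateSpliceSites <- function(model, scaffold, donor = "GT",
                                acceptor = "AG") {
  scaffold <- toupper(dnaToChar(scaffold))
  it <- modelIntrons(model)
  if (any(width(it) < 4L)) stop("intron shorter than 4 nt")
  n <- length(it)
  if (n == 0L) {
    return(data.frame(intron = integer(), donor = character(),
                      acceptor = character(), canonical = logical()))
  }
  don <- character(n)
  acc <- character(n)
  for (i in seq_len(n)) {
    s <- start(it)[i]
    e <- end(it)[i]
    if (modelStrand(model) == "+") {
      don[i] <- substr(scaffold, s, s + 1L)
      acc[i] <- substr(scaffold, e - 1L, e)
    } else {
      don[i] <- revComp(substr(scaffold, e - 1L, e))
      acc[i] <- revComp(substr(scaffold, s, s + 1L))
    }
  }
  data.frame(intron = seq_len(n), donor = don, acceptor = acc,
             canonical = don == donor & acc == acceptor)
}

#' Fill a scaffold N-gap from a bridging amplicon
#'
#' The amplicon must span the single N-run of the region, with its first and
#' last `flank` bases matching the scaffold uniquely and its non-N
#' neighbourhood matching exactly up to the N-run. The amplicon may be given
#' in either orientation.
#'
#' @param scaffold Public scaffold sequence (with the N-run).
#' @param bridgingAmplicon Amplicon spanning the gap.
#' @param flank Anchor length (default 30).
#' @return list(gapInterval = IRanges of the N-run on the input scaffold,
#'   fillSequence, delta = fill length minus placeholder length,
#'   scaffoldFilled = reconstructed scaffold string).
#' @export
fillGap <- function(scaffold, bridgingAmplicon, flank = 30L) {
  sc <- toupper(dnaToChar(scaffold))
  scDNA <- DNAString(sc)
  tryOrient <- function(amp) {
    n <- nchar(amp)
    if (n < 2L * flank) return(NULL)
    pre <- substr(amp, 1L, flank)
    suf <- substr(amp, n - flank + 1L, n)
    mp <- matchPattern(pre, scDNA)
    ms <- matchPattern(suf, scDNA)
    if (length(mp) != 1L || length(ms) != 1L) return(NULL)
    if (start(ms) <= end(mp)) return(NULL)
    list(amp = amp, aStart = start(mp), aEnd = end(ms))
  }
  hit <- tryOrient(toupper(dnaToChar(bridgingAmplicon)))
  if (is.null(hit)) hit <- tryOrient(revComp(toupper(dnaToChar(bridgingAmplicon))))
  if (is.null(hit))
    stop("amplicon flanks not found (or ambiguous) on the scaffold")

  region <- substr(sc, hit$aStart, hit$aEnd)
  runs <- gregexpr("N+", region)[[1L]]
  if (runs[1L] == -1L || length(runs) != 1L)
    stop("the spanned region must contain exactly one N-run")
  nStart <- hit$aStart + runs[1L] - 1L
  nLen <- attr(runs, "match.length")[1L]
  leftLen <- nStart - hit$aStart
  rightLen <- hit$aEnd - (nStart + nLen - 1L)
  fill <- substr(hit$amp, leftLen + 1L, nchar(hit$amp) - rightLen)
  if (grepl("N", fill, fixed = TRUE))
    stop("gap fill still contains N")
  if (substr(hit$amp, 1L, leftLen) != substr(sc, hit$aStart, nStart - 1L) ||
      substr(hit$amp, nchar(hit$amp) - rightLen + 1L, nchar(hit$amp)) !=
        substr(sc, nStart + nLen, hit$aEnd))
    stop("amplicon disagrees with the scaffold outside the N-run")
  filled <- paste0(substr(sc, 1L, nStart - 1L), fill,
                   substr(sc, nStart + nLen, nchar(sc)))
  list(gapInterval = IRanges(nStart, nStart + nLen - 1L),
       fillSequence = fill,
       delta = nchar(fill) - nLen,
       scaffoldFilled = filled)
}

#' Build the spliced transcript from a model
#'
#' Concatenates exon sequences 5'->3' on the transcribed strand and records
#' the transcript-to-scaffold coordinate bijection (for a minus-strand gene,
#' transcript position t maps to scaffold position tss - t + 1 within each
#' exon).
#'
#' @param model An [ExonIntronModel-class] (forward-scaffold coordinates,
#'   exons in transcript order).
#' @param scaffold Scaffold sequence (forward strand, gap already filled).
#' @return A [TranscriptRecord-class].
#' @export
buildTranscript <- function(model, scaffold) {
  sc <- toupper(dnaToChar(scaffold))
  ex <- modelExons(model)
  pieces <- character(length(ex))
  mapChunks <- vector("list", length(ex))
  for (i in seq_along(ex)) {
    s <- start(ex)[i]
    e <- end(ex)[i]
    seqI <- substr(sc, s, e)
    if (grepl("N", seqI, fixed = TRUE))
      stop(sprintf("exon %d still contains N", i))
    if (modelStrand(model) == "+") {
      pieces[i] <- seqI
      mapChunks[[i]] <- s:e
    } else {
      pieces[i] <- revComp(seqI)
      mapChunks[[i]] <- e:s
    }
  }
  lens <- width(ex)
  new("TranscriptRecord",
      sequence = DNAString(paste(pieces, collapse = "")),
      exonBoundaries = if (length(ex) > 1L)
        as.integer(cumsum(lens)[-length(lens)]) else integer(),
      coordMap = as.integer(unlist(mapChunks)),
      strand = modelStrand(model))
}

#' Transcript coordinate(s) -> scaffold position(s)
#' @param record A [TranscriptRecord-class].
#' @param t Transcript positions.
#' @export
txToScaffold <- function(record, t) record@coordMap[t]

#' Scaffold position(s) -> transcript coordinate(s) (NA outside exons)
#' @param record A [TranscriptRecord-class].
#' @param s Forward-scaffold positions.
#' @export
scaffoldToTx <- function(record, s) match(s, record@coordMap)

#' Summarise a model as an exon/intron table
#'
#' One row per exon and intron in gene order, with the first and last 8
#' transcribed-strand bases and the length, followed by totals rows for the
#' transcript (exon rows) and the gene span (all rows).
#'
#' @param model An [ExonIntronModel-class].
#' @param scaffold Scaffold sequence (forward strand).
#' @return data.frame(feature, first8, last8, length).
#' @export
summarizeModel <- function(model, scaffold) {
  sc <- toupper(dnaToChar(scaffold))
  minus <- modelStrand(model) == "-"
  featSeq <- function(iv) {
    s <- substr(sc, start(iv), end(iv))
    if (minus) revComp(s) else s
  }
  ex <- modelExons(model)
  it <- modelIntrons(model)
  rows <- list()
  for (i in seq_along(ex)) {
    s <- featSeq(ex[i])
    rows[[length(rows) + 1L]] <- data.frame(
      feature = sprintf("Exon %d", i),
      first8 = substr(s, 1L, 8L),
      last8 = substr(s, max(1L, nchar(s) - 7L), nchar(s)),
      length = nchar(s), stringsAsFactors = FALSE)
    if (i <= length(it)) {
      s <- featSeq(it[i])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = sprintf("Intron %d", i),
        first8 = substr(s, 1L, 8L),
        last8 = substr(s, max(1L, nchar(s) - 7L), nchar(s)),
        length = nchar(s), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rbind(out,
        data.frame(feature = "Transcript (exons)", first8 = "", last8 = "",
                   length = sum(width(ex)), stringsAsFactors = FALSE),
        data.frame(feature = "Gene span", first8 = "", last8 = "",
                   length = sum(width(ex)) + sum(width(it)),
                   stringsAsFactors = FALSE))
}

#' Lift a region-coordinate model onto the scaffold
#'
#' [inferExons()] works on a transcribed-strand genomic region; this helper
#' converts its model into forward-scaffold coordinates for a gene whose
#' transcribed-strand region starts at forward-scaffold position
#' `regionStart` ("+" genes) or ends at `regionEnd` ("-" genes, where region
#' position 1 corresponds to the highest scaffold coordinate).
#'
#' @param model Model in region coordinates (strand "+").
#' @param strand Gene strand on the scaffold.
#' @param regionStart Forward-scaffold position of region base 1 (for "+").
#' @param regionEnd Forward-scaffold position of region base 1 (for "-",
#'   i.e. the scaffold coordinate that region position 1 maps to).
#' @return An [ExonIntronModel-class] in forward-scaffold coordinates.
#' @export
liftModel <- function(model, strand, regionStart = 1L, regionEnd = NULL) {
  ex <- modelExons(model)
  it <- modelIntrons(model)
  if (strand == "+") {
    off <- regionStart - 1L
    ExonIntronModel(IRanges(start(ex) + off, end(ex) + off),
                    if (length(it)) IRanges(start(it) + off, end(it) + off)
                    else IRanges(), "+")
  } else {
    stopifnot(!is.null(regionEnd))
    flip <- function(iv) {
      if (length(iv) == 0L) return(IRanges())
      IRanges(regionEnd - end(iv) + 1L, regionEnd - start(iv) + 1L)
    }
    ExonIntronModel(flip(ex), flip(it), "-")
  }
}
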