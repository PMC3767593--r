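## Central S4 containers. Result tables of individual operations are plain
## DataFrame/data.frame/list values; the classes below hold the objects that
## flow between pipeline stages.

#' RepeatSpec: specification of one planted tandem-repeat array
#'
#' Describes a head-to-tail repeat array to be planted into the synthetic
#' transcript: monomer length (period), fractional copy number (a trailing
#' partial copy of `round(frac * period)` bases is planted), per-base
#' substitution divergence of the copies relative to the consensus monomer,
#' and the transcript coordinate of the first base. `monomerCpg` lists monomer
#' positions (1-based, position of the C) at which the monomer carries a CG
#' dinucleotide; arrays inside the promoter CpG window must declare their CGs
#' this way so the window-wide CpG accounting stays exact.
#'
#' @slot monomerLength integer, period in bp (>= 2).
#' @slot copies numeric, fractional copy number (>= 2 for plantable arrays).
#' @slot spacerLength integer, bases between copies (0 = head-to-tail).
#' @slot divergence numeric in [0, 0.3], per-base substitution probability.
#' @slot transcriptStart integer, 1-based transcript coordinate of the array.
#' @slot monomer character, optional fixed monomer sequence ("" = generate).
#' @slot monomerCpg integer, monomer positions carrying a CG.
#' @exportClass RepeatSpec
setClass("RepeatSpec",
  representation(
    monomerLength = "integer",
    copies = "numeric",
    spacerLength = "integer",
    divergence = "numeric",
    transcriptStart = "integer",
    monomer = "character",
    monomerCpg = "integer"
  )
)

setValidity("RepeatSpec", function(object) {
  msg <- character()
  if (object@monomerLength < 2L) msg <- c(msg, "monomerLength must be >= 2")
  if (object@copies < 2) msg <- c(msg, "copies must be >= 2 for plantable arrays")
  if (object@divergence < 0 || object@divergence > 0.3)
    msg <- c(msg, "divergence must lie in [0, 0.3]")
  if (object@spacerLength < 0L) msg <- c(msg, "spacerLength must be >= 0")
  if (object@transcriptStart < 1L) msg <- c(msg, "transcriptStart must be >= 1")
  if (nzchar(object@monomer) && nchar(object@monomer) != object@monomerLength)
    msg <- c(msg, "monomer length does not equal monomerLength")
  if (length(msg) > 0L) msg else TRUE
})

#' Create a RepeatSpec
#'
#' @param monomerLength Period in bp.
#' @param copies Fractional copy number (e.g. 91.7).
#' @param transcriptStart 1-based transcript coordinate of the first base.
#' @param divergence Per-base substitution probability of copies vs consensus.
#' @param spacerLength Bases between copies (0 for head-to-tail).
#' @param monomer Optional fixed monomer sequence.
#' @param monomerCpg Monomer positions (C of a CG) carrying CG dinucleotides.
#' @return A [RepeatSpec-class] object.
#' @export
RepeatSpec <- function(monomerLength, copies, transcriptStart,
                       divergence = 0, spacerLength = 0L,
                       monomer = "", monomerCpg = integer()) {
  new("RepeatSpec",
      monomerLength = as.integer(monomerLength), copies = as.numeric(copies),
      spacerLength = as.integer(spacerLength), divergence = as.numeric(divergence),
      transcriptStart = as.integer(transcriptStart),
      monomer = as.character(monomer), monomerCpg = as.integer(monomerCpg))
}

#' GeneSpec: blueprint of the synthetic lncRNA locus
#'
#' Declares every feature the scaffold generator plants: exon/intron lengths
#' (exons = introns + 1), strand (default minus, with the TSS at the high
#' scaffold coordinate), flank lengths, tandem-repeat arrays, promoter CpG
#' offsets (no-zero coordinates; every CG within the +/- `promoterWindow`
#' region occurs exactly at these offsets), per-sex methylation probabilities,
#' an N-gap (placeholder length on the public scaffold, true fill length in
#' the ground truth), canonical splice dinucleotides, the poly-A signal and
#' its distance upstream of the terminus, promoter motif plants, and the
#' inclusive offset between the homology-expected and true termination sites.
#'
#' @slot exonLengths,intronLengths integer vectors of feature lengths (bp).
#' @slot strand "+" or "-".
#' @slot flankLengths named integer (upstream, downstream) in transcription sense.
#' @slot repeatSpecs list of [RepeatSpec-class].
#' @slot promoterCpgOffsets strictly increasing integer offsets, no 0.
#' @slot methylProfile named list (male, female) of per-site methylation
#'   probabilities (scalars are recycled over analysed sites).
#' @slot gap list(intron, fillLength, placeholder): which intron carries the
#'   N-gap, the true fill length and the public placeholder N-run length.
#' @slot spliceDonor,spliceAcceptor intron-terminal dinucleotides.
#' @slot polyASignal list(hexamer, upstream): signal sequence and its distance
#'   (terminus minus signal end) upstream of the termination site.
#' @slot motifPlants list of list(pattern, instance, start): IUPAC pattern, the
#'   concrete planted instance and its promoter start offset.
#' @slot promoterWindow half-width of the CpG search window (bp).
#' @slot terminusShift inclusive offset between expected and true terminus.
#' @exportClass GeneSpec
setClass("GeneSpec",
  representation(
    exonLengths = "integer",
    intronLengths = "integer",
    strand = "character",
    flankLengths = "integer",
    repeatSpecs = "list",
    promoterCpgOffsets = "integer",
    methylProfile = "list",
    gap = "list",
    spliceDonor = "character",
    spliceAcceptor = "character",
    polyASignal = "list",
    motifPlants = "list",
    promoterWindow = "integer",
    terminusShift = "integer"
  )
)

setValidity("GeneSpec", function(object) {
  msg <- character()
  ne <- length(object@exonLengths)
  ni <- length(object@intronLengths)
  if (ne != ni + 1L)
    msg <- c(msg, "length(exonLengths) must equal length(intronLengths) + 1")
  if (any(c(object@exonLengths, object@intronLengths) <= 0L))
    msg <- c(msg, "all exon and intron lengths must be > 0")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (nchar(object@spliceDonor) != 2L || nchar(object@spliceAcceptor) != 2L)
    msg <- c(msg, "splice donor/acceptor must be dinucleotides")
  off <- object@promoterCpgOffsets
  if (any(off == 0L)) msg <- c(msg, "promoter CpG offsets must not contain 0")
  if (is.unsorted(off, strictly = TRUE))
    msg <- c(msg, "promoter CpG offsets must be strictly increasing")
  ## repeat arrays: disjoint transcript intervals, each inside one exon
  if (length(object@repeatSpecs) > 0L) {
    ivs <- do.call(rbind, lapply(object@repeatSpecs, function(r) {
      span <- repeatSpan(r)
      c(r@transcriptStart, r@transcriptStart + span - 1L)
    }))
    o <- order(ivs[, 1L])
    ivs <- ivs[o, , drop = FALSE]
    if (nrow(ivs) > 1L && any(ivs[-1L, 1L] <= ivs[-nrow(ivs), 2L]))
      msg <- c(msg, "repeat arrays overlap in transcript coordinates")
    bnd <- cumsum(object@exonLengths)
    exonIdx <- function(t) findInterval(t - 1L, c(0L, bnd))
    if (any(exonIdx(ivs[, 1L]) != exonIdx(ivs[, 2L])) ||
        any(ivs[, 2L] > sum(object@exonLengths)))
      msg <- c(msg, "each repeat array must lie inside a single exon")
  }
  up <- object@flankLengths[["upstream"]]
  if (up < object@promoterWindow)
    msg <- c(msg, "upstream flank must cover the promoter window")
  if (length(msg) > 0L) msg else TRUE
})

## Planted span of a repeat array in bp (full copies + partial tail + spacers).
repeatSpan <- function(r) {
  full <- floor(r@copies)
  part <- round((r@copies - full) * r@monomerLength)
  as.integer(full * r@monomerLength + part +
             (full - 1L + (part > 0L)) * r@spacerLength)
}

#' ScaffoldBundle: synthetic scaffold plus ground truth
#'
#' The public scaffold (`scaffoldSeq`, carrying the N-run placeholder at the
#' gap), the spliced transcript, the generating [GeneSpec-class] and a `truth`
#' list recording every planted coordinate and state (exon/intron scaffold
#' intervals on the gap-filled scaffold, TSS/terminus positions, repeat
#' truth, CpG offsets, bisulfite amplicon regions, gap fill, poly-A signal
#' and motif intervals). All truth coordinates refer to the gap-filled
#' scaffold; the public scaffold differs only inside the gap interval.
#'
#' @slot scaffoldSeq DNAString, public scaffold with the N-run.
#' @slot transcriptSeq DNAString, spliced transcript (RNA as DNA).
#' @slot spec the generating [GeneSpec-class].
#' @slot truth list of planted features (see [truthTable()]).
#' @exportClass ScaffoldBundle
setClass("ScaffoldBundle",
  representation(
    scaffoldSeq = "DNAString",
    transcriptSeq = "DNAString",
    spec = "GeneSpec",
    truth = "list"
  )
)

setValidity("ScaffoldBundle", function(object) {
  msg <- character()
  sp <- object@spec
  if (length(object@transcriptSeq) != sum(sp@exonLengths))
    msg <- c(msg, "transcript length must equal sum of exon lengths")
  tr <- object@truth
  span <- sum(sp@exonLengths) + sum(sp@intronLengths)
  if (sum(width(tr$exons)) + sum(width(tr$introns)) != span)
    msg <- c(msg, "exon+intron scaffold intervals must tile the gene span")
  if (length(msg) > 0L) msg else TRUE
})

#' ExonIntronModel: ordered exon/intron intervals on the scaffold
#'
#' Exons and introns are stored in transcript order as IRanges on the forward
#' scaffold strand (1-based inclusive); for a minus-strand gene the intervals
#' therefore descend along the scaffold. They strictly alternate and tile the
#' gene span.
#'
#' @slot exons,introns IRanges in transcript order on forward scaffold coords.
#' @slot strand "+" or "-".
#' @exportClass ExonIntronModel
setClass("ExonIntronModel",
  representation(exons = "IRanges", introns = "IRanges", strand = "character")
)

setValidity("ExonIntronModel", function(object) {
  msg <- character()
  ne <- length(object@exons)
  ni <- length(object@introns)
  if (ne != ni + 1L) msg <- c(msg, "need one more exon than introns")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  ## alternation/tiling on the forward strand
  if (ni > 0L) {
    ex <- object@exons
    it <- object@introns
    ok <- TRUE
    for (i in seq_len(ni)) {
      if (object@strand == "+") {
        ok <- ok && start(it)[i] == end(ex)[i] + 1L &&
          start(ex)[i + 1L] == end(it)[i] + 1L
      } else {
        ok <- ok && end(it)[i] == start(ex)[i] - 1L &&
          end(ex)[i + 1L] == start(it)[i] - 1L
      }
    }
    if (!ok) msg <- c(msg, "exons and introns must alternate and tile the span")
  }
  if (length(msg) > 0L) msg else TRUE
})

ExonIntronModel <- function(exons, introns, strand) {
  new("ExonIntronModel", exons = exons, introns = introns,
      strand = as.character(strand))
}

#' TranscriptRecord: spliced transcript with its scaffold coordinate map
#'
#' @slot sequence DNAString, exons concatenated 5'->3' on the transcribed strand.
#' @slot exonBoundaries integer, transcript coordinates of the last base of
#'   each non-terminal exon (junction positions).
#' @slot coordMap integer vector: `coordMap[t]` is the forward-scaffold
#'   position of transcript position `t` (a bijection on exonic positions).
#' @slot strand "+" or "-".
#' @exportClass TranscriptRecord
setClass("TranscriptRecord",
  representation(sequence = "DNAString", exonBoundaries = "integer",
                 coordMap = "integer", strand = "character")
)

setValidity("TranscriptRecord", function(object) {
  msg <- character()
  if (length(object@sequence) != length(object@coordMap))
    msg <- c(msg, "coordMap must cover every transcript position")
  if (anyDuplicated(object@coordMap))
    msg <- c(msg, "coordMap must be a bijection on exonic positions")
  if (length(msg) > 0L) msg else TRUE
})

#' BisulfiteCallMatrix: clones x CpG-sites methylation calls
#'
#' Integer matrix with 1 = methylated, 0 = unmethylated, NA = missing (site
#' not covered by the clone or ambiguous base). Columns are named by promoter
#' offset; per-clone conversion QC (fraction of non-CpG cytosines converted)
#' and the count of clones excluded by the QC filter travel with the matrix.
#'
#' @slot calls integer matrix, clones x sites.
#' @slot sites integer, promoter offsets of the columns.
#' @slot conversionQC numeric, per-clone non-CpG C conversion fraction.
#' @slot excluded integer, clones dropped (failed QC or unmappable).
#' @exportClass BisulfiteCallMatrix
setClass("BisulfiteCallMatrix",
  representation(calls = "matrix", sites = "integer",
                 conversionQC = "numeric", excluded = "integer")
)

setValidity("BisulfiteCallMatrix", function(object) {
  msg <- character()
  if (ncol(object@calls) != length(object@sites))
    msg <- c(msg, "column count must equal site count")
  if (nrow(object@calls) != length(object@conversionQC))
    msg <- c(msg, "conversionQC must have one entry per clone")
  v <- object@calls[!is.na(object@calls)]
  if (length(v) > 0L && !all(v %in% c(0L, 1L)))
    msg <- c(msg, "calls must be 0, 1 or NA")
  qc <- object@conversionQC[!is.na(object@conversionQC)]
  if (length(qc) > 0L && (any(qc < 0) || any(qc > 1)))
    msg <- c(msg, "conversion QC fractions must lie in [0, 1]")
  if (length(msg) > 0L) msg else TRUE
})

#' Construct a BisulfiteCallMatrix
#'
#' @param calls Integer matrix (1/0/NA), clones x sites.
#' @param sites Promoter offsets of the columns.
#' @param conversionQC Per-clone non-CpG C conversion fraction (default 1).
#' @param excluded Number of excluded clones.
#' @return A [BisulfiteCallMatrix-class].
#' @export
BisulfiteCallMatrix <- function(calls, sites,
                                conversionQC = rep(1, nrow(calls)),
                                excluded = 0L) {
  mode(calls) <- "integer"
  colnames(calls) <- as.character(sites)
  new("BisulfiteCallMatrix", calls = calls, sites = as.integer(sites),
      conversionQC = as.numeric(conversionQC), excluded = as.integer(excluded))
}

#' RepeatRegion: one detected tandem-repeat region
#'
#' @slot interval integer(2), 1-based inclusive transcript interval.
#' @slot period integer, monomer length in bp.
#' @slot copyNumber numeric, span/period rounded half-up to 1 decimal.
#' @slot consensus character, per-column majority monomer.
#' @slot meanIdentity numeric, mean per-copy identity vs the consensus.
#' @slot copies data.frame with per-copy start, end, identity.
#' @exportClass RepeatRegion
setClass("RepeatRegion",
  representation(interval = "integer", period = "integer",
                 copyNumber = "numeric", consensus = "character",
                 meanIdentity = "numeric", copies = "data.frame")
)

setValidity("RepeatRegion", function(object) {
  msg <- character()
  if (object@period < 2L) msg <- c(msg, "period must be >= 2")
  if (object@copyNumber < 2) msg <- c(msg, "reported regions need >= 2 copies")
  span <- diff(object@interval) + 1L
  if (abs(span / object@period - object@copyNumber) > 0.05 + 1e-9)
    msg <- c(msg, "span/period must round to copyNumber at 1 decimal")
  if (length(msg) > 0L) msg else TRUE
})

## ---- accessors & show ------------------------------------------------------

#' @describeIn ScaffoldBundle-class public scaffold sequence (with N-gap).
#' @param bundle A [ScaffoldBundle-class].
#' @export
scaffoldSeq <- function(bundle) bundle@scaffoldSeq

#' @describeIn ScaffoldBundle-class spliced transcript sequence.
#' @export
transcriptSeq <- function(bundle) bundle@transcriptSeq

#' @describeIn ScaffoldBundle-class ground-truth feature list.
#' @export
truthTable <- function(bundle) bundle@truth

#' @describeIn ScaffoldBundle-class the generating GeneSpec.
#' @export
geneSpec <- function(bundle) bundle@spec

#' Exon intervals of a model
#' @param x An [ExonIntronModel-class].
#' @return IRanges of exons in transcript order (forward-scaffold coords).
#' @export
modelExons <- function(x) x@exons

#' Intron intervals of a model
#' @param x An [ExonIntronModel-class].
#' @return IRanges of introns in transcript order.
#' @export
modelIntrons <- function(x) x@introns

#' Strand of a model
#' @param x An [ExonIntronModel-class].
#' @export
modelStrand <- function(x) x@strand

#' Methylation call matrix
#' @param x A [BisulfiteCallMatrix-class].
#' @return Integer matrix clones x sites (1/0/NA).
#' @export
methCalls <- function(x) x@calls

#' Promoter offsets of the call-matrix sites
#' @param x A [BisulfiteCallMatrix-class].
#' @export
methSites <- function(x) x@sites

setMethod("show", "GeneSpec", function(object) {
  cat(sprintf("GeneSpec: %d exons / %d introns, strand '%s'\n",
              length(object@exonLengths), length(object@intronLengths),
              object@strand))
  cat(sprintf("  transcript %d bp, gene span %d bp\n",
              sum(object@exonLengths),
              sum(object@exonLengths) + sum(object@intronLengths)))
  cat(sprintf("  %d repeat arrays, %d promoter CpG offsets (+/- %d bp window)\n",
              length(object@repeatSpecs), length(object@promoterCpgOffsets),
              object@promoterWindow))
})

setMethod("show", "ScaffoldBundle", function(object) {
  cat(sprintf("ScaffoldBundle: scaffold %d bp (gap placeholder %d N), transcript %d bp\n",
              length(object@scaffoldSeq), object@spec@gap$placeholder,
              length(object@transcriptSeq)))
  cat(sprintf("  strand '%s', TSS at scaffold %d, terminus at %d\n",
              object@spec@strand, object@truth$tssPos, object@truth$terminusPos))
})

setMethod("show", "ExonIntronModel", function(object) {
  cat(sprintf("ExonIntronModel: %d exons, %d introns, strand '%s'\n",
              length(object@exons), length(object@introns), object@strand))
})

setMethod("show", "TranscriptRecord", function(object) {
  cat(sprintf("TranscriptRecord: %d bp, %d junctions, strand '%s'\n",
              length(object@sequence), length(object@exonBoundaries),
              object@strand))
})

setMethod("show", "BisulfiteCallMatrix", function(object) {
  cat(sprintf("BisulfiteCallMatrix: %d clones x %d sites (%d excluded)\n",
              nrow(object@calls), ncol(object@calls), object@excluded))
})

setMethod("show", "RepeatRegion", function(object) {
  cat(sprintf("RepeatRegion: +%d..+%d, period %d bp, %.1f copies, identity %.3f\n",
              object@interval[1L], object@interval[2L], object@period,
              object@copyNumber, object@meanIdentity))
})
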