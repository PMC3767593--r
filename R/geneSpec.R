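#' Create a GeneSpec
#'
#' Low-level constructor; most users start from [deskGeneSpec()] (fast
#' default locus) or [paperScaleGeneSpec()] (full-size locus whose exon and
#' intron lengths reproduce the published porcine XIST table).
#'
#' @param exonLengths,intronLengths Integer vectors of lengths in bp
#'   (one more exon than introns).
#' @param strand "+" or "-" (default "-": TSS at the high scaffold coordinate).
#' @param flankLengths Named integer vector c(upstream=, downstream=) in the
#'   transcription sense; upstream must cover `promoterWindow`.
#' @param repeatSpecs List of [RepeatSpec()] arrays (transcript coordinates).
#' @param promoterCpgOffsets Strictly increasing promoter offsets (no 0) at
#'   which - and only at which - CG dinucleotides occur within the window.
#' @param methylProfile Named list with elements `male` and `female`:
#'   per-site methylation probabilities (scalars recycled).
#' @param gap list(intron=, fillLength=, placeholder=): intron index carrying
#'   the N-gap, true fill length and placeholder N-run length.
#' @param spliceDonor,spliceAcceptor Intron-terminal dinucleotides.
#' @param polyASignal list(hexamer=, upstream=): poly-A signal and its
#'   distance (terminus position minus signal end) upstream of the terminus.
#' @param motifPlants List of list(pattern=, instance=, start=): IUPAC
#'   pattern, planted instance, promoter start offset.
#' @param promoterWindow Half-width of the CpG window (default 2000 bp).
#' @param terminusShift Inclusive offset between the homology-expected and the
#'   true termination site (default 10, i.e. expected..true spans 10 bases).
#' @return A validated [GeneSpec-class].
#' @export
GeneSpec <- function(exonLengths, intronLengths,
                     strand = "-",
                     flankLengths = c(upstream = 2300L, downstream = 400L),
                     repeatSpecs = list(),
                     promoterCpgOffsets = integer(),
                     methylProfile = list(male = 0.96, female = 0.50),
                     gap = list(intron = NA_integer_, fillLength = 0L,
                                placeholder = 0L),
                     spliceDonor = "GT", spliceAcceptor = "AG",
                     polyASignal = list(hexamer = "AATAAA", upstream = 21L),
                     motifPlants = list(),
                     promoterWindow = 2000L,
                     terminusShift = 10L) {
  new("GeneSpec",
      exonLengths = as.integer(exonLengths),
      intronLengths = as.integer(intronLengths),
      strand = strand,
      flankLengths = setNames(as.integer(flankLengths),
                              c("upstream", "downstream")),
      repeatSpecs = repeatSpecs,
      promoterCpgOffsets = as.integer(promoterCpgOffsets),
      methylProfile = methylProfile,
      gap = gap,
      spliceDonor = spliceDonor, spliceAcceptor = spliceAcceptor,
      polyASignal = polyASignal,
      motifPlants = motifPlants,
      promoterWindow = as.integer(promoterWindow),
      terminusShift = as.integer(terminusShift))
}

## Shared promoter layout: 78 CGs in the +/-2 kb window, 67 of them dense
## (13 between -284 and +53, 54 between +285 and +1727), mirroring the
## published site counts. Eight of the dense sites sit inside the 24-mer
## repeat array at +327 (one CG per monomer copy, monomer position 11).
defaultCpgOffsets <- function() {
  upstreamSparse <- c(-1950L, -1900L, -1500L, -1450L, -1100L, -1050L,
                      -700L, -650L, -490L)
  dense1 <- c(-284L, -250L, -220L, -190L, -160L, -130L, -100L, -70L, -40L,
              -5L, 20L, 35L, 53L)
  inRepeat <- 327L + 10L + 24L * 0:7            # CG at monomer position 11
  dense2 <- c(285L, 300L, inRepeat,
              as.integer(round(seq(560L, 1727L, length.out = 44L))))
  downstreamSparse <- c(1940L, 1990L)
  sort(c(upstreamSparse, dense1, dense2, downstreamSparse))
}

## Promoter motif plants shared by both presets: a TATA-box-binding-protein
## consensus at -30..-25 and a YY1 site instance spanning the missing zero.
defaultMotifPlants <- function() {
  list(
    list(pattern = "TTAAAG", instance = "TTAAAG", start = -30L),
    list(pattern = "CCGCCATNTT", instance = "CCGCCATATT", start = -6L)
  )
}

## 24-mer monomer for the 5' (A-type) repeat region: CG-free except one CG at
## positions 11-12 and junction-safe (does not start with G or end with C),
## so the tandem array contributes exactly one CpG site per copy.
aRepeatMonomer <- function() "TATTAGACAACGATTACCATTAGA"

#' Desk-scale default GeneSpec
#'
#' A minus-strand, 7-exon locus small enough for routine testing: exons
#' c(3200, 89, 136, 209, 329, 129, 714) bp and introns a tenth of the
#' published lengths. Exon 1 is kept larger than the +/-2 kb promoter window
#' so that - as in the real locus - only the first (24-mer) repeat region lies
#' inside the CpG window; repeat regions 2-4 are planted beyond +2000. The
#' CpG layout reproduces the published counts (78 total, 13 + 54 dense), the
#' N-gap sits in intron 2 (80 bp fill vs 20 N placeholder) and the poly-A
#' signal ends 21 bp upstream of the terminus.
#'
#' @param divergence3 Per-base divergence of the 96-mer array (default 0.10).
#' @return A [GeneSpec-class].
#' @export
deskGeneSpec <- function(divergence3 = 0.10) {
  GeneSpec(
    exonLengths = c(3200L, 89L, 136L, 209L, 329L, 129L, 714L),
    intronLengths = c(146L, 227L, 214L, 36L, 39L, 99L),
    repeatSpecs = list(
      RepeatSpec(24L, 8.0, 327L, divergence = 0,
                 monomer = aRepeatMonomer(), monomerCpg = 11L),
      RepeatSpec(6L, 23.0, 2060L, divergence = 0),
      RepeatSpec(96L, 9.7, 2230L, divergence = divergence3),
      RepeatSpec(149L, 2.0, 4350L, divergence = 0)
    ),
    promoterCpgOffsets = defaultCpgOffsets(),
    gap = list(intron = 2L, fillLength = 80L, placeholder = 20L),
    motifPlants = defaultMotifPlants()
  )
}

#' Paper-scale GeneSpec
#'
#' Full-size preset: exon lengths c(17184, 89, 136, 209, 329, 129, 7139) and
#' intron lengths c(1460, 2271, 2136, 356, 390, 989), so the transcript sums
#' to 25,215 bp and the gene span to 32,817 bp. Repeat arrays are planted at
#' the published transcript coordinates (24-mer x 8 at +327, 6-mer x 23 at
#' +2723, 96-mer x 91.7 at +4302, 149-mer x 2 at +24059), the N-gap in intron
#' 2 uses the published 626-bp fill against a 100-bp placeholder, and the
#' promoter CpG/motif layout matches [deskGeneSpec()].
#'
#' @param divergence3 Per-base divergence of the 96-mer array (default 0.10).
#' @return A [GeneSpec-class].
#' @export
paperScaleGeneSpec <- function(divergence3 = 0.10) {
  GeneSpec(
    exonLengths = c(17184L, 89L, 136L, 209L, 329L, 129L, 7139L),
    intronLengths = c(1460L, 2271L, 2136L, 356L, 390L, 989L),
    repeatSpecs = list(
      RepeatSpec(24L, 8.0, 327L, divergence = 0,
                 monomer = aRepeatMonomer(), monomerCpg = 11L),
      RepeatSpec(6L, 23.0, 2723L, divergence = 0),
      RepeatSpec(96L, 91.7, 4302L, divergence = divergence3),
      RepeatSpec(149L, 2.0, 24059L, divergence = 0)
    ),
    promoterCpgOffsets = defaultCpgOffsets(),
    gap = list(intron = 2L, fillLength = 626L, placeholder = 100L),
    motifPlants = defaultMotifPlants()
  )
}
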