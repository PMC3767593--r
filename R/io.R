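## File interfaces: FASTA/FASTQ via Biostrings, BED/GFF3/bedGraph via
## rtracklayer, truth and summary tables as TSV, GeneSpec as a flat
## key=value config.

#' Write a DNAStringSet as FASTA
#' @param x [Biostrings::DNAStringSet].
#' @param file Output path.
#' @export
writeFasta <- function(x, file) {
  writeXStringSet(x, filepath = file, format = "fasta")
  invisible(file)
}

#' Write reads as FASTQ with constant quality
#' @param reads [Biostrings::DNAStringSet].
#' @param file Output path.
#' @param quality Constant Phred character (default "I", Q40).
#' @export
writeFastq <- function(reads, file, quality = "I") {
  q <- PhredQuality(vapply(width(reads), function(w) strrep(quality, w), ""))
  writeXStringSet(reads, filepath = file, format = "fastq", qualities = q)
  invisible(file)
}

#' Write the bundle's planted features as BED and the truth table as TSV
#'
#' BED intervals are 0-based half-open on the public scaffold is not
#' possible for gap-shifted features, so all coordinates refer to the
#' gap-filled scaffold (recorded in the companion FASTA).
#'
#' @param bundle A [ScaffoldBundle-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- truthTable(bundle)
  fa <- file.path(dir, "scaffold.fa")
  writeFasta(DNAStringSet(c(scaffold = as.character(scaffoldSeq(bundle)),
                            scaffold_filled = tr$scaffoldFilled,
                            transcript = as.character(transcriptSeq(bundle)))),
             fa)
  feats <- rbind(
    data.frame(type = "exon", start = start(tr$exons), end = end(tr$exons),
               name = sprintf("exon%d", seq_along(tr$exons))),
    if (length(tr$introns) > 0L)
      data.frame(type = "intron", start = start(tr$introns),
                 end = end(tr$introns),
                 name = sprintf("intron%d", seq_along(tr$introns))),
    data.frame(type = "tss", start = tr$tssPos, end = tr$tssPos,
               name = "tss"),
    data.frame(type = "terminus", start = tr$terminusPos,
               end = tr$terminusPos, name = "terminus"),
    if (length(tr$gap$filledInterval) > 0L)
      data.frame(type = "gap_fill", start = start(tr$gap$filledInterval),
                 end = end(tr$gap$filledInterval), name = "gap_fill")
  )
  tsv <- file.path(dir, "truth.tsv")
  write.table(feats, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- file.path(dir, "truth.bed")
  gr <- GRanges("scaffold_filled", IRanges(feats$start, feats$end),
                strand = tr$strand)
  gr$name <- feats$name
  rtracklayer::export(gr, bed, format = "BED")
  invisible(c(fa, tsv, bed))
}

#' Export an exon-intron model as GFF3
#'
#' One gene feature plus one exon feature per exon, 1-based inclusive, on
#' the given sequence name.
#'
#' @param model An [ExonIntronModel-class].
#' @param file Output path.
#' @param seqname Scaffold name (default "scaffold").
#' @param geneId Gene identifier.
#' @export
writeModelGff3 <- function(model, file, seqname = "scaffold",
                           geneId = "lncRNA_gene") {
  ex <- modelExons(model)
  lo <- min(start(ex))
  hi <- max(end(ex))
  gr <- GRanges(seqname,
                IRanges(c(lo, start(ex)), c(hi, end(ex))),
                strand = modelStrand(model))
  gr$type <- c("gene", rep("exon", length(ex)))
  gr$ID <- c(geneId, sprintf("%s:exon%d", geneId, seq_along(ex)))
  gr$Parent <- c(NA_character_, rep(geneId, length(ex)))
  rtracklayer::export(gr, file, format = "GFF3")
  invisible(file)
}

#' Export a coverage track as bedGraph
#' @param track Result of [coverageTrack()].
#' @param file Output path.
#' @param seqname Reference name.
#' @param normalized Write normalized (TRUE) or raw depth.
#' @export
writeBedGraph <- function(track, file, seqname = "locus", normalized = TRUE) {
  v <- if (normalized) track$normalized else track$depth
  r <- rle(v)
  ends <- cumsum(r$lengths)
  startsv <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GRanges(seqname, IRanges(startsv[keep], ends[keep]),
                score = r$values[keep])
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Write read placements as a minimal SAM file
#'
#' Header plus the 11 mandatory fields, ungapped CIGAR, constant mapping
#' quality.
#'
#' @param alignments Result of [mapReads()].
#' @param file Output path.
#' @param refName Reference name.
#' @param refLength Reference length.
#' @export
writeSam <- function(alignments, file, refName = "locus", refLength) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", refName, as.integer(refLength))),
             con)
  pl <- alignments$placements
  lens <- alignments$readLengths
  for (i in seq_len(nrow(pl))) {
    flag <- if (pl$strand[i] == "-") 16L else 0L
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       pl$id[i], flag, refName, pl$pos[i], lens[i],
                       pl$mismatches[i]), con)
  }
  invisible(file)
}

#' Serialize a GeneSpec to a flat key=value config file
#' @param spec A [GeneSpec-class].
#' @param file Output path.
#' @export
writeGeneSpecConfig <- function(spec, file) {
  kv <- c(
    sprintf("exonLengths=%s", paste(spec@exonLengths, collapse = ",")),
    sprintf("intronLengths=%s", paste(spec@intronLengths, collapse = ",")),
    sprintf("strand=%s", spec@strand),
    sprintf("flankUpstream=%d", spec@flankLengths[["upstream"]]),
    sprintf("flankDownstream=%d", spec@flankLengths[["downstream"]]),
    sprintf("promoterCpgOffsets=%s",
            paste(spec@promoterCpgOffsets, collapse = ",")),
    sprintf("methylMale=%s", paste(spec@methylProfile$male, collapse = ",")),
    sprintf("methylFemale=%s", paste(spec@methylProfile$female, collapse = ",")),
    sprintf("gapIntron=%s", spec@gap$intron),
    sprintf("gapFillLength=%d", spec@gap$fillLength),
    sprintf("gapPlaceholder=%d", spec@gap$placeholder),
    sprintf("spliceDonor=%s", spec@spliceDonor),
    sprintf("spliceAcceptor=%s", spec@spliceAcceptor),
    sprintf("polyAHexamer=%s", spec@polyASignal$hexamer),
    sprintf("polyAUpstream=%d", spec@polyASignal$upstream),
    sprintf("promoterWindow=%d", spec@promoterWindow),
    sprintf("terminusShift=%d", spec@terminusShift)
  )
  for (i in seq_along(spec@repeatSpecs)) {
    r <- spec@repeatSpecs[[i]]
    kv <- c(kv,
            sprintf("repeat%d=%d,%s,%d,%s,%d,%s,%s", i, r@monomerLength,
                    format(r@copies), r@transcriptStart,
                    format(r@divergence), r@spacerLength, r@monomer,
                    paste(r@monomerCpg, collapse = ";")))
  }
  for (i in seq_along(spec@motifPlants)) {
    m <- spec@motifPlants[[i]]
    kv <- c(kv, sprintf("motif%d=%s,%s,%d", i, m$pattern, m$instance, m$start))
  }
  writeLines(kv, file)
  invisible(file)
}

#' Read a GeneSpec from a flat key=value config file
#' @param file Config path written by [writeGeneSpecConfig()].
#' @return A [GeneSpec-class].
#' @export
readGeneSpecConfig <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  names(vals) <- keys
  ints <- function(k) as.integer(strsplit(vals[[k]], ",")[[1L]])
  nums <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1L]])
  reps <- lapply(grep("^repeat[0-9]+$", keys, value = TRUE), function(k) {
    f <- strsplit(vals[[k]], ",", fixed = TRUE)[[1L]]
    RepeatSpec(as.integer(f[1L]), as.numeric(f[2L]), as.integer(f[3L]),
               divergence = as.numeric(f[4L]), spacerLength = as.integer(f[5L]),
               monomer = if (length(f) >= 6L) f[6L] else "",
               monomerCpg = if (length(f) >= 7L && nzchar(f[7L]))
                 as.integer(strsplit(f[7L], ";")[[1L]]) else integer())
  })
  motifs <- lapply(grep("^motif[0-9]+$", keys, value = TRUE), function(k) {
    f <- strsplit(vals[[k]], ",", fixed = TRUE)[[1L]]
    list(pattern = f[1L], instance = f[2L], start = as.integer(f[3L]))
  })
  GeneSpec(
    exonLengths = ints("exonLengths"),
    intronLengths = ints("intronLengths"),
    strand = vals[["strand"]],
    flankLengths = c(upstream = as.integer(vals[["flankUpstream"]]),
                     downstream = as.integer(vals[["flankDownstream"]])),
    repeatSpecs = reps,
    promoterCpgOffsets = ints("promoterCpgOffsets"),
    methylProfile = list(male = nums("methylMale"),
                         female = nums("methylFemale")),
    gap = list(intron = as.integer(vals[["gapIntron"]]),
               fillLength = as.integer(vals[["gapFillLength"]]),
               placeholder = as.integer(vals[["gapPlaceholder"]])),
    spliceDonor = vals[["spliceDonor"]],
    spliceAcceptor = vals[["spliceAcceptor"]],
    polyASignal = list(hexamer = vals[["polyAHexamer"]],
                       upstream = as.integer(vals[["polyAUpstream"]])),
    motifPlants = motifs,
    promoterWindow = as.integer(vals[["promoterWindow"]]),
    terminusShift = as.integer(vals[["terminusShift"]])
  )
}
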