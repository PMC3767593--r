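## Simulated experimental readouts from a ScaffoldBundle. All simulators are
## deterministic given (bundle, arguments, seed).

## Extended 5' axis: upstream flank followed by the spliced transcript, so a
## clone start can be addressed by one promoter-style offset (negative =
## genomic upstream, positive = transcript coordinate).
extendedAxis <- function(bundle) {
  tr <- truthTable(bundle)
  u <- tr$upstreamFlank
  paste0(substr(tr$geneForwardSeq, 1L, u), as.character(transcriptSeq(bundle)))
}

axisIndex <- function(offset, u) ifelse(offset > 0L, u + offset, u + 1L + offset)

#' Simulate 5'/3' RACE clone sequences
#'
#' 5' clones start exactly at the requested promoter offsets (negative
#' offsets extend into genomic upstream sequence, mimicking alternative
#' starts upstream of the reference TSS) and run downstream along the spliced
#' transcript. 3' clones end exactly at the requested transcript positions
#' and carry an appended poly-A tract.
#'
#' @param bundle A [ScaffoldBundle-class].
#' @param end "five" or "three".
#' @param offsets For `end = "five"`: promoter offsets of clone starts (no 0).
#'   For `end = "three"`: transcript coordinates of clone ends (default: the
#'   true terminus).
#' @param clonesPerOffset Clones per offset (default 3).
#' @param cloneLength Genomic/transcript bases per clone (default 400).
#' @param polyALength Poly-A tract length range for 3' clones.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] named `<end>RACE_<offset>_<i>`.
#' @export
simulateRaceClones <- function(bundle, end = c("five", "three"),
                               offsets = NULL, clonesPerOffset = 3L,
                               cloneLength = 400L, polyALength = c(10L, 20L),
                               seed = 1L) {
  end <- match.arg(end)
  withr::local_seed(as.integer(seed))
  tr <- truthTable(bundle)
  u <- tr$upstreamFlank
  Lt <- length(transcriptSeq(bundle))
  tx <- as.character(transcriptSeq(bundle))

  if (clonesPerOffset <= 0L) return(DNAStringSet())
  if (end == "five") {
    if (is.null(offsets)) offsets <- c(-5L, -3L, 1L, 16L, 48L, 72L, 143L, 211L)
    if (any(offsets == 0L)) stop("promoter offsets have no position 0")
    bad <- offsets[offsets < -u | offsets > Lt]
    if (length(bad) > 0L)
      stop(sprintf("offset %d lies outside the gene span", bad[1L]))
    axis <- extendedAxis(bundle)
    seqs <- character(0)
    nms <- character(0)
    for (o in offsets) {
      i <- axisIndex(o, u)
      s <- substr(axis, i, min(nchar(axis), i + cloneLength - 1L))
      for (k in seq_len(clonesPerOffset)) {
        seqs <- c(seqs, s)
        nms <- c(nms, sprintf("fiveRACE_%d_%d", o, k))
      }
    }
    return(setNames(DNAStringSet(seqs), nms))
  }

  ## 3' clones
  if (is.null(offsets)) offsets <- Lt
  bad <- offsets[offsets < 1L | offsets > Lt]
  if (length(bad) > 0L)
    stop(sprintf("offset %d lies outside the gene span", bad[1L]))
  seqs <- character(0)
  nms <- character(0)
  for (o in offsets) {
    body <- substr(tx, max(1L, o - cloneLength + 1L), o)
    for (k in seq_len(clonesPerOffset)) {
      nA <- sample(polyALength[1L]:polyALength[2L], 1L)
      seqs <- c(seqs, paste0(body, strrep("A", nA)))
      nms <- c(nms, sprintf("threeRACE_%d_%d", o, k))
    }
  }
  setNames(DNAStringSet(seqs), nms)
}

#' Simulate bisulfite-converted clone sequences
#'
#' For each bisulfite amplicon region (default: the regions recorded in the
#' bundle truth, 8-16 CpG sites each covering the 67 dense sites), draws
#' `nClones` clones: each CpG site is methylated with the sex's per-site
#' probability, then every unmethylated C (CpG or not) is converted C->T with
#' probability `conversionRate` (top-strand model). The per-clone, per-site
#' truth states are returned alongside the sequences.
#'
#' @param bundle A [ScaffoldBundle-class].
#' @param sex "male" or "female"; must have a methylation profile in the spec.
#' @param nClones Clones per region (default 10).
#' @param conversionRate Probability an unmethylated C converts (in (0.9, 1]).
#' @param seed Integer seed.
#' @param regions Optional data.frame(start, end) of promoter-coordinate
#'   regions; defaults to the truth `bsRegions`.
#' @return list(clones = DNAStringSet, truth = data.frame(clone, region, site,
#'   methylated), sites = covered promoter offsets, regions = region table).
#' @export
simulateBisulfiteClones <- function(bundle, sex = c("male", "female"),
                                    nClones = 10L, conversionRate = 0.99,
                                    seed = 1L, regions = NULL) {
  sex <- match.arg(sex)
  prof <- geneSpec(bundle)@methylProfile[[sex]]
  if (is.null(prof)) stop(sprintf("no methylation profile for sex '%s'", sex))
  if (conversionRate <= 0.9 || conversionRate > 1)
    stop("conversionRate must lie in (0.9, 1]")
  withr::local_seed(as.integer(seed))

  tr <- truthTable(bundle)
  u <- tr$upstreamFlank
  gseq <- tr$geneForwardSeq
  if (is.null(regions)) regions <- tr$bsRegions
  offsets <- tr$cpgOffsets

  clones <- character(0)
  nms <- character(0)
  states <- list()
  allSites <- integer(0)
  for (ri in seq_len(nrow(regions))) {
    a <- regions$start[ri]; b <- regions$end[ri]
    ga <- promoterToG(a, u); gb <- promoterToG(b, u)
    ref <- substr(gseq, ga, gb)
    sites <- offsets[offsets >= a & offsets <= b &
                     promoterLinear(offsets) >= promoterLinear(a) &
                     promoterLinear(offsets) <= promoterLinear(b)]
    allSites <- c(allSites, sites)
    sitePos <- promoterToG(sites, u) - ga + 1L       # 1-based within region
    p <- rep_len(prof, length(sites))
    for (k in seq_len(nClones)) {
      meth <- stats::runif(length(sites)) < p
      conv <- bisulfiteConvert(ref, setNames(as.logical(meth),
                                             as.character(sitePos)),
                               conversionRate = conversionRate)
      clones <- c(clones, conv)
      nms <- c(nms, sprintf("%s_%s_clone%02d", sex, regions$region[ri], k))
      states[[length(states) + 1L]] <- data.frame(
        clone = nms[length(nms)], region = regions$region[ri],
        site = sites, methylated = meth, stringsAsFactors = FALSE)
    }
  }
  list(clones = setNames(DNAStringSet(clones), nms),
       truth = do.call(rbind, states),
       sites = sort(allSites), regions = regions)
}

#' In-silico bisulfite conversion
#'
#' Top-strand model: every cytosine not protected by a methylated CpG state
#' converts C->T with probability `conversionRate`; methylated-CpG cytosines
#' are left unchanged.
#'
#' @param reference DNA string (character or DNAString).
#' @param methylStates Named logical vector; names are 1-based positions of
#'   the CpG cytosines in `reference`, values the methylation state. Must
#'   cover every CG in the reference.
#' @param conversionRate Conversion probability for unmethylated cytosines.
#' @return Converted sequence (character).
#' @export
bisulfiteConvert <- function(reference, methylStates, conversionRate = 1.0) {
  s <- strsplit(dnaToChar(reference), "")[[1]]
  cg <- which(s[-length(s)] == "C" & s[-1L] == "G")
  declared <- as.integer(names(methylStates))
  if (!all(cg %in% declared))
    stop("methylStates must cover every CpG site in the reference")
  protectedPos <- declared[as.logical(methylStates)]
  cs <- which(s == "C")
  convertible <- setdiff(cs, protectedPos)
  doConvert <- convertible[stats::runif(length(convertible)) < conversionRate]
  s[doConvert] <- "T"
  paste(s, collapse = "")
}

#' Simulate paired-end RNA-seq reads from the locus
#'
#' Female samples express the transcript: fragments of length `insert` are
#' drawn uniformly from the spliced transcript, read 1 is the fragment's
#' first `readLen` bases (transcript strand) and read 2 the reverse
#' complement of its last `readLen` bases. Male samples yield zero
#' transcript-derived pairs.
#'
#' @param bundle A [ScaffoldBundle-class].
#' @param sex "male" or "female".
#' @param nPairs Number of read pairs.
#' @param readLen Read length (default 90).
#' @param insert Insert (fragment) length (default 200).
#' @param seed Integer seed.
#' @return list(read1, read2): [Biostrings::DNAStringSet]s (empty for male).
#' @export
simulateRnaseq <- function(bundle, sex = c("female", "male"), nPairs = 1000L,
                           readLen = 90L, insert = 200L, seed = 1L) {
  sex <- match.arg(sex)
  withr::local_seed(as.integer(seed))
  tx <- as.character(transcriptSeq(bundle))
  Lt <- nchar(tx)
  if (insert > Lt) stop("insert length exceeds the transcript length")
  if (readLen > insert) stop("read length exceeds the insert length")
  if (sex == "male" || nPairs <= 0L) {
    return(list(read1 = DNAStringSet(), read2 = DNAStringSet()))
  }
  starts <- sample.int(Lt - insert + 1L, nPairs, replace = TRUE)
  r1 <- substr(rep(tx, nPairs), starts, starts + readLen - 1L)
  f2 <- substr(rep(tx, nPairs), starts + insert - readLen, starts + insert - 1L)
  r2 <- as.character(reverseComplement(DNAStringSet(f2)))
  ids <- sprintf("pair%06d", seq_len(nPairs))
  list(read1 = setNames(DNAStringSet(r1), paste0(ids, "/1")),
       read2 = setNames(DNAStringSet(r2), paste0(ids, "/2")))
}

#' Simulate PCR amplicons from cDNA or genomic templates
#'
#' The forward primer must match the template (spliced transcript for
#' `template = "cdna"`, gap-filled transcribed-strand gene frame for
#' `template = "gdna"`) exactly and uniquely; the reverse primer is given in
#' its own 5'->3' orientation and matched as its reverse complement. The
#' amplicon is the template substring between and including both primer
#' sites, so primer pairs spanning introns give shorter cDNA than gDNA
#' amplicons.
#'
#' @param bundle A [ScaffoldBundle-class].
#' @param primerPairs List of c(fwd, rev) 5'->3' primer sequences.
#' @param template "cdna" or "gdna".
#' @return Named [Biostrings::DNAStringSet] of amplicons.
#' @export
simulateAmplicons <- function(bundle, primerPairs, template = c("cdna", "gdna")) {
  template <- match.arg(template)
  tmpl <- if (template == "cdna") {
    as.character(transcriptSeq(bundle))
  } else {
    truthTable(bundle)$geneForwardSeq
  }
  uniqueHit <- function(pat, what) {
    m <- matchPattern(pat, DNAString(tmpl))
    if (length(m) == 0L)
      stop(sprintf("primer '%s' not found on the %s template", what, template))
    if (length(m) > 1L)
      stop(sprintf("primer '%s' matches the %s template %d times", what,
                   template, length(m)))
    c(start(m), end(m))
  }
  out <- character(0)
  nms <- character(0)
  for (i in seq_along(primerPairs)) {
    pr <- primerPairs[[i]]
    f <- uniqueHit(pr[1L], pr[1L])
    r <- uniqueHit(revComp(pr[2L]), pr[2L])
    if (r[2L] <= f[1L])
      stop(sprintf("primer pair %d is inverted on the %s template", i, template))
    out <- c(out, substr(tmpl, f[1L], r[2L]))
    nms <- c(nms, names(primerPairs)[i] %||% sprintf("amplicon%d", i))
  }
  setNames(DNAStringSet(out), nms)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a) || a == "") b else a
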