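## Synthetic locus construction.
##
## The locus is assembled in the "gene-forward" frame G: a character vector
## holding the transcribed-strand sequence of upstream flank + gene span +
## downstream flank, so every planted feature is written in its natural
## orientation. For a minus-strand gene the scaffold is the reverse complement
## of G and all coordinates are flipped at the end.

#' Build a synthetic scaffold with ground truth
#'
#' Generates a uniform-ACGT background, plants every feature declared in the
#' [GeneSpec-class] (splice dinucleotides, tandem-repeat arrays, promoter
#' motifs, the poly-A signal, CG dinucleotides exactly at the declared
#' promoter offsets and nowhere else within the window) and cuts the N-gap
#' into the public scaffold. Overlapping plants that disagree are rejected
#' with an error naming the conflicting features. Output is deterministic
#' given `(spec, seed)`.
#'
#' @param spec A [GeneSpec-class].
#' @param seed Integer seed; all randomness derives from it.
#' @return A [ScaffoldBundle-class]. Its `truth` list records (all coordinates
#'   on the gap-filled scaffold unless noted): `tssPos`, `terminusPos`,
#'   `expectedTerminusPos`, `exons`/`introns` (IRanges in transcript order),
#'   `geneForwardSeq` (filled transcribed-strand frame), `upstreamFlank`,
#'   `scaffoldFilled`, `txMapScaffold` (transcript -> scaffold bijection),
#'   `repeats` (planted arrays with consensus), `cpgOffsets`, `bsRegions`,
#'   `gap` (fill sequence, delta, public placeholder interval), `polyA` and
#'   `motifs`.
#' @examples
#' b <- buildScaffold(deskGeneSpec(), seed = 1)
#' length(transcriptSeq(b))
#' @export
buildScaffold <- function(spec, seed = 1L) {
  validObject(spec)
  withr::local_seed(as.integer(seed))

  ex <- spec@exonLengths
  it <- spec@intronLengths
  Lt <- sum(ex)
  span <- Lt + sum(it)
  u <- spec@flankLengths[["upstream"]]
  d <- spec@flankLengths[["downstream"]]
  Lg <- u + span + d
  W <- spec@promoterWindow

  g <- sample(c("A", "C", "G", "T"), Lg, replace = TRUE)
  owner <- character(Lg)

  ## exon/intron layout in G coordinates (transcript order)
  exStart <- integer(length(ex)); exEnd <- integer(length(ex))
  itStart <- integer(length(it)); itEnd <- integer(length(it))
  pos <- u + 1L
  for (i in seq_along(ex)) {
    exStart[i] <- pos; exEnd[i] <- pos + ex[i] - 1L
    pos <- exEnd[i] + 1L
    if (i <= length(it)) {
      itStart[i] <- pos; itEnd[i] <- pos + it[i] - 1L
      pos <- itEnd[i] + 1L
    }
  }
  ## transcript coordinate -> G index
  txG <- unlist(lapply(seq_along(ex), function(i) exStart[i]:exEnd[i]))

  plantSeq <- function(idx, chars, name) {
    stopifnot(length(idx) == length(chars))
    clash <- owner[idx] != "" & g[idx] != chars
    if (any(clash)) {
      i <- idx[which(clash)[1L]]
      stop(sprintf("planting conflict: '%s' overlaps '%s' at gene-forward position %d",
                   name, owner[i], i), call. = FALSE)
    }
    g[idx] <<- chars
    owner[idx] <<- ifelse(owner[idx] == "", name, owner[idx])
  }

  ## 1. splice dinucleotides on the transcribed strand; junctions are made
  ##    unambiguous (the following exon must not start with the intron's
  ##    first base, the preceding exon must not end with its last base), so
  ##    splice placement is unique and spliced reads cannot run into introns
  don <- strsplit(spec@spliceDonor, "")[[1]]
  acc <- strsplit(spec@spliceAcceptor, "")[[1]]
  for (i in seq_along(it)) {
    plantSeq(itStart[i] + 0:1, don, "splice")
    plantSeq(itEnd[i] - 1:0, acc, "splice")
    if (owner[exEnd[i]] == "" && g[exEnd[i]] == acc[2]) {
      g[exEnd[i]] <- sample(setdiff(c("A", "C", "T"), acc[2]), 1L)
    }
    if (owner[exStart[i + 1L]] == "" && g[exStart[i + 1L]] == don[1]) {
      g[exStart[i + 1L]] <- sample(setdiff(c("A", "C", "T"), don[1]), 1L)
    }
  }

  ## 2. tandem-repeat arrays
  winLo <- u - W + 1L
  winHi <- u + W
  repTruth <- list()
  for (ri in seq_along(spec@repeatSpecs)) {
    r <- spec@repeatSpecs[[ri]]
    p <- r@monomerLength
    spanR <- repeatSpan(r)
    gs <- txG[r@transcriptStart]
    inWindow <- gs <= winHi && (gs + spanR - 1L) >= winLo
    monomer <- if (nzchar(r@monomer)) {
      strsplit(r@monomer, "")[[1]]
    } else {
      makeMonomer(p, r@monomerCpg, constrainCpg = inWindow)
    }
    arr <- buildArray(monomer, r, inWindow)
    plantSeq(gs + seq_along(arr) - 1L, arr, paste0("repeat", ri))
    repTruth[[ri]] <- data.frame(
      txStart = r@transcriptStart,
      txEnd = r@transcriptStart + spanR - 1L,
      period = p, copies = r@copies, divergence = r@divergence,
      consensus = paste(monomer, collapse = ""),
      stringsAsFactors = FALSE)
  }
  repTruth <- if (length(repTruth)) do.call(rbind, repTruth) else
    data.frame(txStart = integer(), txEnd = integer(), period = integer(),
               copies = numeric(), divergence = numeric(),
               consensus = character())

  ## 3. promoter motifs (no-zero coordinates)
  motifTruth <- list()
  for (m in spec@motifPlants) {
    inst <- strsplit(m$instance, "")[[1]]
    offs <- promoterFromLinear(promoterLinear(m$start) + seq_along(inst) - 1L)
    plantSeq(promoterToG(offs, u), inst, "motif")
    motifTruth[[length(motifTruth) + 1L]] <- data.frame(
      pattern = m$pattern, instance = m$instance,
      start = offs[1L], end = offs[length(offs)], stringsAsFactors = FALSE)
  }
  motifTruth <- if (length(motifTruth)) do.call(rbind, motifTruth) else
    data.frame(pattern = character(), instance = character(),
               start = integer(), end = integer())

  ## 4. poly-A signal: hexamer whose last base sits `upstream` bp before the
  ##    terminus (distance = terminus position - signal end position)
  hex <- strsplit(spec@polyASignal$hexamer, "")[[1]]
  sigEndTx <- Lt - spec@polyASignal$upstream
  sigTx <- (sigEndTx - length(hex) + 1L):sigEndTx
  plantSeq(txG[sigTx], hex, "polyA")

  ## 5. CpG accounting in the +/- window: CGs exactly at the declared offsets
  offIdx <- promoterToG(spec@promoterCpgOffsets, u)
  for (j in seq_along(offIdx)) {
    i <- offIdx[j]
    for (kk in 0:1) {
      want <- c("C", "G")[kk + 1L]
      if (owner[i + kk] != "" && g[i + kk] != want) {
        stop(sprintf("CpG offset %d conflicts with planted feature '%s'",
                     spec@promoterCpgOffsets[j], owner[i + kk]), call. = FALSE)
      }
      g[i + kk] <- want
    }
  }
  cpgLock <- logical(Lg)
  cpgLock[c(offIdx, offIdx + 1L)] <- TRUE
  ## destroy stray CGs (C position inside the window)
  scan <- winLo:min(winHi, Lg - 1L)
  isCG <- g[scan] == "C" & g[scan + 1L] == "G"
  for (i in scan[isCG]) {
    if (i %in% offIdx) next
    fixable <- function(k) !cpgLock[k] &&
      (owner[k] == "" || startsWith(owner[k], "repeat"))
    if (fixable(i) && owner[i] == "") {
      g[i] <- sample(c("A", "T"), 1L)
    } else if (fixable(i + 1L) && owner[i + 1L] == "") {
      g[i + 1L] <- sample(c("A", "T"), 1L)
    } else if (fixable(i)) {
      g[i] <- sample(c("A", "T"), 1L)      # inside a repeat: extra divergence
    } else if (fixable(i + 1L)) {
      g[i + 1L] <- sample(c("A", "T"), 1L)
    } else {
      stop(sprintf("stray CG at promoter offset %d locked by '%s'/'%s'",
                   gToPromoter(i, u), owner[i], owner[i + 1L]), call. = FALSE)
    }
  }
  stray <- sum(g[scan] == "C" & g[scan + 1L] == "G") -
    length(spec@promoterCpgOffsets)
  if (stray != 0L) stop("CpG planting failed to converge", call. = FALSE)

  ## 6. keep the planted poly-A signal unique in the 3' scan neighbourhood
  tail60 <- txG[max(1L, Lt - 59L):Lt]
  hexStr <- spec@polyASignal$hexamer
  repeat {
    tailSeq <- paste(g[tail60], collapse = "")
    occ <- gregexpr(hexStr, tailSeq, fixed = TRUE)[[1]]
    occ <- occ[occ > 0L]
    occTx <- (max(1L, Lt - 59L) - 1L) + occ
    extra <- occTx[occTx != sigTx[1L]]
    if (length(extra) == 0L) break
    i <- txG[extra[1L]]
    if (owner[i] != "") stop("cannot disambiguate poly-A signal", call. = FALSE)
    g[i] <- sample(setdiff(c("A", "C", "G", "T"), g[i]), 1L)
  }

  ## 7. N-gap: excise the true fill from the public copy
  gapInfo <- list(filledInterval = IRanges(), publicInterval = IRanges(),
                  fillSeq = "", delta = 0L)
  gPub <- g
  if (!is.na(spec@gap$intron) && spec@gap$fillLength > 0L) {
    gi <- spec@gap$intron
    fl <- spec@gap$fillLength
    ph <- spec@gap$placeholder
    ilen <- it[gi]
    if (fl > ilen - 8L)
      stop("gap fill does not fit inside the designated intron", call. = FALSE)
    fstart <- itStart[gi] + 2L + floor((ilen - 4L - fl) / 2)
    fend <- fstart + fl - 1L
    gapInfo$fillSeq <- paste(g[fstart:fend], collapse = "")
    gapInfo$delta <- fl - ph
    gPub <- c(g[seq_len(fstart - 1L)], rep("N", ph), g[(fend + 1L):Lg])
    gapInfo$gFillStart <- fstart
    gapInfo$gFillEnd <- fend
  }
  LgPub <- length(gPub)

  ## 8. orientation: forward-scaffold coordinates
  minus <- spec@strand == "-"
  gIvToScaffold <- function(s, e, len) {
    if (minus) IRanges(len - e + 1L, len - s + 1L) else IRanges(s, e)
  }
  gPosToScaffold <- function(p, len) if (minus) len - p + 1L else p

  filledStr <- paste(g, collapse = "")
  pubStr <- paste(gPub, collapse = "")
  scaffoldFilled <- if (minus) revComp(filledStr) else filledStr
  scaffoldPub <- if (minus) revComp(pubStr) else pubStr
  transcript <- paste(g[txG], collapse = "")

  exonsIR <- do.call("c", lapply(seq_along(ex), function(i)
    gIvToScaffold(exStart[i], exEnd[i], Lg)))
  intronsIR <- if (length(it)) do.call("c", lapply(seq_along(it), function(i)
    gIvToScaffold(itStart[i], itEnd[i], Lg))) else IRanges()

  if (!is.na(spec@gap$intron) && spec@gap$fillLength > 0L) {
    gapInfo$filledInterval <-
      gIvToScaffold(gapInfo$gFillStart, gapInfo$gFillEnd, Lg)
    gapInfo$publicInterval <- gIvToScaffold(
      gapInfo$gFillStart, gapInfo$gFillStart + spec@gap$placeholder - 1L, LgPub)
  }

  truth <- list(
    strand = spec@strand,
    upstreamFlank = u,
    geneForwardSeq = filledStr,
    scaffoldFilled = scaffoldFilled,
    tssPos = gPosToScaffold(u + 1L, Lg),
    terminusPos = gPosToScaffold(u + span, Lg),
    expectedTerminusPos = gPosToScaffold(txG[Lt - (spec@terminusShift - 1L)], Lg),
    exons = exonsIR,
    introns = intronsIR,
    exonsGene = IRanges(exStart, exEnd),
    intronsGene = if (length(it)) IRanges(itStart, itEnd) else IRanges(),
    tssGene = u + 1L,
    terminusGene = u + span,
    txMapScaffold = gPosToScaffold(txG, Lg),
    repeats = repTruth,
    cpgOffsets = spec@promoterCpgOffsets,
    bsRegions = makeBsRegions(spec@promoterCpgOffsets),
    gap = gapInfo,
    polyA = list(hexamer = hexStr, txEnd = sigEndTx,
                 upstream = spec@polyASignal$upstream),
    motifs = motifTruth,
    methylProfile = spec@methylProfile
  )

  new("ScaffoldBundle",
      scaffoldSeq = DNAString(scaffoldPub),
      transcriptSeq = DNAString(transcript),
      spec = spec, truth = truth)
}

## Random monomer generation. Inside the promoter window the monomer must
## carry CGs exactly at `cpg` (C positions) and be junction-safe.
makeMonomer <- function(p, cpg, constrainCpg) {
  for (attempt in 1:200) {
    m <- sample(c("A", "C", "G", "T"), p, replace = TRUE)
    if (!constrainCpg) {
      ## still junction-safe so tandem joints don't spawn window CGs later
      if (m[p] == "C" && m[1L] == "G") next
      return(m)
    }
    m[cpg] <- "C"; m[cpg + 1L] <- "G"
    pairs <- which(m[-p] == "C" & m[-1L] == "G")
    if (!setequal(pairs, cpg)) next
    if (m[p] == "C" || m[1L] == "G") next
    return(m)
  }
  stop("could not generate a monomer satisfying the CpG constraints",
       call. = FALSE)
}

## Concatenate copies (+ optional spacers + fractional tail) applying per-base
## divergence. CG-bearing monomer positions are never mutated when the array
## sits in the promoter window, so the CpG truth stays exact.
buildArray <- function(monomer, r, inWindow) {
  p <- r@monomerLength
  full <- floor(r@copies)
  part <- round((r@copies - full) * p)
  shield <- if (inWindow) unique(c(r@monomerCpg, r@monomerCpg + 1L)) else integer()
  mutate <- function(copy) {
    if (r@divergence <= 0) return(copy)
    hit <- which(stats::runif(length(copy)) < r@divergence)
    hit <- setdiff(hit, shield)
    for (i in hit) copy[i] <- sample(setdiff(c("A", "C", "G", "T"), copy[i]), 1L)
    copy
  }
  pieces <- list()
  for (ci in seq_len(full)) {
    pieces[[length(pieces) + 1L]] <- mutate(monomer)
    if (r@spacerLength > 0L && (ci < full || part > 0L))
      pieces[[length(pieces) + 1L]] <-
        sample(c("A", "C", "G", "T"), r@spacerLength, replace = TRUE)
  }
  if (part > 0L) pieces[[length(pieces) + 1L]] <- mutate(monomer)[seq_len(part)]
  unlist(pieces)
}

## Partition the dense promoter CpG sites into bisulfite amplicon regions of
## 8-16 sites. With the default 67-site dense layout the grouping is the fixed
## 13/12/11/11/10/10 six-region split; otherwise sites are split into
## near-equal chunks of at most 12.
makeBsRegions <- function(offsets, maxGap = 200L, minSites = 5L, pad = 15L) {
  lin <- promoterLinear(offsets)
  brk <- c(0L, which(diff(lin) > maxGap), length(lin))
  chains <- lapply(seq_len(length(brk) - 1L), function(i)
    (brk[i] + 1L):brk[i + 1L])
  dense <- unlist(chains[vapply(chains, length, 1L) >= minSites])
  ds <- offsets[dense]
  n <- length(ds)
  if (n == 0L) {
    return(data.frame(region = character(), start = integer(),
                      end = integer(), nSites = integer()))
  }
  sizes <- if (n == 67L) c(13L, 12L, 11L, 11L, 10L, 10L) else {
    k <- ceiling(n / 12L)
    rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  }
  stopifnot(sum(sizes) == n)
  idx <- cumsum(c(0L, sizes))
  out <- lapply(seq_along(sizes), function(i) {
    s <- ds[(idx[i] + 1L):idx[i + 1L]]
    data.frame(region = sprintf("BS%d", i),
               start = promoterFromLinear(promoterLinear(s[1L]) - pad),
               end = promoterFromLinear(promoterLinear(s[length(s)]) + pad),
               nSites = length(s))
  })
  out <- do.call(rbind, out)
  attr(out, "siteGroups") <- lapply(seq_along(sizes), function(i)
    ds[(idx[i] + 1L):idx[i + 1L]])
  out
}
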