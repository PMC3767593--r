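## CpG enumeration around the TSS, dense-region clustering, clone-level
## bisulfite methylation calling and sex-stratified summaries.
## (In-silico conversion itself lives with the other simulators:
## bisulfiteConvert().)

#' Enumerate CpG sites around the TSS
#'
#' Lists the promoter offsets (position of the C, no-zero convention) of
#' every CG dinucleotide within the +/- `window` region around the TSS on
#' the transcribed strand.
#'
#' @param x A [ScaffoldBundle-class], or a character reference sequence.
#' @param tss For a character reference: 1-based index of the TSS base.
#' @param window Half-width in bp (default 2000).
#' @return list(sites = integer promoter offsets, window = half-width).
#' @export
scanCpg <- function(x, tss = NULL, window = 2000L) {
  if (is.character(x)) {
    if (is.null(tss)) stop("tss is required for a raw reference sequence")
    if (tss - window < 1L || tss + window - 1L > nchar(x))
      stop("reference does not cover the +/- window around the TSS")
    ## one extra base so a C at the window edge can still be checked for its G
    win <- substr(toupper(x), tss - window,
                  min(nchar(x), tss + window))
  } else {
    tr <- truthTable(x)
    u <- tr$upstreamFlank
    if (u < window) stop("reference does not cover the +/- window around the TSS")
    win <- substr(tr$geneForwardSeq, u - window + 1L,
                  min(nchar(tr$geneForwardSeq), u + window + 1L))
  }
  occ <- gregexpr("CG", win, fixed = TRUE)[[1L]]
  occ <- occ[occ > 0L & occ <= 2L * window]
  list(sites = promoterFromLinear(as.integer(occ) - window),
       window = as.integer(window))
}

#' Cluster CpG sites into dense regions
#'
#' Single-linkage chaining: consecutive sites are joined while their distance
#' on the gap-free promoter axis is at most `maxGap`; chains with at least
#' `minSites` sites are reported with endpoints at their outermost sites.
#' The output is a function of the site set only (input order is irrelevant).
#'
#' @param map A site map from [scanCpg()] (or an integer vector of offsets).
#' @param maxGap Maximum intra-region inter-site distance in bp (default 200).
#' @param minSites Minimum sites per reported region (default 5).
#' @return data.frame(start, end, nSites) in promoter coordinates.
#' @export
denseRegions <- function(map, maxGap = 200L, minSites = 5L) {
  stopifnot(maxGap > 0L)
  sites <- if (is.list(map)) map$sites else as.integer(map)
  sites <- sort(unique(sites))
  empty <- data.frame(start = integer(), end = integer(), nSites = integer())
  if (length(sites) == 0L) return(empty)
  lin <- promoterLinear(sites)
  brk <- c(0L, which(diff(lin) > maxGap), length(lin))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    if (length(idx) < minSites) return(NULL)
    data.frame(start = sites[idx[1L]], end = sites[idx[length(idx)]],
               nSites = length(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Call per-clone, per-site methylation from bisulfite clones
#'
#' Clones are placed on the promoter window by exact matching in the
#' C/T-collapsed space (every C read as T on both clone and reference, the
#' only degeneracy bisulfite conversion introduces); placement must be
#' unique and ungapped. At each covered CpG site a clone C calls methylated,
#' T unmethylated, anything else missing. Clones whose non-CpG cytosine
#' conversion fraction is below `minConversion` are excluded and counted.
#'
#' @param clones [Biostrings::DNAStringSet] of bisulfite clone sequences
#'   (transcribed strand).
#' @param bundle A [ScaffoldBundle-class] providing the unconverted
#'   reference window.
#' @param map CpG site map from [scanCpg()] (default: scan the bundle).
#' @param minConversion Minimum non-CpG C conversion per clone (default 0.95).
#' @return A [BisulfiteCallMatrix-class] over all map sites.
#' @export
callMethylation <- function(clones, bundle, map = NULL, minConversion = 0.95) {
  if (is.null(map)) map <- scanCpg(bundle)
  W <- map$window
  win <- promoterWindowSeq(bundle, W)
  winT <- chartr("C", "T", win)
  winTD <- DNAString(winT)
  siteIdx <- promoterLinear(map$sites) + W          # index of the C in `win`
  winChars <- strsplit(win, "")[[1L]]
  nonCpgC <- setdiff(which(winChars == "C"), siteIdx)

  rows <- list()
  qc <- numeric(0)
  excluded <- 0L
  keptNames <- character(0)
  for (ci in seq_along(clones)) {
    cl <- toupper(dnaToChar(clones[[ci]]))
    m <- matchPattern(chartr("C", "T", cl), winTD)
    if (length(m) != 1L) {
      warning(sprintf("clone %d could not be placed uniquely; excluded", ci))
      excluded <- excluded + 1L
      next
    }
    off <- start(m) - 1L
    span <- off + seq_len(nchar(cl))
    clChars <- strsplit(cl, "")[[1L]]
    ## conversion QC on non-CpG reference cytosines covered by the clone
    cc <- nonCpgC[nonCpgC %in% span]
    conv <- if (length(cc) > 0L) mean(clChars[cc - off] == "T") else NA_real_
    if (!is.na(conv) && conv < minConversion) {
      excluded <- excluded + 1L
      next
    }
    calls <- rep(NA_integer_, length(siteIdx))
    covered <- which(siteIdx %in% span)
    for (k in covered) {
      b <- clChars[siteIdx[k] - off]
      calls[k] <- if (b == "C") 1L else if (b == "T") 0L else NA_integer_
    }
    rows[[length(rows) + 1L]] <- calls
    qc <- c(qc, conv)
    keptNames <- c(keptNames, names(clones)[ci] %||% sprintf("clone%d", ci))
  }
  if (length(rows) == 0L)
    stop("no clone could be placed on the reference window")
  calls <- do.call(rbind, rows)
  rownames(calls) <- keptNames
  BisulfiteCallMatrix(calls, map$sites, conversionQC = qc,
                      excluded = excluded)
}

#' Summarise a bisulfite call matrix
#'
#' Aggregate methylation is the pooled call fraction,
#' 100 * methylated / (methylated + unmethylated), rounded half-up to two
#' decimals; the clone-mean aggregate (mean over clones of their own
#' percentage) is reported alongside, the two coinciding when every clone
#' covers every site. The mean methylated sites per clone is scaled to the
#' full site panel (sum over sites of the per-site methylated fraction),
#' rounded half-up to one decimal.
#'
#' @param x A [BisulfiteCallMatrix-class].
#' @param regions Optional data.frame(start, end) of promoter-coordinate
#'   regions (e.g. from [denseRegions()]) for per-region percentages.
#' @return list(perSitePercent, perRegionPercent, aggregatePercent,
#'   aggregateCloneMeanPercent, meanMethylatedSitesPerClone, nMethylated,
#'   nUnmethylated, nMissing).
#' @export
summarizeMethylation <- function(x, regions = NULL) {
  calls <- methCalls(x)
  nM <- sum(calls == 1L, na.rm = TRUE)
  nU <- sum(calls == 0L, na.rm = TRUE)
  if (nM + nU == 0L) stop("call matrix contains no informative calls")
  perSite <- apply(calls, 2L, function(col) {
    k <- sum(!is.na(col))
    if (k == 0L) NA_real_ else roundHalfUp(100 * sum(col, na.rm = TRUE) / k, 2L)
  })
  cloneFrac <- apply(calls, 1L, function(row) {
    k <- sum(!is.na(row))
    if (k == 0L) NA_real_ else sum(row, na.rm = TRUE) / k
  })
  siteFrac <- apply(calls, 2L, function(col) {
    k <- sum(!is.na(col))
    if (k == 0L) NA_real_ else sum(col, na.rm = TRUE) / k
  })
  perRegion <- NULL
  if (!is.null(regions)) {
    sites <- methSites(x)
    perRegion <- vapply(seq_len(nrow(regions)), function(i) {
      inR <- sites >= regions$start[i] & sites <= regions$end[i]
      sub <- calls[, inR, drop = FALSE]
      m <- sum(sub == 1L, na.rm = TRUE)
      u <- sum(sub == 0L, na.rm = TRUE)
      if (m + u == 0L) NA_real_ else roundHalfUp(100 * m / (m + u), 2L)
    }, numeric(1L))
    names(perRegion) <- rownames(regions)
  }
  list(perSitePercent = perSite,
       perRegionPercent = perRegion,
       aggregatePercent = roundHalfUp(100 * nM / (nM + nU), 2L),
       aggregateCloneMeanPercent = roundHalfUp(
         100 * mean(cloneFrac, na.rm = TRUE), 2L),
       meanMethylatedSitesPerClone = roundHalfUp(
         sum(siteFrac, na.rm = TRUE), 1L),
       nMethylated = nM, nUnmethylated = nU,
       nMissing = sum(is.na(calls)))
}

#' Text lollipop grid of a call matrix
#'
#' One row per clone and one column per site: '*' methylated, 'o'
#' unmethylated, '.' missing, with '|' separators at dense-region
#' boundaries.
#'
#' @param x A [BisulfiteCallMatrix-class].
#' @param regions Optional dense regions (data.frame(start, end)) for
#'   separators.
#' @return Character vector, one line per clone (plus a header line).
#' @export
lollipopReport <- function(x, regions = NULL) {
  calls <- methCalls(x)
  sites <- methSites(x)
  sep <- rep(FALSE, length(sites))
  if (!is.null(regions) && nrow(regions) > 1L) {
    for (i in 2:nrow(regions)) {
      sep[which(sites >= regions$start[i])[1L]] <- TRUE
    }
  }
  glyphRow <- function(row) {
    g <- ifelse(is.na(row), ".", ifelse(row == 1L, "*", "o"))
    paste(ifelse(sep, paste0("|", g), g), collapse = "")
  }
  header <- glyphRow(rep(NA_integer_, length(sites)))
  header <- chartr(".", "-", header)
  lines <- vapply(seq_len(nrow(calls)), function(i)
    glyphRow(calls[i, ]), character(1L))
  names(lines) <- rownames(calls)
  c(setNames(header, "sites"), lines)
}
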