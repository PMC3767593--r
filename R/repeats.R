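## Tandem-repeat detection, consensus building and probe-monomer search.
##
## Detection is three-stage: (1) candidate periods are voted by the spacing
## histogram of repeated 8-mers; (2) for each candidate period, stretches of
## high lag-p self-similarity are found from the copy-vs-next-copy identity
## profile and delimited at base resolution by a log-likelihood maximal
## subarray on the lag-p match vector; (3) boundaries are copy-quantized:
## full copies are classified by gapless identity against the region
## consensus, with at most one fractional copy at either end. For periods
## shorter than 12 bp the copy phase is enumerated explicitly and edge copies
## must reach the interior copies' identity (a random flank hexamer fakes a
## 5/6 copy far too easily otherwise), and fractional tails shorter than 6 bp
## are never counted - they are indistinguishable from chance flank matches.
## Copy alignment is gapless; copy number is span/period rounded half-up to
## one decimal.

## log-likelihood weights: a base inside the array matches the consensus with
## prob ~0.95, a flank base with 0.25.
LLR_MATCH <- log(0.95 / 0.25)
LLR_MISS <- log(0.05 / 0.75)

#' Detect tandem-repeat regions in a transcript
#'
#' @param transcript Transcript sequence (character or DNAString).
#' @param periodRange Integer c(min, max) period search range, within
#'   [2, 500] (default c(2, 200)).
#' @param minCopies Minimum fractional copy number for a reported region.
#' @param minIdentity Minimum per-copy identity against the region consensus
#'   (in (0.5, 1]).
#' @param minSpan Minimum region span in bp (default 24); shorter stretches
#'   are indistinguishable from chance micro-repeats in random sequence.
#' @return List of [RepeatRegion-class] sorted by transcript position;
#'   regions are maximal and non-overlapping, with smaller (more primitive)
#'   periods claiming a region first.
#' @export
findTandemRepeats <- function(transcript, periodRange = c(2L, 200L),
                              minCopies = 2, minIdentity = 0.7,
                              minSpan = 24L) {
  stopifnot(periodRange[1L] >= 2L, periodRange[2L] <= 500L)
  if (minIdentity <= 0.5 || minIdentity > 1)
    stop("minIdentity must lie in (0.5, 1]")
  s <- strsplit(toupper(dnaToChar(transcript)), "")[[1L]]
  n <- length(s)
  if (n < 2L * periodRange[1L]) return(list())

  periods <- candidatePeriods(s, periodRange)
  cands <- list()
  for (p in sort(periods)) {
    if (n < 2L * p) next
    cands <- c(cands, regionsAtPeriod(s, p, minIdentity, minCopies, minSpan))
  }
  ## an array detected at a multiple of its true period is reduced to the
  ## smallest divisor period that still explains it
  cands <- lapply(cands, reducePrimitive, s = s, minPeriod = periodRange[1L],
                  minIdentity = minIdentity, minCopies = minCopies,
                  minSpan = minSpan)
  if (length(cands) == 0L) return(list())
  ## greedy non-overlapping selection, largest explanatory span first (a
  ## chance micro-repeat inside a long divergent array must not displace it),
  ## smaller period on near-ties
  spans <- vapply(cands, function(r) diff(r@interval) + 1L, 1L)
  ord <- order(-spans, vapply(cands, function(r) r@period, 1L))
  claimed <- IRanges()
  regions <- list()
  for (i in ord) {
    iv <- IRanges(cands[[i]]@interval[1L], cands[[i]]@interval[2L])
    if (length(findOverlaps(iv, claimed)) > 0L) next
    claimed <- c(claimed, iv)
    regions[[length(regions) + 1L]] <- cands[[i]]
  }
  regions[order(vapply(regions, function(r) r@interval[1L], 1L))]
}

## If the region's sequence is also self-similar at a divisor of its period,
## re-refine there: the primitive period wins.
reducePrimitive <- function(reg, s, minPeriod, minIdentity, minCopies,
                            minSpan) {
  p <- reg@period
  n <- length(s)
  divs <- which(p %% seq_len(p - 1L) == 0L)
  divs <- divs[divs >= minPeriod]
  for (d in sort(divs)) {
    a <- reg@interval[1L]
    b <- reg@interval[2L]
    if (b - d <= a) next
    idx <- a:(b - d)
    if (mean(s[idx] == s[idx + d]) < minIdentity) next
    m <- s[seq_len(n - d)] == s[(d + 1L):n]
    r2 <- refineRegion(s, m, d, a, b, minIdentity, minCopies, minSpan)
    if (!is.null(r2)) return(r2)
  }
  reg
}

## Vote candidate periods from spacings between consecutive occurrences of
## repeated 8-mers. An array of period p votes at p (and its multiples, which
## lose to p because periods are tried in ascending order).
candidatePeriods <- function(s, periodRange, k = 8L, minVotes = 4L) {
  n <- length(s)
  if (n < k + periodRange[1L]) return(integer())
  str <- paste(s, collapse = "")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(str, starts, starts + k - 1L)
  o <- order(kmers)
  d <- diff(starts[o])
  same <- kmers[o][-1L] == kmers[o][-length(o)]
  ## order() is stable, so positions stay ascending within a k-mer group
  sp <- d[same]
  sp <- sp[sp >= periodRange[1L] & sp <= periodRange[2L]]
  if (length(sp) == 0L) return(integer())
  tab <- table(sp)
  as.integer(names(tab)[tab >= minVotes])
}

## All verified repeat regions for one period.
regionsAtPeriod <- function(s, p, minIdentity, minCopies, minSpan) {
  n <- length(s)
  m <- s[seq_len(n - p)] == s[(p + 1L):n]
  cm <- cumsum(c(0L, m))
  nw <- n - 2L * p + 1L
  if (nw < 1L) return(list())
  ## identity of the p-window starting at i vs the window one period later
  wid <- (cm[(p + 1L):(p + nw)] - cm[seq_len(nw)]) / p
  seed <- wid >= minIdentity
  if (!any(seed)) return(list())
  r <- rle(seed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= 2L)
  if (length(keep) == 0L) return(list())
  ## long divergent arrays dip below the window threshold here and there;
  ## merge seed runs separated by less than two periods into one stretch
  stretches <- list(c(starts[keep[1L]], ends[keep[1L]]))
  for (j in keep[-1L]) {
    last <- stretches[[length(stretches)]]
    if (starts[j] - last[2L] <= 2L * p) {
      stretches[[length(stretches)]][2L] <- ends[j]
    } else {
      stretches[[length(stretches) + 1L]] <- c(starts[j], ends[j])
    }
  }
  out <- list()
  for (st in stretches) {
    reg <- refineRegion(s, m, p, st[1L], st[2L] + 2L * p - 1L,
                        minIdentity, minCopies, minSpan)
    if (!is.null(reg)) out[[length(out) + 1L]] <- reg
  }
  out
}

## Kadane maximal subarray (first maximal on ties); returns c(from, to) or NULL.
maxSubarray <- function(w) {
  best <- -Inf; bi <- 0L; bj <- 0L
  cur <- 0; ci <- 1L
  for (i in seq_along(w)) {
    if (cur <= 0) { cur <- w[i]; ci <- i } else cur <- cur + w[i]
    if (cur > best) { best <- cur; bi <- ci; bj <- i }
  }
  if (best <= 0) NULL else c(bi, bj)
}

identityVs <- function(s, from, cons) {
  mean(s[from:(from + length(cons) - 1L)] == cons)
}

## Copy-quantized region refinement; `a`..`b` is the rough seeded stretch and
## `m` the precomputed lag-p match vector. The rough base-level bounds come
## from a log-likelihood maximal subarray on m; the copy phase is then
## enumerated and each candidate explanation (full copies plus fractional
## tails) is scored by its total log-likelihood against the tiled consensus,
## which penalises flank bases claimed as array content.
refineRegion <- function(s, m, p, a, b, minIdentity, minCopies, minSpan) {
  n <- length(s)
  lo <- max(1L, a - 2L * p)
  hi <- min(n - p, b + p)
  w <- ifelse(m[lo:hi], LLR_MATCH, LLR_MISS)
  sub <- maxSubarray(w)
  if (is.null(sub)) return(NULL)
  start0 <- lo + sub[1L] - 1L
  end0 <- lo + sub[2L] - 1L + p          # lag-p similarity spans one extra copy
  if (end0 - start0 + 1L < 2L * p) return(NULL)

  best <- NULL
  for (phi in 0:(p - 1L)) {
    fit <- phaseFit(s, p, start0 + phi, end0, minIdentity)
    if (is.null(fit)) next
    if (is.null(best) || fit$score > best$score) best <- fit
  }
  if (is.null(best) || best$nFull < 2L) return(NULL)

  span <- best$regEnd - best$regStart + 1L
  if (span < minSpan) return(NULL)
  copyNumber <- roundHalfUp(span / p, 1L)
  if (copyNumber < minCopies) return(NULL)

  fin <- consensusOfChunks(s, best$firstStart, best$nFull, p)
  meanIdent <- mean(fin$identities)
  if (meanIdent < minIdentity) return(NULL)
  copies <- data.frame(
    start = best$firstStart + (seq_len(best$nFull) - 1L) * p,
    end = best$firstStart + seq_len(best$nFull) * p - 1L,
    identity = fin$identities)
  new("RepeatRegion", interval = c(best$regStart, best$regEnd),
      period = as.integer(p), copyNumber = copyNumber,
      consensus = paste(fin$consensus, collapse = ""),
      meanIdentity = meanIdent, copies = copies)
}

## One candidate phase: full copies by identity walk, fractional tails by a
## log-likelihood walk against the tiled consensus. Short periods (< 12 bp)
## are copy-quantized - no mid-copy cuts, tails of at least 6 bases at the
## interior copies' identity - because a random flank hexamer apes a short
## partial copy far too easily.
phaseFit <- function(s, p, anchor, end0, minIdentity) {
  n <- length(s)
  if (anchor + 2L * p - 1L > min(n, end0 + p)) return(NULL)
  fit <- copyWalk(s, p, anchor, end0, minIdentity, adaptive = p < 12L)
  if (is.null(fit) || fit$nFull < 2L) return(NULL)
  cons <- fit$cons
  firstStart <- fit$firstStart
  lastStart <- firstStart + (fit$nFull - 1L) * p
  partialMin <- if (p < 12L) 6L else 1L
  identThr <- if (p < 12L) max(0.8, fit$interiorMin) else 0.8

  ## right boundary: walk from the last full copy's start; the walk may trim
  ## a straddling copy or extend a fractional tail beyond it
  idxR <- lastStart:min(n, lastStart + 2L * p - 2L)
  eqR <- s[idxR] == cons[((idxR - lastStart) %% p) + 1L]
  llR <- cumsum(ifelse(eqR, LLR_MATCH, LLR_MISS))
  bR <- which.max(llR)
  if (bR > p) {
    extLen <- bR - p
    if (extLen < partialMin || mean(eqR[(p + 1L):bR]) < identThr) bR <- p
  }
  if (p < 12L && bR < p) bR <- p       # no mid-copy cuts at short periods
  nFull <- fit$nFull
  if (llR[bR] <= 0) {
    regEnd <- lastStart - 1L
    nFull <- nFull - 1L
  } else {
    regEnd <- lastStart + bR - 1L
    if (bR < p) nFull <- nFull - 1L
  }

  ## left boundary: fractional lead before the first full copy
  maxL <- min(firstStart - 1L, p - 1L)
  regStart <- firstStart
  if (maxL >= 1L) {
    xs <- firstStart - seq_len(maxL)
    eqL <- s[xs] == cons[((xs - firstStart) %% p) + 1L]  # R %% is non-negative
    llL <- cumsum(ifelse(eqL, LLR_MATCH, LLR_MISS))
    bL <- which.max(llL)
    if (llL[bL] > 0 && bL >= partialMin &&
        mean(eqL[seq_len(bL)]) >= identThr) {
      regStart <- firstStart - bL
    }
  }
  if (nFull < 2L || regEnd <= regStart) return(NULL)

  idx <- regStart:regEnd
  eq <- s[idx] == cons[((idx - firstStart) %% p) + 1L]
  list(score = sum(ifelse(eq, LLR_MATCH, LLR_MISS)),
       regStart = regStart, regEnd = regEnd,
       firstStart = firstStart, nFull = nFull)
}

## Grow full copies outward from an anchor at `start0`, consensus taken from
## the rough core. With `adaptive`, edge copies must reach the interior
## copies' minimum identity (short periods only).
copyWalk <- function(s, p, start0, end0, minIdentity, adaptive) {
  n <- length(s)
  nCore <- (end0 - start0 + 1L) %/% p
  if (nCore < 2L) return(NULL)
  cons <- consensusOfChunks(s, start0, nCore, p)$consensus
  firstStart <- start0
  while (firstStart - p >= 1L &&
         identityVs(s, firstStart - p, cons) >= minIdentity) {
    firstStart <- firstStart - p
  }
  lastStart <- max(firstStart, start0 + (nCore - 1L) * p)
  while (lastStart + 2L * p - 1L <= n &&
         identityVs(s, lastStart + p, cons) >= minIdentity) {
    lastStart <- lastStart + p
  }
  nFull <- (lastStart - firstStart) %/% p + 1L
  ident <- vapply(seq_len(nFull), function(i)
    identityVs(s, firstStart + (i - 1L) * p, cons), numeric(1L))
  interiorMin <- if (nFull > 2L) min(ident[2:(nFull - 1L)]) else min(ident)
  if (adaptive && nFull > 2L) {
    thr <- max(minIdentity, interiorMin)
    while (nFull > 2L && ident[1L] < thr) {
      firstStart <- firstStart + p
      ident <- ident[-1L]
      nFull <- nFull - 1L
    }
    while (nFull > 2L && ident[nFull] < thr) {
      ident <- ident[-nFull]
      nFull <- nFull - 1L
    }
  }
  list(firstStart = firstStart, nFull = nFull, cons = cons,
       identSum = sum(ident), interiorMin = interiorMin)
}

## Majority consensus over nFull chunks of length p starting at `from`.
consensusOfChunks <- function(s, from, nFull, p) {
  mat <- matrix(s[from:(from + nFull * p - 1L)], nrow = p)
  baseOrder <- c("A", "C", "G", "T")
  cons <- apply(mat, 1L, function(col) {
    cnt <- tabulate(match(col, baseOrder), nbins = 4L)
    baseOrder[which.max(cnt)]   # ties resolved in fixed A<C<G<T order
  })
  identities <- colMeans(mat == cons)
  list(consensus = cons, identities = identities)
}

#' Build a consensus monomer for a repeat region
#'
#' Copies are aligned gaplessly at the fixed period; the consensus is the
#' per-column majority base, ties resolved in fixed A<C<G<T order. A
#' trailing partial copy (when the region length is not a period multiple)
#' is excluded from the consensus but reported.
#'
#' @param regionSeq Repeat-region sequence (>= 2 periods long).
#' @param period Monomer length in bp.
#' @return list(consensus = character monomer, identities = per-copy identity
#'   vs the consensus, tieColumns = columns whose majority was tied).
#' @export
buildConsensus <- function(regionSeq, period) {
  s <- strsplit(toupper(dnaToChar(regionSeq)), "")[[1L]]
  if (length(s) < 2L * period)
    stop("region must span at least two full periods")
  nFull <- length(s) %/% period
  mat <- matrix(s[seq_len(nFull * period)], nrow = period)
  baseOrder <- c("A", "C", "G", "T")
  counts <- apply(mat, 1L, function(col)
    tabulate(match(col, baseOrder), nbins = 4L))
  cons <- baseOrder[apply(counts, 2L, which.max)]
  ties <- which(apply(counts, 2L, function(x) sum(x == max(x)) > 1L))
  identities <- colMeans(mat == cons)
  list(consensus = paste(cons, collapse = ""), identities = identities,
       tieColumns = as.integer(ties))
}

#' Search a transcript for a probe monomer
#'
#' Best gapless sliding-window identity of the probe against the transcript -
#' the query-monomer mode used to test for the absence of a repeat family
#' (absence = best identity below `threshold`).
#'
#' @param transcript Transcript sequence.
#' @param probe Probe monomer.
#' @param threshold Presence threshold on identity (default 0.7).
#' @return list(bestIdentity, position = 1-based start of the best window,
#'   present).
#' @export
probeMonomer <- function(transcript, probe, threshold = 0.7) {
  s <- strsplit(toupper(dnaToChar(transcript)), "")[[1L]]
  q <- strsplit(toupper(dnaToChar(probe)), "")[[1L]]
  n <- length(s)
  L <- length(q)
  if (L > n) stop("probe longer than transcript")
  nw <- n - L + 1L
  cnt <- integer(nw)
  for (j in seq_len(L)) {
    cnt <- cnt + (s[j:(nw + j - 1L)] == q[j])
  }
  best <- which.max(cnt)
  list(bestIdentity = cnt[best] / L, position = best,
       present = cnt[best] / L >= threshold)
}
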