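## Independent oracles and fixture builders shared across the suite.
## Oracles are deliberately naive (quadratic DP, exhaustive recursion, direct
## tallies) and never call the code paths they check.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

mutateSeq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

## ---- local alignment oracle (Biostrings dynamic programming) --------------

swOracleScore <- function(query, subject) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = TRUE)
  fwd <- Biostrings::score(Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 2))
  rev <- Biostrings::score(Biostrings::pairwiseAlignment(
    rcomp(query), subject, type = "local", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 2))
  as.integer(max(fwd, rev))
}

## ---- read-mapping oracle (plain R double loop) ----------------------------

mapOracleR <- function(read, ref, maxMM) {
  rl <- nchar(read)
  L <- nchar(ref)
  best <- list(mm = maxMM + 1L, pos = NA_integer_, strand = NA_character_)
  for (str in c("+", "-")) {
    q <- if (str == "+") read else rcomp(read)
    qc <- strsplit(q, "")[[1]]
    for (p in seq_len(L - rl + 1L)) {
      mm <- sum(qc != strsplit(substr(ref, p, p + rl - 1L), "")[[1]])
      if (mm < best$mm || (mm == best$mm && !is.na(best$pos) && p < best$pos)) {
        best <- list(mm = mm, pos = p, strand = str)
      }
    }
  }
  if (best$mm > maxMM) return(NULL)
  best
}

## ---- candidate-region oracle (explicit merge + predicate) -----------------

candOracle <- function(hits, minScore, minSpecies) {
  if (nrow(hits) == 0L) return(NULL)
  o <- order(hits$sStart, hits$sEnd)
  h <- hits[o, , drop = FALSE]
  merged <- list(c(h$sStart[1L], h$sEnd[1L]))
  for (i in seq_len(nrow(h))[-1L]) {
    last <- merged[[length(merged)]]
    ## integer-interval union: adjacent ranges ([a,b], [b+1,c]) coalesce
    if (h$sStart[i] <= last[2L] + 1L) {
      merged[[length(merged)]][2L] <- max(last[2L], h$sEnd[i])
    } else {
      merged[[length(merged) + 1L]] <- c(h$sStart[i], h$sEnd[i])
    }
  }
  out <- NULL
  for (iv in merged) {
    inReg <- hits$sStart <= iv[2L] & hits$sEnd >= iv[1L]
    strong <- hits[inReg & hits$score > minScore, , drop = FALSE]
    if (length(unique(strong$species)) >= minSpecies) {
      out <- rbind(out, data.frame(start = iv[1L], end = iv[2L],
                                   nSpecies = length(unique(strong$species))))
    }
  }
  out
}

## ---- folding oracles ------------------------------------------------------

## exhaustive max-pair count by naive recursion (no memoisation, no DP table)
enumMaxPairs <- function(s, minLoop = 3L) {
  ch <- strsplit(toupper(s), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < minLoop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + minLoop + 1L):j) {
      if (ok(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(ch))
}

## hairpin count by explicit pair matching: a hairpin is a pair whose
## enclosed substring contains no brackets
stemLoopOracle <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  stack <- integer(0)
  pairs <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (is.null(pairs)) return(0L)
  sum(apply(pairs, 1L, function(p) {
    inner <- ch[seq(p[1L] + 1L, p[2L] - 1L)]
    all(inner == ".")
  }))
}

## ---- tandem-array fixture (built directly, not via buildScaffold) ---------

plantArray <- function(period, copies, divergence, flank = 400L,
                       monomer = NULL) {
  if (is.null(monomer)) {
    ## junction-safe and primitive: a monomer that is itself periodic would
    ## plant an array of a smaller true period
    isPrimitive <- function(m) {
      divs <- setdiff(which(period %% seq_len(period - 1L) == 0L), period)
      !any(vapply(divs, function(d)
        all(m == m[((seq_along(m) - 1L) %% d) + 1L]), logical(1)))
    }
    repeat {
      monomer <- sample(BASES, period, replace = TRUE)
      if (!(monomer[period] == "C" && monomer[1L] == "G") &&
          isPrimitive(monomer)) break
    }
  } else {
    monomer <- strsplit(monomer, "")[[1]]
  }
  full <- floor(copies)
  part <- round((copies - full) * period)
  mut <- function(m) {
    hit <- which(stats::runif(length(m)) < divergence)
    for (i in hit) m[i] <- sample(setdiff(BASES, m[i]), 1)
    m
  }
  arr <- unlist(c(lapply(seq_len(full), function(i) mut(monomer)),
                  if (part > 0L) list(mut(monomer)[seq_len(part)])))
  left <- sample(BASES, flank, replace = TRUE)
  right <- sample(BASES, flank, replace = TRUE)
  list(seq = paste(c(left, arr, right), collapse = ""),
       start = flank + 1L,
       end = flank + length(arr),
       copies = copies, period = period,
       monomer = paste(monomer, collapse = ""))
}

## ---- misc -----------------------------------------------------------------

## single-linkage CpG clustering oracle on the gap-free promoter axis
denseOracle <- function(sites, maxGap, minSites) {
  sites <- sort(sites)
  lin <- ifelse(sites > 0L, sites, sites + 1L)
  groups <- list(1L)
  for (i in seq_along(sites)[-1L]) {
    if (lin[i] - lin[i - 1L] <= maxGap) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], i)
    } else {
      groups[[length(groups) + 1L]] <- i
    }
  }
  out <- NULL
  for (g in groups) {
    if (length(g) >= minSites) {
      out <- rbind(out, data.frame(start = sites[g[1L]],
                                   end = sites[g[length(g)]],
                                   nSites = length(g)))
    }
  }
  out
}

## a quick 7-exon gene spec with small features for round-trip tests
smallGeneSpec <- function(nExons = 7L) {
  exons <- sample(60:240, nExons, replace = TRUE)
  introns <- sample(25:90, nExons - 1L, replace = TRUE)
  GeneSpec(exonLengths = exons, intronLengths = introns,
           flankLengths = c(upstream = 80L, downstream = 60L),
           promoterCpgOffsets = integer(),
           gap = list(intron = NA_integer_, fillLength = 0L, placeholder = 0L),
           promoterWindow = 60L)
}

## shared desk-scale bundle (built once per test run)
deskBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildScaffold(deskGeneSpec(), seed = 1L)
    cache
  }
})
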