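test_that("paper-scale preset reproduces the published transcript and span arithmetic", {
  spec <- paperScaleGeneSpec()
  ## independent arithmetic: sum the published table lengths by hand
  exp_tx <- 17184 + 89 + 136 + 209 + 329 + 129 + 7139
  exp_span <- exp_tx + 1460 + 2271 + 2136 + 356 + 390 + 989
  expect_identical(exp_tx, 25215)
  expect_identical(exp_span, 32817)
  b <- buildScaffold(spec, seed = 3)
  expect_identical(length(transcriptSeq(b)), 25215L)
  tr <- truthTable(b)
  expect_identical(sum(IRanges::width(tr$exons)) + sum(IRanges::width(tr$introns)),
                   32817L)
})

test_that("a single-exon spec degenerates to span = exon length", {
  spec <- GeneSpec(exonLengths = 500L, intronLengths = integer(),
                   flankLengths = c(upstream = 80L, downstream = 60L),
                   gap = list(intron = NA_integer_, fillLength = 0L,
                              placeholder = 0L),
                   promoterWindow = 60L)
  b <- buildScaffold(spec, seed = 5)
  tr <- truthTable(b)
  expect_identical(length(transcriptSeq(b)), 500L)
  expect_identical(sum(IRanges::width(tr$exons)), 500L)
  expect_length(tr$introns, 0L)
})

test_that("identical (spec, seed) give byte-identical output; seeds differ", {
  a <- buildScaffold(deskGeneSpec(), seed = 11)
  b <- buildScaffold(deskGeneSpec(), seed = 11)
  c <- buildScaffold(deskGeneSpec(), seed = 12)
  expect_identical(as.character(scaffoldSeq(a)), as.character(scaffoldSeq(b)))
  expect_identical(truthTable(a)$geneForwardSeq, truthTable(b)$geneForwardSeq)
  expect_false(identical(as.character(scaffoldSeq(a)),
                         as.character(scaffoldSeq(c))))
})

test_that("every planted intron carries the canonical dinucleotides on the transcribed strand", {
  b <- deskBundle()
  tr <- truthTable(b)
  g <- tr$geneForwardSeq
  it <- tr$intronsGene
  for (i in seq_along(it)) {
    expect_identical(substr(g, IRanges::start(it)[i], IRanges::start(it)[i] + 1L), "GT")
    expect_identical(substr(g, IRanges::end(it)[i] - 1L, IRanges::end(it)[i]), "AG")
  }
})

test_that("CG dinucleotides in the promoter window sit exactly at the declared offsets", {
  b <- deskBundle()
  win <- promoterWindowSeq(b)
  occ <- gregexpr("CG", win, fixed = TRUE)[[1]]
  occ <- occ[occ > 0]
  got <- ifelse(occ - 2000L >= 1L, occ - 2000L, occ - 2001L)
  expect_identical(as.integer(got), geneSpec(b)@promoterCpgOffsets)
  expect_length(got, 78L)
})

test_that("conflicting feature plants are rejected with a named conflict", {
  spec <- deskGeneSpec()
  bad <- spec
  bad@repeatSpecs[[2]] <- RepeatSpec(6L, 40L, 2060L)   # runs into the 96-mer
  expect_error(validObject(bad), "overlap")
  ## a CpG offset punched into the planted TSS-proximal motif must conflict
  spec2 <- deskGeneSpec()
  spec2@promoterCpgOffsets <- sort(unique(c(spec2@promoterCpgOffsets, -3L)))
  expect_error(buildScaffold(spec2, seed = 1), "conflict")
})

test_that("5' RACE clones start exactly at the planted offsets", {
  b <- deskBundle()
  offs <- c(-5L, -3L, 1L, 16L, 48L, 72L, 143L, 211L)
  clones <- simulateRaceClones(b, "five", offsets = offs,
                               clonesPerOffset = 2, seed = 21)
  expect_length(clones, 16L)
  ## brute-force oracle: every clone with offset +1 must start at the TSS
  one <- simulateRaceClones(b, "five", offsets = 1L, clonesPerOffset = 5,
                            seed = 22)
  tr <- truthTable(b)
  sc <- tr$scaffoldFilled
  for (i in seq_along(one)) {
    probe <- rcomp(substr(as.character(one[[i]]), 1, 40))   # minus-strand gene
    hit <- regexpr(probe, sc, fixed = TRUE)
    expect_identical(as.integer(hit) + 39L, tr$tssPos)
  }
  expect_length(simulateRaceClones(b, "five", offsets = 1L,
                                   clonesPerOffset = 0, seed = 1), 0L)
  expect_error(simulateRaceClones(b, "five", offsets = 99999L, seed = 1),
               "outside the gene span")
})

test_that("3' RACE clones end at the terminus and carry a poly-A tract", {
  b <- deskBundle()
  clones <- simulateRaceClones(b, "three", clonesPerOffset = 4, seed = 23)
  tx <- as.character(transcriptSeq(b))
  for (i in seq_along(clones)) {
    cl <- as.character(clones[[i]])
    body <- sub("A*$", "", cl)
    expect_gte(nchar(cl) - nchar(body), 10L)
    expect_identical(substr(tx, nchar(tx) - nchar(body) + 1L, nchar(tx)), body)
  }
})

test_that("bisulfite simulation respects conversion and methylation truth", {
  spec <- deskGeneSpec()
  spec@methylProfile <- list(male = 1.0, female = 0.5)
  b <- buildScaffold(spec, seed = 31)
  ## fully methylated, perfect conversion: clone equals reference at every C
  bs <- simulateBisulfiteClones(b, "male", nClones = 2,
                                conversionRate = 1.0, seed = 32)
  tr <- truthTable(b)
  u <- tr$upstreamFlank
  for (i in seq_along(bs$clones)) {
    nm <- names(bs$clones)[i]
    reg <- bs$regions[bs$regions$region == sub("male_(BS[0-9]+)_.*", "\\1", nm), ]
    ref <- substr(tr$geneForwardSeq,
                  ifelse(reg$start > 0, u + reg$start, u + 1 + reg$start),
                  ifelse(reg$end > 0, u + reg$end, u + 1 + reg$end))
    cl <- as.character(bs$clones[[i]])
    refc <- strsplit(ref, "")[[1]]
    clc <- strsplit(cl, "")[[1]]
    cgpos <- which(refc == "C" & c(refc[-1], "") == "G")
    nonCg <- setdiff(which(refc == "C"), cgpos)
    expect_true(all(clc[cgpos] == "C"))        # methylated CpGs protected
    expect_true(all(clc[nonCg] == "T"))        # all other Cs convert
    expect_identical(clc[refc != "C"], refc[refc != "C"])
  }
})

test_that("female per-site truth states pool to ~0.5 within 3 binomial SDs", {
  b <- deskBundle()
  bs <- simulateBisulfiteClones(b, "female", nClones = 200,
                                conversionRate = 0.99, seed = 33)
  ## Monte-Carlo tally of the generator's own truth states
  frac <- mean(bs$truth$methylated)
  n <- nrow(bs$truth)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("RNA-seq pairs are transcript 90-mers; male yields none", {
  b <- deskBundle()
  rr <- simulateRnaseq(b, "female", nPairs = 60, readLen = 90,
                       insert = 200, seed = 41)
  tx <- as.character(transcriptSeq(b))
  for (r in as.character(c(rr$read1, rr$read2))) {
    expect_identical(nchar(r), 90L)
    inTx <- grepl(r, tx, fixed = TRUE) || grepl(rcomp(r), tx, fixed = TRUE)
    expect_true(inTx)
  }
  empty <- simulateRnaseq(b, "female", nPairs = 0, seed = 1)
  expect_length(empty$read1, 0L)
  male <- simulateRnaseq(b, "male", nPairs = 50, seed = 1)
  expect_length(male$read1, 0L)
  expect_error(simulateRnaseq(b, "female", insert = 1e6, seed = 1),
               "insert")
})

test_that("cDNA amplicons shrink by the spanned intron lengths; gDNA keeps them", {
  b <- deskBundle()
  tx <- as.character(transcriptSeq(b))
  ## primers in exon 1 and exon 7 (outside the repeat arrays) span all six
  ## introns (761 bp at desk scale)
  p1 <- substr(tx, 1700, 1719)
  p2 <- rcomp(substr(tx, 4700, 4719))
  ac <- simulateAmplicons(b, list(E2EL = c(p1, p2)), "cdna")
  ag <- simulateAmplicons(b, list(E2EL = c(p1, p2)), "gdna")
  expect_identical(IRanges::width(ag) - IRanges::width(ac),
                   sum(geneSpec(b)@intronLengths))
  ## a within-exon pair gives identical amplicons on both templates
  q1 <- substr(tx, 700, 719)
  q2 <- rcomp(substr(tx, 1100, 1119))
  expect_identical(as.character(simulateAmplicons(b, list(c(q1, q2)), "cdna")),
                   as.character(simulateAmplicons(b, list(c(q1, q2)), "gdna")))
  expect_error(simulateAmplicons(b, list(c("ACGTACGTACGTACGTACGT", q2)), "cdna"),
               "not found")
})

test_that("a gap-flanking gDNA amplicon is longer by the fill-placeholder delta", {
  b <- deskBundle()
  tr <- truthTable(b)
  g <- tr$geneForwardSeq
  gs <- tr$gap$gFillStart
  ge <- tr$gap$gFillEnd
  fwd <- substr(g, gs - 120, gs - 101)
  rev <- rcomp(substr(g, ge + 101, ge + 120))
  amp <- simulateAmplicons(b, list(c(fwd, rev)), "gdna")
  ## truth arithmetic: 120+120 flank + fill 80; N-placeholder form would be 260
  expect_identical(IRanges::width(amp), 240L + tr$gap$delta + 20L)
  expect_identical(IRanges::width(amp) - (240L + 20L), tr$gap$delta)
})

test_that("GeneSpec invariants reject malformed specifications", {
  expect_error(GeneSpec(exonLengths = c(100L, 50L),
                        intronLengths = integer(),
                        flankLengths = c(upstream = 80L, downstream = 60L),
                        promoterWindow = 60L),
               "intronLengths")
  expect_error(RepeatSpec(6L, 1.5, 100L), "copies")
  expect_error(RepeatSpec(6L, 5, 100L, divergence = 0.5), "divergence")
  spec <- deskGeneSpec()
  spec@promoterCpgOffsets <- c(-5L, 0L, 10L)
  expect_error(validObject(spec), "0")
})
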