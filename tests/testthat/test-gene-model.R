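test_that("an unspliced amplicon yields a single exon and no introns", {
  set.seed(201)
  g <- randSeq(400)
  mdl <- inferExons(g, substr(g, 51, 350))
  expect_length(modelExons(mdl), 1L)
  expect_length(modelIntrons(mdl), 0L)
  expect_identical(c(IRanges::start(modelExons(mdl)),
                     IRanges::end(modelExons(mdl))), c(51L, 350L))
})

test_that("the desk-scale 7-exon truth model is recovered from its transcript", {
  b <- deskBundle()
  tr <- truthTable(b)
  u <- tr$upstreamFlank
  span <- sum(IRanges::width(tr$exonsGene)) + sum(IRanges::width(tr$intronsGene))
  region <- substr(tr$geneForwardSeq, u + 1L, u + span)
  mdl <- inferExons(region, as.character(transcriptSeq(b)))
  expect_identical(IRanges::width(modelExons(mdl)), geneSpec(b)@exonLengths)
  expect_identical(IRanges::width(modelIntrons(mdl)), geneSpec(b)@intronLengths)
  ## planted coordinates match exactly (gene-frame offset u)
  expect_identical(IRanges::start(modelExons(mdl)) + u,
                   IRanges::start(tr$exonsGene))
  ss <- validateSpliceSites(mdl, region)
  expect_true(all(ss$canonical))
})

test_that("random multi-exon plants are recovered across seeds (splice-check oracle)", {
  for (seed in 1:20) {
    set.seed(300 + seed)
    b <- buildScaffold(smallGeneSpec(sample(3:7, 1)), seed = 300 + seed)
    tr <- truthTable(b)
    u <- tr$upstreamFlank
    span <- sum(IRanges::width(tr$exonsGene)) +
      sum(IRanges::width(tr$intronsGene))
    region <- substr(tr$geneForwardSeq, u + 1L, u + span)
    amp <- as.character(transcriptSeq(b))
    mdl <- inferExons(region, amp)
    ## oracle: splicing the reported exons must reproduce the amplicon
    spliced <- paste(vapply(seq_along(modelExons(mdl)), function(i)
      substr(region, IRanges::start(modelExons(mdl))[i],
             IRanges::end(modelExons(mdl))[i]), ""), collapse = "")
    expect_identical(spliced, amp)
    ## and the planted structure is recovered exactly
    expect_identical(IRanges::width(modelExons(mdl)), geneSpec(b)@exonLengths)
    expect_true(all(validateSpliceSites(mdl, region)$canonical))
  }
})

test_that("an unexplainable amplicon reports its best partial explanation", {
  set.seed(202)
  g <- randSeq(300)
  amp <- paste0(substr(g, 1, 80), randSeq(60))
  expect_error(inferExons(g, amp), "partial explanation")
})

test_that("non-canonical donors are flagged; minus-strand dinucleotides read from the reverse complement", {
  set.seed(203)
  g <- randSeq(260)
  ## plant a GC..AG intron at 101..160 by hand
  gch <- strsplit(g, "")[[1]]
  gch[101:102] <- c("G", "C")
  gch[159:160] <- c("A", "G")
  g <- paste(gch, collapse = "")
  mdl <- ExonIntronModel <- new("ExonIntronModel",
                                exons = IRanges::IRanges(c(1L, 161L), c(100L, 260L)),
                                introns = IRanges::IRanges(101L, 160L),
                                strand = "+")
  ss <- validateSpliceSites(mdl, g)
  expect_identical(ss$donor, "GC")
  expect_false(ss$canonical)
  ## minus strand: hand-computed reverse-complement case. The transcribed
  ## strand of a minus-strand intron at forward coords 41..100 starts at
  ## forward position 100 reading leftwards.
  fwd <- paste(rep("A", 140), collapse = "")
  fch <- strsplit(fwd, "")[[1]]
  fch[99:100] <- c("A", "C")   # revcomp("AC") = "GT" -> donor
  fch[41:42] <- c("C", "T")    # revcomp("CT") = "AG" -> acceptor
  fwd <- paste(fch, collapse = "")
  mdl2 <- new("ExonIntronModel",
              exons = IRanges::IRanges(c(101L, 1L), c(140L, 40L)),
              introns = IRanges::IRanges(41L, 100L), strand = "-")
  ss2 <- validateSpliceSites(mdl2, fwd)
  expect_identical(ss2$donor, "GT")
  expect_identical(ss2$acceptor, "AG")
  expect_true(ss2$canonical)
  ## introns shorter than 4 nt are rejected
  mdl3 <- new("ExonIntronModel",
              exons = IRanges::IRanges(c(1L, 104L), c(100L, 140L)),
              introns = IRanges::IRanges(101L, 103L), strand = "+")
  expect_error(validateSpliceSites(mdl3, fwd), "shorter")
})

test_that("fillGap recovers the planted fill and its delta", {
  b <- deskBundle()
  tr <- truthTable(b)
  g <- tr$geneForwardSeq
  gs <- tr$gap$gFillStart
  ge <- tr$gap$gFillEnd
  amp <- substr(g, gs - 150, ge + 150)
  fg <- fillGap(as.character(scaffoldSeq(b)), amp)
  expect_identical(fg$delta, 60L)
  expect_identical(nchar(fg$fillSequence), 80L)
  expect_identical(fg$scaffoldFilled, tr$scaffoldFilled)
  expect_false(grepl("N", fg$fillSequence, fixed = TRUE))
})

test_that("a fill the same length as the N-run gives delta 0", {
  set.seed(204)
  true <- randSeq(500)
  pub <- paste0(substr(true, 1, 200), strrep("N", 60), substr(true, 261, 500))
  fg <- fillGap(pub, substr(true, 120, 380))
  expect_identical(fg$delta, 0L)
  expect_identical(fg$scaffoldFilled, true)
})

test_that("randomized gap fills reconstruct the truth scaffold exactly", {
  for (seed in 1:10) {
    set.seed(400 + seed)
    fl <- sample(40:400, 1)
    true <- randSeq(800 + fl)
    a <- 300L
    pub <- paste0(substr(true, 1, a), strrep("N", 25),
                  substr(true, a + fl + 1, nchar(true)))
    amp <- substr(true, a - 99, a + fl + 100)
    fg <- fillGap(pub, if (seed %% 2) amp else rcomp(amp))
    expect_identical(fg$scaffoldFilled, true)
    expect_identical(fg$delta, fl - 25L)
  }
  expect_error(fillGap(randSeq(300), randSeq(200)), "flanks")
})

test_that("buildTranscript round-trips every coordinate through the map", {
  b <- deskBundle()
  tr <- truthTable(b)
  mdl <- new("ExonIntronModel", exons = tr$exons, introns = tr$introns,
             strand = "-")
  rec <- buildTranscript(mdl, tr$scaffoldFilled)
  expect_identical(as.character(rec@sequence),
                   as.character(transcriptSeq(b)))
  Lt <- length(rec@sequence)
  ## exhaustive round trip: tx -> scaffold -> tx is the identity
  s <- txToScaffold(rec, seq_len(Lt))
  expect_identical(scaffoldToTx(rec, s), seq_len(Lt))
  expect_identical(anyDuplicated(s), 0L)
  ## the minus-strand convention: transcript position t at scaffold tss-t+1
  ## within exon 1
  expect_identical(s[1:10], tr$tssPos - (1:10) + 1L)
})

test_that("residual N in an exon aborts transcript construction", {
  b <- deskBundle()
  tr <- truthTable(b)
  mdl <- new("ExonIntronModel", exons = tr$exons, introns = tr$introns,
             strand = "-")
  withN <- tr$scaffoldFilled
  substr(withN, IRanges::start(tr$exons)[1] + 5L,
         IRanges::start(tr$exons)[1] + 5L) <- "N"
  expect_error(buildTranscript(mdl, withN), "N")
})

test_that("summarizeModel reproduces the published length column and totals", {
  p <- buildScaffold(paperScaleGeneSpec(), seed = 3)
  tr <- truthTable(p)
  mdl <- new("ExonIntronModel", exons = tr$exons, introns = tr$introns,
             strand = "-")
  smry <- summarizeModel(mdl, tr$scaffoldFilled)
  featRows <- smry[!grepl("Transcript|span", smry$feature), ]
  expect_identical(featRows$length,
                   c(17184L, 1460L, 89L, 2271L, 136L, 2136L, 209L, 356L,
                     329L, 390L, 129L, 989L, 7139L))
  expect_identical(smry$length[smry$feature == "Transcript (exons)"], 25215L)
  expect_identical(smry$length[smry$feature == "Gene span"], 32817L)
  ## splicing the exon rows back together reproduces the transcript
  rec <- buildTranscript(mdl, tr$scaffoldFilled)
  exSeqs <- vapply(seq_along(tr$exons), function(i)
    rcomp(substr(tr$scaffoldFilled, IRanges::start(tr$exons)[i],
                 IRanges::end(tr$exons)[i])), "")
  expect_identical(paste(exSeqs, collapse = ""), as.character(rec@sequence))
  ## first 8 nt of each intron start with GT on the transcribed strand
  intronRows <- smry[grepl("^Intron", smry$feature), ]
  expect_true(all(startsWith(intronRows$first8, "GT")))
  expect_true(all(endsWith(intronRows$last8, "AG")))
})

test_that("a single-exon model summarises to one feature row", {
  set.seed(205)
  g <- randSeq(300)
  mdl <- inferExons(g, g)
  smry <- summarizeModel(mdl, g)
  expect_identical(nrow(smry), 3L)   # one exon + two totals rows
  expect_identical(smry$length[1], 300L)
})
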