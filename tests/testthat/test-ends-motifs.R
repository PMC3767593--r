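test_that("eight planted TSS offsets are called exactly, never merged", {
  b <- deskBundle()
  offs <- c(-5L, -3L, 1L, 16L, 48L, 72L, 143L, 211L)
  clones <- simulateRaceClones(b, "five", offsets = offs,
                               clonesPerOffset = 3, seed = 51)
  ct <- callTss(clones, b)
  expect_identical(ct$calls$offset, sort(offs))
  expect_identical(ct$calls$support, rep(3L, 8L))
  expect_identical(ct$excluded, 0L)
  ## -5 and -3 (2 bp apart) stay distinct calls
  expect_true(all(c(-5L, -3L) %in% ct$calls$offset))
})

test_that("clones at a single offset give a single call; random offset sets are recovered", {
  b <- deskBundle()
  one <- simulateRaceClones(b, "five", offsets = 1L, clonesPerOffset = 6,
                            seed = 52)
  ct <- callTss(one, b)
  expect_identical(nrow(ct$calls), 1L)
  expect_identical(ct$calls$offset, 1L)
  expect_identical(ct$referenceTss, truthTable(b)$tssPos)
  ## 100 random planted offsets -> call set equals the planted distinct set
  set.seed(53)
  offs <- sample(setdiff(-300:400, 0L), 100, replace = TRUE)
  clones <- simulateRaceClones(b, "five", offsets = offs,
                               clonesPerOffset = 1, seed = 54)
  ct2 <- callTss(clones, b, minSupport = 1)
  expect_identical(ct2$calls$offset, sort(unique(offs)))
  ## no call ever touches coordinate 0
  expect_true(all(ct2$calls$offset != 0L))
})

test_that("the terminus is called 10 bp downstream of the expected site (inclusive count)", {
  b <- deskBundle()
  clones <- simulateRaceClones(b, "three", clonesPerOffset = 5, seed = 55)
  tm <- callTerminus(clones, b)
  expect_identical(tm$scaffoldPosition, truthTable(b)$terminusPos)
  expect_identical(tm$offsetInclusive, 10L)
  expect_identical(tm$offsetDifference, 9L)
})

test_that("a terminus at the expected site reports inclusive 1 / shift 0", {
  b <- deskBundle()
  clones <- simulateRaceClones(b, "three", clonesPerOffset = 4, seed = 56)
  tm <- callTerminus(clones, b, expected = truthTable(b)$terminusPos)
  expect_identical(tm$offsetInclusive, 1L)
  expect_identical(tm$offsetDifference, 0L)
})

test_that("random terminus placements are recovered across seeds", {
  b <- deskBundle()
  tx <- as.character(transcriptSeq(b))
  Lt <- nchar(tx)
  tr <- truthTable(b)
  ## when the planted end abuts a genomic A-run the poly-A junction is
  ## irresolvable; the documented convention takes the longest genomic match,
  ## so the truth-side oracle extends the planted end over that A-run
  genomicARun <- function(pos) {
    k <- 0L
    while (pos + k + 1L <= Lt && substr(tx, pos + k + 1L, pos + k + 1L) == "A")
      k <- k + 1L
    k
  }
  for (seed in 1:15) {
    set.seed(500 + seed)
    pos <- sample((Lt - 400):Lt, 1)
    clones <- simulateRaceClones(b, "three", offsets = pos,
                                 clonesPerOffset = 3, seed = 500 + seed)
    tm <- callTerminus(clones, b)
    expPos <- pos + genomicARun(pos)
    expect_identical(tm$txPosition, expPos)
    expect_identical(tm$scaffoldPosition, tr$txMapScaffold[expPos])
  }
  expect_error(callTerminus(Biostrings::DNAStringSet("ACGTACGT"), b),
               "poly-A")
})

test_that("the poly-A signal is found 21 bp upstream of the terminus", {
  b <- deskBundle()
  tx <- as.character(transcriptSeq(b))
  sig <- findPolyASignal(tx, nchar(tx))
  expect_identical(sig$pattern, "AATAAA")
  expect_identical(sig$distance, 21L)
  ## absence in a signal-free window
  expect_null(findPolyASignal(strrep("C", 200), 200L))
  ## multiple signals: the nearest upstream one wins (exhaustive-scan oracle)
  s <- paste0(strrep("C", 50), "AATAAA", strrep("C", 30), "AATAAA",
              strrep("C", 10))
  got <- findPolyASignal(s, nchar(s), window = 90)
  occ <- gregexpr("AATAAA", s, fixed = TRUE)[[1]]
  nearestEnd <- max(occ + 5L)
  expect_identical(got$end, as.integer(nearestEnd))
  expect_identical(got$distance, nchar(s) - as.integer(nearestEnd))
  expect_error(findPolyASignal(s, 50L, window = 5), "window")
})

test_that("promoter motifs are found at their planted no-zero coordinates", {
  b <- deskBundle()
  hits <- scanMotifs(b, c("TTAAAG", "CCGCCATNTT"))
  tb <- hits[hits$pattern == "TTAAAG" & hits$strand == "+", ]
  expect_true(any(tb$start == -30L & tb$end == -25L))
  yy <- hits[hits$pattern == "CCGCCATNTT", ]
  expect_identical(nrow(yy), 1L)
  expect_identical(c(yy$start, yy$end), c(-6L, 4L))   # interval crosses the 0 gap
  expect_identical(yy$match, "CCGCCATATT")            # N matched an A
  ## a 10-mer spanning -6..+4 covers 10 bases (no position 0)
  expect_identical(nchar(yy$match), 10L)
  ## absent pattern -> empty
  expect_identical(nrow(scanMotifs(b, "AAACCCGGGTTTAAACCCGGG")), 0L)
  ## no motif interval touches 0
  expect_true(all(hits$start != 0L & hits$end != 0L))
})

test_that("restriction digests cut where the site dictates and conserve length", {
  amp <- paste0(strrep("C", 399), "TTTAAA", strrep("G", 595))
  res <- digestAmplicon(amp, list(name = "DraI", site = "TTTAAA",
                                  cutOffset = 3L))
  expect_identical(res$fragmentLengths, c(402L, 598L))
  expect_identical(res$cutPositions, 402L)
  ## no site -> a single full-length fragment
  none <- digestAmplicon(strrep("C", 750),
                         list(name = "DraI", site = "TTTAAA", cutOffset = 3L))
  expect_identical(none$fragmentLengths, 750L)
  ## random amplicons: fragments always sum to the length and match a
  ## position-scan oracle
  set.seed(61)
  for (i in 1:50) {
    a <- randSeq(sample(200:1200, 1))
    site <- randSeq(5)
    res <- digestAmplicon(a, list(name = "x", site = site, cutOffset = 2L))
    expect_identical(sum(res$fragmentLengths), nchar(a))
    ## overlap-aware position scan
    occ <- which(vapply(seq_len(nchar(a) - 4L), function(p)
      substr(a, p, p + 4L) == site, logical(1)))
    cuts <- sort(unique(occ + 1L))
    cuts <- cuts[cuts >= 1L & cuts < nchar(a)]
    expect_identical(res$cutPositions, as.integer(cuts))
  }
})
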