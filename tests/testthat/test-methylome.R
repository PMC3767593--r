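test_that("scanCpg finds the planted 78 sites and matches a regex oracle", {
  b <- deskBundle()
  m <- scanCpg(b)
  expect_length(m$sites, 78L)
  expect_identical(m$sites, geneSpec(b)@promoterCpgOffsets)
  ## CG-free window -> empty map
  expect_length(scanCpg(strrep("AT", 3000), tss = 2500L, window = 2000L)$sites,
                0L)
  expect_error(scanCpg(strrep("AT", 100), tss = 100L, window = 2000L),
               "cover")
  ## random references vs a direct regex position scan
  set.seed(801)
  for (i in 1:25) {
    ref <- randSeq(600)
    tss <- 300L
    W <- 200L
    got <- scanCpg(ref, tss = tss, window = W)$sites
    occ <- gregexpr("CG", ref, fixed = TRUE)[[1]]
    occ <- occ[occ > 0]
    rel <- occ - tss + 1L                       # +1 = TSS base
    rel <- rel[rel >= -W + 1L & rel <= W]
    exp <- ifelse(rel >= 1L, rel, rel - 1L)
    exp <- exp[exp >= -W & exp <= W]
    expect_identical(got, as.integer(exp))
  }
})

test_that("dense regions reproduce the published two-cluster layout", {
  b <- deskBundle()
  dr <- denseRegions(scanCpg(b))
  expect_identical(nrow(dr), 2L)
  expect_identical(dr$start, c(-284L, 285L))
  expect_identical(dr$end, c(53L, 1727L))
  expect_identical(dr$nSites, c(13L, 54L))
  expect_identical(sum(dr$nSites), 67L)
})

test_that("dense clustering matches a single-linkage oracle and ignores input order", {
  set.seed(802)
  for (i in 1:25) {
    sites <- sort(sample(setdiff(-500:900, 0L), sample(10:40, 1)))
    got <- denseRegions(sites, maxGap = 80L, minSites = 3L)
    exp <- denseOracle(sites, maxGap = 80L, minSites = 3L)
    if (is.null(exp)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, exp$start)
      expect_identical(got$end, exp$end)
      expect_identical(got$nSites, exp$nSites)
    }
    shuffled <- denseRegions(sample(sites), maxGap = 80L, minSites = 3L)
    expect_identical(got, shuffled)
  }
  ## all sites equidistant below the gap -> one region containing all
  one <- denseRegions(seq(10L, 200L, by = 10L), maxGap = 200L, minSites = 5L)
  expect_identical(nrow(one), 1L)
  expect_identical(one$nSites, 20L)
})

test_that("bisulfiteConvert follows the per-position rule", {
  ## all sites methylated: only non-CpG Cs convert
  ref <- "ACGACTCCG"
  cg <- c(2L, 8L)
  allM <- bisulfiteConvert(ref, setNames(c(TRUE, TRUE), cg))
  expect_identical(allM, "ACGATTTCG")   # C5, C7 convert; CpG C2, C8 protected
  ## no sites methylated at full conversion: C-free output
  noM <- bisulfiteConvert(ref, setNames(c(FALSE, FALSE), cg))
  expect_false(grepl("C", noM, fixed = TRUE))
  expect_error(bisulfiteConvert(ref, setNames(TRUE, 2L)), "cover")
  ## random states vs an independent per-position oracle
  set.seed(803)
  for (i in 1:20) {
    r <- randSeq(120)
    ch <- strsplit(r, "")[[1]]
    cg <- which(ch == "C" & c(ch[-1], "") == "G")
    st <- setNames(sample(c(TRUE, FALSE), length(cg), replace = TRUE), cg)
    got <- bisulfiteConvert(r, st)
    exp <- ch
    for (p in which(ch == "C")) {
      if (!(p %in% cg && st[as.character(p)])) exp[p] <- "T"
    }
    expect_identical(got, paste(exp, collapse = ""))
  }
})

test_that("called methylation equals the generator truth at full conversion", {
  b <- deskBundle()
  for (sex in c("male", "female")) {
    bs <- simulateBisulfiteClones(b, sex, nClones = 10,
                                  conversionRate = 1.0, seed = 811)
    cm <- callMethylation(bs$clones, b)
    calls <- methCalls(cm)
    ## six regions of 8-16 sites whose union covers the 67 dense sites
    covered <- colnames(calls)[colSums(!is.na(calls)) > 0]
    expect_length(covered, 67L)
    expect_true(all(bs$regions$nSites >= 8 & bs$regions$nSites <= 16))
    expect_identical(nrow(bs$regions), 6L)
    for (i in seq_len(nrow(bs$truth))) {
      expect_identical(
        calls[bs$truth$clone[i], as.character(bs$truth$site[i])],
        as.integer(bs$truth$methylated[i]))
    }
    ## conservation: states partition clones x sites
    expect_identical(sum(calls == 1L, na.rm = TRUE) +
                       sum(calls == 0L, na.rm = TRUE) + sum(is.na(calls)),
                     length(calls))
  }
})

test_that("an all-methylated clone calls an all-methylated row", {
  b <- deskBundle()
  spec <- geneSpec(b)
  tr <- truthTable(b)
  u <- tr$upstreamFlank
  reg <- tr$bsRegions[1, ]
  ga <- ifelse(reg$start > 0, u + reg$start, u + 1 + reg$start)
  gb <- ifelse(reg$end > 0, u + reg$end, u + 1 + reg$end)
  ref <- substr(tr$geneForwardSeq, ga, gb)
  ch <- strsplit(ref, "")[[1]]
  cg <- which(ch == "C" & c(ch[-1], "") == "G")
  clone <- bisulfiteConvert(ref, setNames(rep(TRUE, length(cg)), cg))
  cm <- callMethylation(Biostrings::DNAStringSet(clone), b)
  row <- methCalls(cm)[1, ]
  expect_identical(sum(row, na.rm = TRUE), 13L)     # BS1 carries 13 sites
  expect_true(all(row[!is.na(row)] == 1L))
})

test_that("summaries reproduce the published aggregate arithmetic", {
  ## clone mean of 33.4 methylated sites of 67 -> 49.85 %
  female <- matrix(0L, nrow = 5, ncol = 67)
  counts <- c(34L, 33L, 34L, 33L, 33L)                 # mean 33.4
  for (i in 1:5) female[i, seq_len(counts[i])] <- 1L
  sf <- summarizeMethylation(
    BisulfiteCallMatrix(female, sites = seq_len(67)))
  expect_identical(sf$aggregatePercent, 49.85)
  expect_identical(sf$meanMethylatedSitesPerClone, 33.4)
  ## clone mean of 64.5 of 67 -> 96.27 (printed 96.26; truncation ambiguity)
  male <- matrix(0L, nrow = 2, ncol = 67)
  male[1, 1:64] <- 1L
  male[2, 1:65] <- 1L
  sm <- summarizeMethylation(BisulfiteCallMatrix(male, sites = seq_len(67)))
  expect_lt(abs(sm$aggregatePercent - 96.26), 0.02 + 1e-9)
  expect_identical(sm$meanMethylatedSitesPerClone, 64.5)
  ## all-methylated matrix -> 100.00
  allm <- matrix(1L, 3, 10)
  expect_identical(summarizeMethylation(
    BisulfiteCallMatrix(allm, sites = 1:10))$aggregatePercent, 100)
  expect_error(summarizeMethylation(
    BisulfiteCallMatrix(matrix(NA_integer_, 2, 3), sites = 1:3)),
    "no informative")
})

test_that("random matrices summarise to the direct tally", {
  set.seed(821)
  for (i in 1:40) {
    m <- matrix(sample(c(0L, 1L, NA), 60, replace = TRUE,
                       prob = c(0.4, 0.5, 0.1)),
                nrow = 6)
    if (all(is.na(m))) next
    x <- BisulfiteCallMatrix(m, sites = seq_len(10))
    s <- summarizeMethylation(x)
    nm <- sum(m == 1L, na.rm = TRUE)
    nu <- sum(m == 0L, na.rm = TRUE)
    expect_identical(s$aggregatePercent, roundHalfUp(100 * nm / (nm + nu), 2))
    expect_identical(s$nMethylated + s$nUnmethylated + s$nMissing, 60L)
  }
})

test_that("per-site recovery stays within 3 binomial SEs at deep clone counts", {
  b <- deskBundle()
  bs <- simulateBisulfiteClones(b, "female", nClones = 120,
                                conversionRate = 0.99, seed = 822)
  cm <- callMethylation(bs$clones, b)
  calls <- methCalls(cm)
  covered <- which(colSums(!is.na(calls)) > 0)
  p <- 0.5
  for (j in covered) {
    n <- sum(!is.na(calls[, j]))
    phat <- mean(calls[, j], na.rm = TRUE)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n) + 0.01)
  }
})

test_that("the lollipop grid mirrors the call matrix", {
  m <- matrix(c(1L, 0L, NA, 0L, 1L, 1L), nrow = 2, byrow = TRUE)
  x <- BisulfiteCallMatrix(m, sites = c(-5L, 10L, 40L))
  grid <- lollipopReport(x)
  expect_length(grid, 3L)          # header + 2 clones
  body <- grid[-1]
  expect_identical(unname(body[1]), "*o.")
  expect_identical(unname(body[2]), "o**")
  glyphs <- strsplit(paste(body, collapse = ""), "")[[1]]
  expect_identical(sum(glyphs == "*"), sum(m == 1L, na.rm = TRUE))
  expect_identical(sum(glyphs == "o"), sum(m == 0L, na.rm = TRUE))
  expect_identical(sum(glyphs == "."), sum(is.na(m)))
  ## full synthetic set: one row per clone
  b <- deskBundle()
  bs <- simulateBisulfiteClones(b, "female", nClones = 4, seed = 831)
  cm <- callMethylation(bs$clones, b)
  g2 <- lollipopReport(cm, regions = denseRegions(scanCpg(b)))
  expect_length(g2, nrow(methCalls(cm)) + 1L)
})
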