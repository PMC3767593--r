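## Small shared helpers: rounding, random sequence, coordinate conventions.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (0.5 -> 1), the convention
#' used for every reported percentage and fractional copy number in the
#' package. Base R `round()` rounds halves to even, which would turn e.g.
#' 91.65 into 91.6.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' roundHalfUp(91.65, 1)   # 91.7
#' roundHalfUp(96.265, 2)  # 96.27
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Uniform random DNA as a plain character string. Callers are responsible
## for seeding (all exported simulators take a `seed` argument).
randDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

dnaToChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) as.character(x) else as.character(x)
}

revComp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

## ---- Promoter ("no zero") coordinate convention ----------------------------
##
## Positions around the TSS are reported with +1 = the TSS base, negative
## offsets upstream, and no position 0 (-1 abuts +1). Internally a linearised
## axis is used where linear(k) = k for k > 0 and k + 1 for k < 0, so that
## distances and window indices are contiguous.

#' Linearise a no-zero promoter offset
#'
#' Maps promoter offsets (which skip 0) onto a contiguous integer axis:
#' \code{-1 -> 0}, \code{+1 -> 1}. Inclusive base counts between two offsets
#' are then `diff + 1` on the linear axis.
#'
#' @param k Integer vector of promoter offsets (no 0 allowed).
#' @return Integer vector on the gap-free axis.
#' @export
promoterLinear <- function(k) {
  stopifnot(all(k != 0L))
  ifelse(k > 0L, k, k + 1L)
}

#' Invert [promoterLinear()]
#' @param x Integer vector on the linear axis.
#' @return Promoter offsets (no 0).
#' @export
promoterFromLinear <- function(x) {
  ifelse(x >= 1L, x, x - 1L)
}

## Promoter offset -> index into the gene-forward genomic string G, where the
## TSS base is G[u + 1] and u is the upstream flank length.
promoterToG <- function(k, u) {
  stopifnot(all(k != 0L))
  ifelse(k > 0L, u + k, u + 1L + k)
}

gToPromoter <- function(g, u) {
  ifelse(g > u, g - u, g - u - 1L)
}

## Gene-forward coordinate (1-based index into G) <-> forward-scaffold
## coordinate for a minus-strand gene on a scaffold of total length `len`.
gToScaffold <- function(g, len, strand) {
  if (strand == "-") len - g + 1L else g
}

## First mismatch position between two equal-length character scalars,
## compared bytewise; returns the length of the common prefix.
commonPrefixLen <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

## IUPAC degenerate-base table (DNA).
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## Does `seq` (ACGT) satisfy IUPAC `pattern` of the same length?
iupacMatches <- function(pattern, s) {
  p <- strsplit(toupper(pattern), "")[[1]]
  q <- strsplit(toupper(s), "")[[1]]
  if (length(p) != length(q)) return(FALSE)
  all(mapply(function(pp, qq) qq %in% IUPAC_DNA[[pp]], p, q))
}

assertDna <- function(x, what = "sequence") {
  ch <- unique(strsplit(toupper(dnaToChar(x)), "")[[1]])
  bad <- setdiff(ch, c(names(IUPAC_DNA), "N", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
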