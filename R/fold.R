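## Base-pair-maximising secondary-structure folding of repeat monomers
## (Watson-Crick + GU wobble, classic quadratic-space/cubic-time recursion)
## and hairpin counting on dot-bracket strings.

foldPairOK <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
  (a == "G" && b == "C") || (a == "C" && b == "G") ||
  (a == "G" && b == "T") || (a == "T" && b == "G")
}

#' Fold a monomer by base-pair maximisation
#'
#' Maximises the number of Watson-Crick + GU pairs with a minimum hairpin
#' loop of `minLoop` unpaired bases (DNA input is read as RNA, T = U).
#' Traceback is deterministic: the leftmost base pairs with its leftmost
#' optimal partner whenever pairing is optimal.
#'
#' @param monomer Monomer sequence (DNA alphabet).
#' @param minLoop Minimum loop size (default 3, >= 3).
#' @return list(structure = dot-bracket string, pairs = pair count,
#'   stemLoops = hairpin count). Monomers too short to form any pair return
#'   an all-dot structure.
#' @export
foldMonomer <- function(monomer, minLoop = 3L) {
  if (minLoop < 3L) stop("minLoop must be >= 3")
  s <- strsplit(toupper(dnaToChar(monomer)), "")[[1L]]
  n <- length(s)
  if (n < minLoop + 2L) {
    return(list(structure = strrep(".", n), pairs = 0L, stemLoops = 0L))
  }
  ## M[i,j]: max pairs in s[i..j]
  M <- matrix(0L, n, n)
  for (span in (minLoop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]
      ks <- (i + minLoop + 1L):j
      ks <- ks[vapply(ks, function(k) foldPairOK(s[i], s[k]), logical(1L))]
      for (k in ks) {
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
        cand <- 1L + inner + rest
        if (cand > best) best <- cand
      }
      M[i, j] <- best
    }
  }
  ## deterministic traceback, leftmost pairing preferred
  struct <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j || j - i <= minLoop) next
    if (M[i, j] == 0L) next
    paired <- FALSE
    ks <- (i + minLoop + 1L):j
    for (k in ks) {
      if (!foldPairOK(s[i], s[k])) next
      inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
      rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
      if (1L + inner + rest == M[i, j]) {
        struct[i] <- "("
        struct[k] <- ")"
        if (k - 1L > i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  structure1 <- paste(struct, collapse = "")
  list(structure = structure1, pairs = sum(struct == "("),
       stemLoops = countStemLoops(structure1))
}

#' Count hairpin loops in a dot-bracket structure
#'
#' A hairpin (stem-loop) is a pair enclosing only unpaired bases; the count
#' equals the number of '(' ... ')' innermost facings.
#'
#' @param structure Dot-bracket string (balanced).
#' @return Integer hairpin count.
#' @export
countStemLoops <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (length(depth) > 0L && (any(depth < 0L) || depth[length(depth)] != 0L))
    stop("unbalanced dot-bracket structure")
  length(gregexpr("\\([.]*\\)", structure)[[1L]][
    gregexpr("\\([.]*\\)", structure)[[1L]] > 0L])
}
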