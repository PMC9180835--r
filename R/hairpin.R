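## Hairpin prediction by Nussinov maximum base pairing.
##
## Folding maximizes the number of AU/GC/GU pairs (DNA letters: A:T, G:C,
## G:T) with a minimum hairpin loop of 3 unpaired bases.  Maximum matching,
## not free energy, keeps the predictor dependency-free and deterministic;
## traceback prefers the outermost admissible pair so perfect inverted
## repeats are recovered as clean stems.

PAIRABLE <- local({
  p <- matrix(FALSE, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  p["A", "T"] <- p["T", "A"] <- TRUE
  p["G", "C"] <- p["C", "G"] <- TRUE
  p["G", "T"] <- p["T", "G"] <- TRUE   # G:U wobble
  p
})

## Maximum-pairing DP + traceback; returns the partner index of each base
## (0 for unpaired).
nussinov_partner <- function(seq, minLoop = 3L) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(s)
  if (!all(s %in% DNA_BASES)) stop("sequence must be over ACGT/ACGU")
  enc <- match(s, DNA_BASES)
  if (n < minLoop + 2L) return(integer(n))
  M <- matrix(0L, n, n)
  for (j in seq(minLoop + 2L, n)) {
    for (i in seq(j - minLoop - 1L, 1L)) {
      best <- M[i, j - 1L]
      kc <- i:(j - minLoop - 1L)
      ok <- PAIRABLE[cbind(enc[kc], enc[j])]
      if (any(ok)) {
        kc <- kc[ok]
        left <- integer(length(kc))
        sel <- kc > i
        if (any(sel)) left[sel] <- M[cbind(rep.int(i, sum(sel)), kc[sel] - 1L)]
        inner <- M[cbind(kc + 1L, j - 1L)]
        best <- max(best, max(left + 1L + inner))
      }
      M[i, j] <- best
    }
  }
  partner <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i <= minLoop) next
    target <- M[i, j]
    if (target == 0L) next
    paired <- FALSE
    for (k in i:(j - minLoop - 1L)) {
      if (!PAIRABLE[enc[k], enc[j]]) next
      left <- if (k > i) M[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
      if (left + 1L + inner == target) {
        partner[k] <- j; partner[j] <- k
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  partner
}

partner_to_dotbracket <- function(partner) {
  db <- rep(".", length(partner))
  db[partner > seq_along(partner)] <- "("
  db[partner > 0L & partner < seq_along(partner)] <- ")"
  paste(db, collapse = "")
}

#' Predict whether a genomic window folds into a miRNA-style hairpin
#'
#' Folds `window` by Nussinov maximum base pairing (pairs A:U, G:C and G:U
#' wobble; minimum loop 3 nt) and tests the planted-mature criteria: the
#' mature must lie entirely on one arm (all its paired bases point across
#' the loop in the same direction), at least 60% of mature bases must be
#' paired, the innermost loop must span at least 3 nt, and at least 45% of
#' all window bases must be paired.
#'
#' @param window nucleotide string (ACGT or ACGU), at most 300 nt.
#' @param matureSpan integer vector `c(start, end)` of the mature sequence
#'   within the window, 1-based inclusive.
#' @return A list with elements `passed`, `pairedFractionMature`,
#'   `loopLength`, `arm` (`"5p"`, `"3p"` or `NA`), `structure` (dot-bracket)
#'   and `partner` (integer partner vector).
#' @examples
#' arm <- "AGCTAGCTAGCTAGCTAGCTA"
#' pre <- paste0(arm, "TTTTT", memomiR:::revcomp(arm))
#' predictHairpin(pre, c(1, nchar(arm)))$passed
#' @export
predictHairpin <- function(window, matureSpan) {
  window <- toupper(chartr("U", "T", window))
  n <- nchar(window)
  if (n > 300L) stop("window exceeds 300 nt")
  s <- as.integer(matureSpan[1L]); e <- as.integer(matureSpan[2L])
  if (is.na(s) || is.na(e) || s < 1L || e > n || s > e)
    stop("matureSpan must lie inside the window")
  partner <- nussinov_partner(window)
  mat <- s:e
  pairedMat <- partner[mat] > 0L
  frac <- mean(pairedMat)
  partners <- partner[mat][pairedMat]
  arm <- NA_character_
  armOK <- FALSE
  if (length(partners)) {
    if (all(partners > e)) { arm <- "5p"; armOK <- TRUE }
    else if (all(partners < s)) { arm <- "3p"; armOK <- TRUE }
  }
  pairedIdx <- which(partner > seq_len(n))
  loopLength <- if (length(pairedIdx)) {
    min(partner[pairedIdx] - pairedIdx - 1L)
  } else NA_integer_
  windowFrac <- mean(partner > 0L)
  passed <- isTRUE(armOK && frac >= 0.6 && !is.na(loopLength) &&
                   loopLength >= 3L && windowFrac >= 0.45)
  list(passed = passed,
       pairedFractionMature = frac,
       loopLength = loopLength,
       arm = arm,
       structure = partner_to_dotbracket(partner),
       partner = partner)
}
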