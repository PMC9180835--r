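## Internal helpers shared across modules.

#' Reverse complement of a DNA character string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA string(s) of given lengths
#' @noRd
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  }, character(1))
}

#' Largest single-base fraction of a sequence (low-complexity screen)
#' @noRd
max_base_fraction <- function(seqs) {
  if (length(seqs) == 0L) return(numeric(0))
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), DNA_BASES)
  apply(freq, 1L, max) / nchar(seqs)
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

#' Coerce sequence containers to a named character vector without losing
#' names (base as.character() strips them from plain vectors)
#' @noRd
to_named_character <- function(x) {
  if (is.character(x)) x else as.character(x)
}

#' Mean Phred score per quality string (Phred+33)
#' @noRd
mean_phred <- function(quals) {
  vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Encode integers as fixed-width DNA (used for unique UMIs)
#' @noRd
encode_dna <- function(idx, width) {
  stopifnot(all(idx >= 1L), all(idx <= 4^width))
  m <- matrix("A", nrow = length(idx), ncol = width)
  v <- idx - 1L
  for (j in seq_len(width)) {
    m[, width - j + 1L] <- DNA_BASES[(v %% 4L) + 1L]
    v <- v %/% 4L
  }
  apply(m, 1L, paste, collapse = "")
}

#' Write a named character vector of sequences as FASTA
#' @noRd
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta", width = 80L)
  invisible(path)
}

#' Write reads + constant-width qualities as 4-line FASTQ (Phred+33)
#' @noRd
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qs <- Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame of id/seq/qual characters
#' @noRd
read_fastq_df <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Leftmost position where the first 8 nt of the adapter match with <= 1
#' mismatch, per sequence; NA when absent.  Implemented as the minimum over
#' nine fixed-regex searches (the exact 8-mer and the eight one-position
#' wildcards), which is equivalent to a full <=1-mismatch scan.
#' @noRd
adapter_seed_pos <- function(seqs, adapter) {
  seed <- substr(adapter, 1L, 8L)
  if (nchar(seed) < 8L) stop("adapter must be at least 8 nt")
  chars <- strsplit(seed, "")[[1]]
  patterns <- vapply(0:8, function(k) {
    if (k == 0L) return(seed)
    x <- chars; x[k] <- "."
    paste(x, collapse = "")
  }, character(1))
  best <- rep(NA_integer_, length(seqs))
  for (p in patterns) {
    hit <- regexpr(p, seqs)
    hit <- ifelse(hit == -1L, NA_integer_, as.integer(hit))
    best <- pmin(best, hit, na.rm = TRUE)
  }
  best[is.infinite(best)] <- NA_integer_
  best
}

#' Library naming convention used throughout: GROUP_THh_rR, e.g. DM_6h_r2
#' @noRd
library_name <- function(group, timepoint, rep) {
  sprintf("%s_%dh_r%d", group, timepoint, rep)
}

#' Parse library names back into (group, timepoint, replicate)
#' @noRd
parse_library_names <- function(libs) {
  m <- regmatches(libs, regexec("^(CG|DD|DM)_([0-9]+)h_r([0-9]+)$", libs))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("library names must follow GROUP_TIMEh_rREP, offending: ",
         paste(libs[bad], collapse = ", "))
  }
  data.frame(library = libs,
             group = vapply(m, `[`, character(1), 2L),
             timepoint = as.integer(vapply(m, `[`, character(1), 3L)),
             replicate = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}
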