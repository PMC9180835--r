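## Degradome (PARE) target validation: 5'-end profiles, plant miRNA-target
## duplex scoring, T-plot categories 0-4 and the category/abundance filter.

#' Map degradome tags onto transcripts as 5'-end profiles
#'
#' A tag is assigned to every transcript position where its first 20 nt
#' match exactly on the sense strand; multi-mapping tags count once per
#' locus.  Profiles record, per transcript, the number of tag 5' ends at
#' each position.
#'
#' @param reads degradome reads: a FASTQ path or a character vector of read
#'   sequences (>= 18 nt after trimming; shorter reads are dropped and
#'   counted).
#' @param transcripts named character vector / `DNAStringSet` of transcript
#'   sequences.
#' @param matchLength prefix length required to match exactly (default 20).
#' @return list: `profiles` (named list of integer count vectors, one per
#'   covered transcript, length = transcript length), `stats` (mapped /
#'   unmapped / short tag counts).
#' @export
mapTags <- function(reads, transcripts, matchLength = 20L) {
  if (length(transcripts) == 0L) stop("transcript set is empty")
  txs <- to_named_character(transcripts)
  if (is.null(names(txs))) stop("transcripts must be named")
  seqs <- if (length(reads) == 1L && file.exists(reads)) {
    read_fastq_df(reads)$seq
  } else {
    as.character(reads)
  }
  short <- nchar(seqs) < max(18L, matchLength)
  seqs <- seqs[!short]
  prefix <- substr(seqs, 1L, matchLength)
  tab <- table(prefix)
  uniq <- names(tab)

  profiles <- lapply(txs, function(s) integer(nchar(s)))
  mapped <- logical(length(uniq))
  if (length(uniq)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
    for (txId in names(txs)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(txs[[txId]]))
      starts <- S4Vectors::elementNROWS(m)
      hitIdx <- which(starts > 0L)
      if (!length(hitIdx)) next
      mapped[hitIdx] <- TRUE
      for (i in hitIdx) {
        for (st in methods::slot(m[[i]], "start")) {
          profiles[[txId]][st] <- profiles[[txId]][st] + as.integer(tab[[i]])
        }
      }
    }
  }
  nMapped <- sum(as.integer(tab)[mapped])
  profiles <- profiles[vapply(profiles, function(p) any(p > 0L), logical(1))]
  list(profiles = profiles,
       stats = c(reads = length(seqs) + sum(short),
                 short = sum(short),
                 mapped = nMapped,
                 unmapped = length(seqs) - nMapped))
}

DUPLEX_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Score a plant miRNA-target duplex (ungapped)
#'
#' The site is aligned antiparallel to the miRNA (site position `L + 1 - j`
#' opposite miRNA position `j`).  Penalties per position: Watson-Crick
#' match 0, G:U wobble 0.5, mismatch 1.0; penalties are doubled opposite
#' miRNA positions 2-13 (seed-proximal region).  Lower is better; a perfect
#' complement scores 0.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param site target site sequence, 5' to 3', same length as `mirna`.
#' @return numeric penalty score.
#' @examples
#' scoreDuplex("ACGTACGTACGTACGTACGTA",
#'             memomiR:::revcomp("ACGTACGTACGTACGTACGTA"))  # 0
#' @export
scoreDuplex <- function(mirna, site) {
  mirna <- toupper(chartr("U", "T", mirna))
  site <- toupper(chartr("U", "T", site))
  L <- nchar(mirna)
  if (nchar(site) != L) stop("site length must equal miRNA length")
  mi <- strsplit(mirna, "")[[1]]
  ta <- rev(strsplit(site, "")[[1]])   # ta[j] pairs mirna[j]
  pen <- ifelse(DUPLEX_COMPLEMENT[mi] == ta, 0,
                ifelse((mi == "G" & ta == "T") | (mi == "T" & ta == "G"),
                       0.5, 1))
  w <- rep(1, L)
  w[2:min(13L, L)] <- 2
  sum(pen * w)
}

## Vectorized scores for every window of a transcript (shared by
## findCandidateSites and validateTargets).
score_windows <- function(mirna, transcript, starts) {
  mirna <- toupper(chartr("U", "T", mirna))
  transcript <- toupper(chartr("U", "T", transcript))
  L <- nchar(mirna)
  mi <- strsplit(mirna, "")[[1]]
  tx <- strsplit(transcript, "")[[1]]
  total <- numeric(length(starts))
  for (j in seq_len(L)) {
    tpos <- starts + (L - j)           # transcript base opposite mirna[j]
    tb <- tx[tpos]
    pen <- ifelse(DUPLEX_COMPLEMENT[[mi[j]]] == tb, 0,
                  ifelse((mi[j] == "G" & tb == "T") |
                         (mi[j] == "T" & tb == "G"), 0.5, 1))
    if (j >= 2L && j <= 13L) pen <- pen * 2
    total <- total + pen
  }
  total
}

#' Find candidate target sites of a miRNA on a transcript
#'
#' Slides an ungapped window of miRNA length along the transcript, scoring
#' each window with [scoreDuplex()]; windows scoring at most `scoreMax` are
#' candidate sites.  The predicted cleavage position is the transcript base
#' paired to miRNA nucleotide 10: `siteStart + (L - 10)`.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param transcript transcript sequence.
#' @param scoreMax maximum duplex penalty (default 4.0).
#' @return data.frame: `site_start`, `cleavage_pos`, `score` (possibly
#'   empty).
#' @export
findCandidateSites <- function(mirna, transcript, scoreMax = 4.0) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  if (n < L) stop("transcript shorter than miRNA")
  starts <- seq_len(n - L + 1L)
  sc <- score_windows(mirna, transcript, starts)
  keep <- sc <= scoreMax
  data.frame(site_start = starts[keep],
             cleavage_pos = starts[keep] + (L - 10L),
             score = sc[keep])
}

#' T-plot category of a transcript position
#'
#' With `c` the count at `pos`, `M` the profile maximum and `mu` the mean
#' over covered positions (counts >= 1): category 0 when `c > 1` and `c` is
#' the unique maximum; 1 when `c > 1` equals a maximum attained at least
#' twice; 2 when `1 < c < M` and `c > mu`; 3 when `1 < c <= mu`; 4 when
#' `c == 1`.  Uncovered positions have no category (`NA`).
#'
#' @param profile integer vector of per-position 5'-end counts.
#' @param pos 1-based position.
#' @param coveredMean compute `mu` over covered positions only (default
#'   TRUE) or over all positions.
#' @return integer category (0-4) or `NA` for an uncovered position.
#' @export
categorizeSite <- function(profile, pos, coveredMean = TRUE) {
  if (pos < 1L || pos > length(profile)) stop("position outside profile")
  c0 <- profile[pos]
  if (c0 == 0L) return(NA_integer_)
  if (c0 == 1L) return(4L)
  M <- max(profile)
  mu <- if (coveredMean) mean(profile[profile >= 1L]) else mean(profile)
  if (c0 == M) {
    if (sum(profile == M) == 1L) 0L else 1L
  } else if (c0 > mu) 2L else 3L
}

#' Validate miRNA targets against degradome profiles
#'
#' For every candidate miRNA and every degradome-covered transcript, keeps
#' cleavage sites whose duplex score is at most `scoreMax`, whose T-plot
#' category is at most `categoryMax`, and which carry more than one read.
#' Site discovery is driven from the covered peak positions (every position
#' with count > 1 is tested as a putative cleavage site for every miRNA),
#' which yields exactly the qualifying subset of [findCandidateSites()]
#' windows since category <= 3 already requires more than one read.
#'
#' @param mirnas named character vector: candidate miRNA id -> sequence.
#' @param profiles named list of per-transcript count vectors (from
#'   [mapTags()]).
#' @param transcripts named character vector / `DNAStringSet`.
#' @param scoreMax maximum duplex penalty (default 4.0).
#' @param categoryMax maximum T-plot category retained (default 2,
#'   i.e. categories below 3).
#' @param library optional library label recorded on the hits.
#' @param coveredMean see [categorizeSite()].
#' @return data.frame of target hits: `mirna_id`, `transcript_id`,
#'   `cleavage_pos`, `site_start`, `score`, `category`, `reads_at_site`,
#'   `library`.
#' @export
validateTargets <- function(mirnas, profiles, transcripts, scoreMax = 4.0,
                            categoryMax = 2L, library = NA_character_,
                            coveredMean = TRUE) {
  txs <- to_named_character(transcripts)
  hits <- list()
  for (txId in names(profiles)) {
    prof <- profiles[[txId]]
    tx <- txs[[txId]]
    peaks <- which(prof > 1L)
    if (!length(peaks)) next
    cats <- vapply(peaks, function(p) categorizeSite(prof, p, coveredMean),
                   integer(1))
    ok <- cats <= categoryMax
    peaks <- peaks[ok]; cats <- cats[ok]
    if (!length(peaks)) next
    for (mi in names(mirnas)) {
      L <- nchar(mirnas[[mi]])
      starts <- peaks - (L - 10L)
      valid <- starts >= 1L & starts + L - 1L <= nchar(tx)
      if (!any(valid)) next
      sc <- score_windows(mirnas[[mi]], tx, starts[valid])
      keep <- sc <= scoreMax
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- data.frame(
        mirna_id = mi, transcript_id = txId,
        cleavage_pos = peaks[valid][keep],
        site_start = starts[valid][keep],
        score = sc[keep], category = cats[valid][keep],
        reads_at_site = prof[peaks[valid][keep]],
        library = library, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      cleavage_pos = integer(0), site_start = integer(0),
                      score = numeric(0), category = integer(0),
                      reads_at_site = integer(0), library = character(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
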