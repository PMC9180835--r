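## Raw small RNA read preprocessing: adapter trimming with UMI extraction,
## PCR-duplicate removal, tag collapsing and contaminant filtering.

#' Trim one read and extract its UMI
#'
#' Locates the leftmost occurrence of the 3' adapter (tolerating one
#' mismatch in its first 8 nt); the insert is the prefix before the adapter
#' and the UMI the `umiLen` bases following it.  Reads are rejected when
#' mean Phred quality is below `minQuality`, the full read length falls
#' outside the raw `lengthGate`, no adapter is found, the insert is empty
#' (adapter at position 1), or too few bases remain for a full UMI.
#'
#' @param seq read sequence (character).
#' @param qual Phred+33 quality string of the same length.
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param umiLen UMI length in nt (default 12).
#' @param minQuality mean Phred quality threshold (default 20).
#' @param lengthGate allowed raw read length range (default 30-80 nt).
#' @return A list: either `list(insert=, umi=)` or
#'   `list(rejected=TRUE, reason=)` with reason one of `"length_gate"`,
#'   `"low_quality"`, `"no_adapter"`, `"empty_insert"`, `"umi_truncated"`.
#' @examples
#' trimAndExtract(paste0(strrep("ACGT", 5), "TGGAATTCTCGG", strrep("A", 12)),
#'                strrep("I", 44), "TGGAATTCTCGG")
#' @export
trimAndExtract <- function(seq, qual, adapter, umiLen = 12L,
                           minQuality = 20, lengthGate = c(30L, 80L)) {
  res <- trim_reads(seq, qual, adapter, umiLen, minQuality, lengthGate)
  if (res$status == "ok") list(insert = res$insert, umi = res$umi)
  else list(rejected = TRUE, reason = res$status)
}

## Vectorized trimming core shared by trimAndExtract and preprocessLibrary.
trim_reads <- function(seqs, quals, adapter, umiLen = 12L,
                       minQuality = 20, lengthGate = c(30L, 80L)) {
  stopifnot(length(seqs) == length(quals), nchar(adapter) >= 8L)
  n <- length(seqs)
  status <- rep("ok", n)
  len <- nchar(seqs)
  status[len < lengthGate[1L] | len > lengthGate[2L]] <- "length_gate"
  meanQ <- mean_phred(quals)
  status[status == "ok" & meanQ < minQuality] <- "low_quality"
  pos <- adapter_seed_pos(seqs, adapter)
  status[status == "ok" & is.na(pos)] <- "no_adapter"
  status[status == "ok" & !is.na(pos) & pos == 1L] <- "empty_insert"
  insert <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  ok <- status == "ok"
  if (any(ok)) {
    insert[ok] <- substr(seqs[ok], 1L, pos[ok] - 1L)
    uStart <- pos[ok] + nchar(adapter)
    umi[ok] <- substr(seqs[ok], uStart, uStart + umiLen - 1L)
    short <- nchar(umi) < umiLen & ok
    status[short] <- "umi_truncated"
    insert[short] <- NA_character_
    umi[short] <- NA_character_
  }
  list(status = status, insert = insert, umi = umi)
}

#' Collapse PCR duplicates by (insert, UMI)
#'
#' Molecules identical in both insert and UMI collapse to one; the PCR
#' duplication ratio is `1 - unique/total` (0 for empty input).
#'
#' @param molecules data.frame with columns `insert` and `umi`.
#' @return `list(unique = <deduplicated data.frame>, duplicationRatio = )`.
#' @examples
#' m <- data.frame(insert = c("ACGT", "ACGT", "ACGT", "TTTT"),
#'                 umi = c("AA", "AA", "AC", "GG"))
#' dedupUmi(m)$duplicationRatio   # 0.25
#' @export
dedupUmi <- function(molecules) {
  stopifnot(all(c("insert", "umi") %in% names(molecules)))
  total <- nrow(molecules)
  if (total == 0L) {
    return(list(unique = molecules, duplicationRatio = 0))
  }
  uniq <- molecules[!duplicated(paste(molecules$insert, molecules$umi,
                                      sep = "\r")), , drop = FALSE]
  list(unique = uniq, duplicationRatio = 1 - nrow(uniq) / total)
}

#' Collapse deduplicated molecules into unique tags with per-library counts
#'
#' @param moleculesPerLibrary named list (library -> data.frame with column
#'   `insert`) of UMI-deduplicated molecules.
#' @return data.frame with column `seq` and one integer count column per
#'   library (zero where a tag is absent); count sums equal the molecule
#'   counts.
#' @export
collapseTags <- function(moleculesPerLibrary) {
  stopifnot(is.list(moleculesPerLibrary), length(moleculesPerLibrary) > 0L)
  libs <- names(moleculesPerLibrary)
  dt <- data.table::rbindlist(lapply(libs, function(lib) {
    data.table::data.table(seq = moleculesPerLibrary[[lib]]$insert,
                           library = lib)
  }))
  counts <- dt[, .N, by = c("seq", "library")]
  wide <- data.table::dcast(counts, seq ~ library, value.var = "N", fill = 0L)
  out <- as.data.frame(wide)
  missing <- setdiff(libs, names(out))
  for (m in missing) out[[m]] <- 0L
  out[, c("seq", libs)]
}

#' Remove contaminant, low-complexity and off-length tags
#'
#' A tag is removed when it is an exact full-length substring of any
#' contaminant record (sense strand; class recorded from the record name
#' prefix), an exact substring of an mRNA record (class `"mRNA"`), or
#' low-complexity (one base exceeding `maxBaseFraction` of its length).
#' Tags passing these filters are additionally restricted to
#' `tagLengths` nt for the miRNA tag set; off-length clean tags are
#' reported separately, not discarded silently.
#'
#' @param tags data.frame from [collapseTags()] (`seq` + count columns).
#' @param contaminants named character vector / `DNAStringSet` of decoy
#'   records; class is the record name up to the last `_` (e.g. `rRNA_1`).
#' @param mrna optional named character vector / `DNAStringSet` of mRNA
#'   records.
#' @param tagLengths length window of the retained miRNA tag set.
#' @param maxBaseFraction low-complexity threshold (default 0.8).
#' @return `list(tags = , removed = , offLength = , stats = )`: the clean
#'   in-window tag table, removed tags with their class, clean tags outside
#'   the window, and removal counts by class.
#' @export
filterContaminants <- function(tags, contaminants, mrna = NULL,
                               tagLengths = c(18L, 25L),
                               maxBaseFraction = 0.8) {
  if (length(contaminants) == 0L)
    stop("contaminant reference set is empty")
  cont <- to_named_character(contaminants)
  if (is.null(names(cont)) || any(!nzchar(names(cont))))
    stop("contaminant records must be named")
  classes <- sub("_[^_]*$", "", names(cont))
  if (!is.null(mrna) && length(mrna)) {
    m <- to_named_character(mrna)
    cont <- c(cont, m)
    classes <- c(classes, rep("mRNA", length(m)))
  }
  byClass <- split(cont, classes)
  concat <- vapply(byClass, paste, character(1), collapse = "#")

  seqs <- tags$seq
  tagClass <- rep(NA_character_, length(seqs))
  lowc <- max_base_fraction(seqs) > maxBaseFraction
  tagClass[lowc] <- "low_complexity"
  todo <- which(is.na(tagClass))
  for (cls in names(concat)) {
    if (!length(todo)) break
    hit <- vapply(seqs[todo], grepl, logical(1), x = concat[[cls]],
                  fixed = TRUE, USE.NAMES = FALSE)
    tagClass[todo[hit]] <- cls
    todo <- todo[!hit]
  }
  removed <- !is.na(tagClass)
  len <- nchar(seqs)
  inWindow <- !removed & len >= tagLengths[1L] & len <= tagLengths[2L]
  offLen <- !removed & !inWindow

  stats <- c(table(tagClass[removed]))
  stats <- c(stats, off_length = sum(offLen))
  list(tags = tags[inWindow, , drop = FALSE],
       removed = data.frame(seq = seqs[removed], class = tagClass[removed],
                            stringsAsFactors = FALSE),
       offLength = tags[offLen, , drop = FALSE],
       stats = stats)
}

#' Preprocess one small RNA FASTQ library
#'
#' Runs trimming/UMI extraction and duplicate collapsing on one library and
#' returns its unique molecules plus per-stage statistics.
#'
#' @param fastq path to a FASTQ file.
#' @inheritParams trimAndExtract
#' @return `list(molecules = data.frame(insert, umi), stats = named numeric)`
#'   with stats `raw_reads`, per-reason rejection counts, `molecules`,
#'   `unique_molecules` and `duplication_ratio`.
#' @export
preprocessLibrary <- function(fastq, adapter, umiLen = 12L,
                              minQuality = 20, lengthGate = c(30L, 80L)) {
  reads <- read_fastq_df(fastq)
  tr <- trim_reads(reads$seq, reads$qual, adapter, umiLen, minQuality,
                   lengthGate)
  ok <- tr$status == "ok"
  mol <- data.frame(insert = tr$insert[ok], umi = tr$umi[ok],
                    stringsAsFactors = FALSE)
  dd <- dedupUmi(mol)
  reasons <- c("length_gate", "low_quality", "no_adapter", "empty_insert",
               "umi_truncated")
  rej <- vapply(reasons, function(r) sum(tr$status == r), numeric(1))
  stats <- c(raw_reads = nrow(reads), rej,
             molecules = nrow(mol),
             unique_molecules = nrow(dd$unique),
             duplication_ratio = dd$duplicationRatio)
  list(molecules = dd$unique, stats = stats)
}

#' Preprocess a set of libraries into a tag table
#'
#' @param fastqs named character vector (library name -> FASTQ path).
#' @inheritParams trimAndExtract
#' @return `list(tags = data.frame(seq, <library counts>), stats =
#'   data.frame, one row per library)`.
#' @export
preprocessLibraries <- function(fastqs, adapter, umiLen = 12L,
                                minQuality = 20, lengthGate = c(30L, 80L)) {
  stopifnot(!is.null(names(fastqs)), all(nzchar(names(fastqs))))
  per <- lapply(fastqs, preprocessLibrary, adapter = adapter,
                umiLen = umiLen, minQuality = minQuality,
                lengthGate = lengthGate)
  tags <- collapseTags(lapply(per, `[[`, "molecules"))
  stats <- as.data.frame(do.call(rbind, lapply(per, `[[`, "stats")))
  stats <- cbind(library = names(fastqs), stats)
  rownames(stats) <- NULL
  list(tags = tags, stats = stats)
}
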