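## miRNA catalog: tag classification into known (gp1a), precursor-variant
## (gp1b), conserved (gp2a/gp2b/gp3) and novel (gp4) groups, ACGT101-style
## variant naming, and base-composition summaries.

MIRNA_GROUPS <- c("gp1a", "gp1b", "gp2a", "gp2b", "gp3", "gp4")

## End-free alignment of a tag against a reference mature, tolerating <= 2
## substitutions and <= 2 nt trimming/extension at either end.  Returns NULL
## when no admissible alignment exists.
align_variant <- function(tag, ref) {
  lt <- nchar(tag); lr <- nchar(ref)
  if (abs(lt - lr) > 4L) return(NULL)
  tagC <- strsplit(tag, "")[[1]]
  refC <- strsplit(ref, "")[[1]]
  best <- NULL
  for (s in -2:2) {            # shift: tag[i] aligns ref[i + s]
    d3 <- (lt + s) - lr        # positive: 3' extension, negative: 3' trim
    if (abs(d3) > 2L) next
    i <- seq_len(lt)
    ov <- i[i + s >= 1L & i + s <= lr]
    if (length(ov) < max(lt, lr) - 4L) next
    mism <- ov[tagC[ov] != refC[ov + s]]
    if (length(mism) > 2L) next
    cand <- list(shift = s, d3 = d3, subs = mism,
                 refBase = refC[mism + s], tagBase = tagC[mism],
                 cost = length(mism) + abs(s) + abs(d3))
    if (is.null(best) || cand$cost < best$cost ||
        (cand$cost == best$cost && length(cand$subs) < length(best$subs))) {
      best <- cand
    }
  }
  best
}

#' Name a tag relative to a reference mature miRNA
#'
#' Builds the variant suffix: `L-k`/`L+k` for k-nt trimming/extension at the
#' 5' end, `R-k`/`R+k` at the 3' end, and `nss<pos><ref><tag>` for n
#' substitutions (positions 1-based on the tag, reference base then tag
#' base).  Identical sequences return the reference name unchanged.
#'
#' @param tag tag sequence.
#' @param ref reference mature sequence.
#' @param refName reference miRNA name.
#' @return The suffixed id, or `NA_character_` when the tag cannot be
#'   aligned within 2 substitutions and 2-nt end shifts.
#' @examples
#' nameVariant("GCTAGCTAGCTAGCTAGCT", "TAGCTAGCTAGCTAGCTAGCT", "tae-miR531")
#' # "tae-miR531_L-2"
#' @export
nameVariant <- function(tag, ref, refName) {
  al <- align_variant(toupper(tag), toupper(ref))
  if (is.null(al)) return(NA_character_)
  parts <- character(0)
  ends <- ""
  if (al$shift > 0L) ends <- paste0(ends, "L-", al$shift)
  if (al$shift < 0L) ends <- paste0(ends, "L+", -al$shift)
  if (al$d3 > 0L) ends <- paste0(ends, "R+", al$d3)
  if (al$d3 < 0L) ends <- paste0(ends, "R-", -al$d3)
  if (nzchar(ends)) parts <- c(parts, ends)
  if (length(al$subs)) {
    parts <- c(parts, paste0(length(al$subs), "ss",
                             paste0(al$subs, al$refBase, al$tagBase,
                                    collapse = "")))
  }
  if (length(parts)) paste(c(refName, parts), collapse = "_") else refName
}

## Best admissible match of a tag in a set of reference matures; exact
## matches win, then the lowest-cost variant alignment.
best_mature_match <- function(tag, matures) {
  hit <- match(tag, matures)
  if (!is.na(hit)) {
    return(list(name = names(matures)[hit], seq = matures[[hit]], cost = 0L))
  }
  lt <- nchar(tag)
  cand <- which(abs(nchar(matures) - lt) <= 4L)
  best <- NULL
  for (i in cand) {
    al <- align_variant(tag, matures[[i]])
    if (!is.null(al) && (is.null(best) || al$cost < best$al$cost)) {
      best <- list(i = i, al = al)
      if (al$cost == 0L) break
    }
  }
  if (is.null(best)) return(NULL)
  list(name = names(matures)[best$i], seq = matures[[best$i]],
       cost = best$al$cost)
}

## Derive the conventional precursor name of a mature ("tae-miR123-5p" ->
## "tae-MIR123").
precursor_name_of <- function(matureName) {
  sub("miR", "MIR", sub("-[53]p$", "", matureName), fixed = TRUE)
}

#' Classify a unique tag into a miRNA group
#'
#' Decision cascade: (gp1a) the tag matches a wheat mature (<= 2
#' substitutions and/or <= 2-nt end trimming/extension) and maps within that
#' mature's precursor; (gp1b) the tag maps within a wheat precursor without
#' matching an annotated mature; (gp2a) it matches a non-wheat mature and
#' maps to a genome window passing [predictHairpin()]; (gp2b) as gp2a but
#' the hairpin fails; (gp3) non-wheat mature match without genome mapping;
#' (gp4) no mature match anywhere, genome mapping plus a passing hairpin;
#' otherwise unassigned.
#'
#' @param tag tag sequence (18-25 nt).
#' @param wheatMature,wheatPrecursor named character vectors (or
#'   `DNAStringSet`s) of wheat mature and precursor references; precursor
#'   names follow the `tae-MIRn` convention derived from mature names.
#' @param otherMature optional non-wheat mature reference set.
#' @param genome optional named set of genome windows for hairpin
#'   evaluation.
#' @return A list with `group` (one of gp1a..gp4 or `"unassigned"`), `id`
#'   (suffixed name; `NA` when unassigned), `precursorId`, `arm` and, for
#'   genome-derived groups, the `hairpin` result.
#' @export
classifyTag <- function(tag, wheatMature, wheatPrecursor,
                        otherMature = NULL, genome = NULL) {
  tag <- toupper(chartr("U", "T", tag))
  wheatMature <- to_named_character(wheatMature)
  wheatPrecursor <- to_named_character(wheatPrecursor)
  unassigned <- list(group = "unassigned", id = NA_character_,
                     precursorId = NA_character_, arm = NA_character_)

  wm <- best_mature_match(tag, wheatMature)
  if (!is.null(wm)) {
    pid <- precursor_name_of(wm$name)
    if (pid %in% names(wheatPrecursor) &&
        Biostrings::countPattern(tag,
                                 Biostrings::DNAString(wheatPrecursor[[pid]]),
                                 max.mismatch = 2) > 0L) {
      return(list(group = "gp1a",
                  id = nameVariant(tag, wm$seq, wm$name),
                  precursorId = pid,
                  arm = sub("^.*-([53]p)$", "\\1", wm$name)))
    }
  }
  ## gp1b: inside a wheat precursor, but not an annotated mature
  if (length(wheatPrecursor)) {
    hits <- which(grepl(tag, wheatPrecursor, fixed = TRUE))
    if (length(hits)) {
      pid <- names(wheatPrecursor)[hits[1L]]
      pos <- as.integer(regexpr(tag, wheatPrecursor[[pid]], fixed = TRUE))
      arm <- if (pos <= nchar(wheatPrecursor[[pid]]) / 2) "5p" else "3p"
      return(list(group = "gp1b",
                  id = paste0(pid, "-p", substr(arm, 1L, 1L)),
                  precursorId = pid, arm = arm))
    }
  }
  genome_hit <- function() {
    if (is.null(genome) || !length(genome)) return(NULL)
    g <- to_named_character(genome)
    hits <- which(grepl(tag, g, fixed = TRUE))
    if (!length(hits)) return(NULL)
    w <- hits[1L]
    pos <- as.integer(regexpr(tag, g[[w]], fixed = TRUE))
    list(name = names(g)[w], seq = g[[w]],
         span = c(pos, pos + nchar(tag) - 1L))
  }
  om <- if (!is.null(otherMature) && length(otherMature)) {
    best_mature_match(tag, to_named_character(otherMature))
  } else NULL
  if (!is.null(om)) {
    gh <- genome_hit()
    if (is.null(gh)) {
      return(list(group = "gp3", id = nameVariant(tag, om$seq, om$name),
                  precursorId = NA_character_, arm = NA_character_))
    }
    hp <- predictHairpin(gh$seq, gh$span)
    grp <- if (hp$passed) "gp2a" else "gp2b"
    return(list(group = grp, id = nameVariant(tag, om$seq, om$name),
                precursorId = gh$name, arm = hp$arm, hairpin = hp))
  }
  gh <- genome_hit()
  if (!is.null(gh)) {
    hp <- predictHairpin(gh$seq, gh$span)
    if (hp$passed) {
      return(list(group = "gp4", id = NA_character_,  # named at catalog level
                  precursorId = gh$name, arm = hp$arm, hairpin = hp))
    }
  }
  unassigned
}

#' Build the miRNA expression catalog from a clean tag table
#'
#' Classifies every tag (see [classifyTag()]) and assembles the classified
#' ones into a `SummarizedExperiment`: assay `counts` holds per-library tag
#' counts, `rowData` the sequence/group/precursor annotation, `colData` the
#' parsed (group, timepoint, replicate) design when library names follow the
#' `GROUP_Th_rR` convention.  Novel (gp4) entries are named
#' `PC-<arm>-<rank>` by the lexicographic rank of their sequence; duplicate
#' ids get a numeric suffix.
#'
#' @param tags data.frame from [filterContaminants()] (`seq` + one count
#'   column per library).
#' @inheritParams classifyTag
#' @return A list: `se` (the `SummarizedExperiment`) and `unassigned`
#'   (data.frame of unclassifiable tags).
#' @export
buildCatalog <- function(tags, wheatMature, wheatPrecursor,
                         otherMature = NULL, genome = NULL) {
  wheatMature <- to_named_character(wheatMature)
  wheatPrecursor <- to_named_character(wheatPrecursor)
  seqs <- tags$seq
  res <- lapply(seqs, classifyTag, wheatMature = wheatMature,
                wheatPrecursor = wheatPrecursor, otherMature = otherMature,
                genome = genome)
  group <- vapply(res, `[[`, character(1), "group")
  id <- vapply(res, `[[`, character(1), "id")
  precursorId <- vapply(res, `[[`, character(1), "precursorId")
  arm <- vapply(res, `[[`, character(1), "arm")
  isNovel <- group == "gp4"
  id[isNovel] <- novel_ids(seqs[isNovel], arm[isNovel])
  keep <- group != "unassigned"
  id[keep] <- make.unique(id[keep], sep = "_")

  libs <- setdiff(names(tags), "seq")
  counts <- as.matrix(tags[keep, libs, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- id[keep]
  colData <- tryCatch(parse_library_names(libs),
                      error = function(e) data.frame(library = libs))
  rownames(colData) <- libs
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(seq = seqs[keep], group = group[keep],
                                   precursorId = precursorId[keep],
                                   arm = arm[keep]),
    colData = S4Vectors::DataFrame(colData))
  list(se = se,
       unassigned = tags[!keep, , drop = FALSE])
}

#' Per-position base composition of tags, grouped by length
#'
#' @param seqs tag sequences.
#' @param weights per-tag weights (e.g. total counts); default 1.
#' @param lengths tag lengths to report (default 18-25).
#' @return data.frame with columns `length`, `position`, `A`, `C`, `G`, `U`
#'   (count-weighted frequencies summing to 1 per row); lengths with no tags
#'   are omitted.
#' @export
baseComposition <- function(seqs, weights = NULL, lengths = 18:25) {
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs))
  seqs <- toupper(chartr("U", "T", seqs))
  out <- list()
  for (L in lengths) {
    sel <- nchar(seqs) == L
    if (!any(sel)) next
    mat <- do.call(rbind, strsplit(seqs[sel], ""))
    w <- weights[sel]
    for (p in seq_len(L)) {
      tot <- vapply(DNA_BASES, function(b) sum(w[mat[, p] == b]), numeric(1))
      freq <- tot / sum(tot)
      out[[length(out) + 1L]] <- data.frame(
        length = L, position = p,
        A = freq[["A"]], C = freq[["C"]], G = freq[["G"]], U = freq[["T"]])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
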