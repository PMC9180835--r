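## Synthetic scenario generator: references, small RNA libraries, degradome
## libraries and ground truth for a planted drought-memory study design.

CONTAMINANT_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")

## Deterministic novel-miRNA naming shared by the generator and the catalog:
## rank of the tag sequence among all novel tags, prefixed with the arm.
novel_ids <- function(seqs, arms) {
  if (length(seqs) == 0L) return(character(0))
  paste0("PC-", arms, "-", match(seqs, sort(seqs)))
}

build_hairpin <- function(mature, loopSeq, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  if (arm == "5p") {
    list(seq = paste0(mature, loopSeq, revcomp(mature)), span = c(1L, L))
  } else {
    list(seq = paste0(revcomp(mature), loopSeq, mature),
         span = c(L + nchar(loopSeq) + 1L, 2L * L + nchar(loopSeq)))
  }
}

## Hairpin window guaranteed to pass predictHairpin (loop resampled if an
## adversarial loop sequence spoils the fold; construction almost always
## passes first try).
make_hairpin_window <- function(mature, loopLength, arm) {
  for (i in 1:25) {
    hp <- build_hairpin(mature, random_dna(loopLength), arm)
    if (predictHairpin(hp$seq, hp$span)$passed) return(hp)
  }
  stop("could not build a folding hairpin for mature ", mature)
}

#' Build the synthetic reference bundle for a scenario
#'
#' Generates every reference a scenario needs: wheat-style mature and
#' precursor FASTA entries, a non-wheat ("other species") mature set, genome
#' windows (hairpin precursors for novel/conserved miRNAs plus decoys),
#' contaminant decoys (rRNA/tRNA/snRNA/snoRNA/repeat), the transcriptome
#' with planted cleavage sites, and a GO/KEGG annotation map.  All planted
#' tag sequences are screened so that the read layout parses unambiguously
#' (no spurious adapter-seed hits), no tag is low-complexity, and no tag is
#' a substring of a contaminant or transcript record.
#'
#' @param config a [ScenarioConfig-class].
#' @return A `MirnaReferenceBundle`: a list with elements `mature`,
#'   `precursor`, `otherMature`, `genome`, `contaminants`, `transcripts`
#'   (named sequence vectors), `contaminantTags`, `mirnas` (planted miRNA
#'   table with expected catalog ids), `pairs` (planted cleavage sites),
#'   `annotation` (gene/term map) and `windows` (mature spans of genome
#'   windows).
#' @examples
#' ref <- makeReference(scenarioConfig(seed = 3L))
#' length(ref$mature)
#' @export
makeReference <- function(config) {
  validObject(config)
  set.seed(config@seed)
  plan <- plan_scenario(config)
  n <- nrow(plan)
  adapter <- config@adapter
  lenR <- config@matureLengths

  seen <- new.env(hash = TRUE, parent = emptyenv())
  tag_ok <- function(s) {
    if (exists(s, envir = seen, inherits = FALSE)) return(FALSE)
    if (max_base_fraction(s) > 0.7) return(FALSE)
    pos <- adapter_seed_pos(paste0(s, adapter), adapter)
    !is.na(pos) && pos == nchar(s) + 1L
  }
  claim <- function(s) assign(s, TRUE, envir = seen)
  new_tag <- function(len = NULL) {
    repeat {
      L <- if (is.null(len)) sample(seq(lenR[1L], lenR[2L]), 1L) else len
      s <- random_dna(L)
      if (tag_ok(s)) { claim(s); return(s) }
    }
  }

  mature <- character(0)     # wheat mature reference (miRBase-style)
  precursor <- character(0)  # wheat precursors
  otherMature <- character(0)
  genome <- character(0)
  windowSpans <- list()

  plan$seq <- NA_character_
  plan$mature_ref <- NA_character_
  plan$precursor_id <- NA_character_
  plan$arm <- NA_character_
  plan$catalog_id <- NA_character_
  plan$expected_group <- plan$group

  wheatIdx <- 0L
  osaIdx <- 0L
  next_wheat <- function() { wheatIdx <<- wheatIdx + 1L; wheatIdx }

  ## wheat-known entries (and unexpressed references for gp1b parents)
  gp1aRows <- which(plan$group == "gp1a")
  for (i in gp1aRows) {
    w <- next_wheat()
    tag <- new_tag()
    mname <- sprintf("tae-miR%04d-5p", w)
    pname <- sprintf("tae-MIR%04d", w)
    mature[mname] <- tag
    precursor[pname] <- build_hairpin(tag, random_dna(config@loopLength), "5p")$seq
    plan$seq[i] <- tag
    plan$mature_ref[i] <- mname
    plan$precursor_id[i] <- pname
    plan$arm[i] <- "5p"
    plan$catalog_id[i] <- mname
  }

  ## gp1b: the expressed tag is the unannotated 3p arm of a wheat precursor
  for (i in which(plan$group == "gp1b")) {
    w <- next_wheat()
    tag <- new_tag()
    refM <- revcomp(tag)            # annotated (unexpressed) 5p mature
    mname <- sprintf("tae-miR%04d-5p", w)
    pname <- sprintf("tae-MIR%04d", w)
    mature[mname] <- refM
    precursor[pname] <- build_hairpin(refM, random_dna(config@loopLength), "5p")$seq
    plan$seq[i] <- tag
    plan$precursor_id[i] <- pname
    plan$arm[i] <- "3p"
    plan$catalog_id[i] <- sprintf("tae-MIR%04d-p3", w)
  }

  ## variants: expressed isoforms of an already-planted wheat mature
  variantRows <- which(plan$group == "variant")
  vparents <- sample(gp1aRows, length(variantRows))
  for (k in seq_along(variantRows)) {
    i <- variantRows[k]
    parent <- vparents[k]
    pseq <- plan$seq[parent]
    tag <- NULL
    if (k %% 2L == 1L) {
      cand <- substr(pseq, 3L, nchar(pseq))           # 5' trim by 2 -> _L-2
      if (tag_ok(cand)) tag <- cand
    }
    if (is.null(tag)) {                                # one substitution
      for (pos in rev(seq_len(nchar(pseq)))) {
        old <- substr(pseq, pos, pos)
        for (nb in setdiff(DNA_BASES, old)) {
          cand <- pseq
          substr(cand, pos, pos) <- nb
          if (tag_ok(cand)) { tag <- cand; break }
        }
        if (!is.null(tag)) break
      }
    }
    claim(tag)
    plan$seq[i] <- tag
    plan$mature_ref[i] <- plan$mature_ref[parent]
    plan$precursor_id[i] <- plan$precursor_id[parent]
    plan$arm[i] <- "5p"
    plan$catalog_id[i] <- nameVariant(tag, pseq, plan$mature_ref[parent])
    plan$expected_group[i] <- "gp1a"
  }

  ## conserved entries matched to a non-wheat mature
  for (i in which(plan$group %in% c("gp2a", "gp2b", "gp3"))) {
    osaIdx <- osaIdx + 1L
    tag <- new_tag()
    oname <- sprintf("osa-miR%03d", 500L + osaIdx)
    otherMature[oname] <- tag
    plan$seq[i] <- tag
    plan$mature_ref[i] <- oname
    plan$catalog_id[i] <- oname
    if (plan$group[i] == "gp2a") {
      hp <- make_hairpin_window(tag, config@loopLength, "5p")
      gname <- sprintf("win_gp2a_%03d", osaIdx)
      genome[gname] <- hp$seq
      windowSpans[[gname]] <- hp$span
      plan$arm[i] <- "5p"
    } else if (plan$group[i] == "gp2b") {
      gname <- sprintf("win_gp2b_%03d", osaIdx)
      genome[gname] <- paste0(random_dna(2L), tag, random_dna(2L))
      windowSpans[[gname]] <- c(3L, nchar(tag) + 2L)
    }
  }

  ## novel entries: genome-only hairpins (gp4)
  gp4Rows <- which(plan$group == "gp4")
  gp4Arms <- rep(c("5p", "3p"), length.out = length(gp4Rows))
  for (k in seq_along(gp4Rows)) {
    i <- gp4Rows[k]
    tag <- new_tag()
    hp <- make_hairpin_window(tag, config@loopLength, gp4Arms[k])
    gname <- sprintf("win_novel_%04d", k)
    genome[gname] <- hp$seq
    windowSpans[[gname]] <- hp$span
    plan$seq[i] <- tag
    plan$arm[i] <- gp4Arms[k]
  }
  plan$catalog_id[gp4Rows] <- novel_ids(plan$seq[gp4Rows], plan$arm[gp4Rows])

  ## unexpressed decoy references and random genome windows
  for (d in 1:20) {
    w <- next_wheat()
    m <- new_tag()
    mature[sprintf("tae-miR%04d-5p", w)] <- m
    precursor[sprintf("tae-MIR%04d", w)] <-
      build_hairpin(m, random_dna(config@loopLength), "5p")$seq
  }
  for (d in 1:8) {
    osaIdx <- osaIdx + 1L
    otherMature[sprintf("osa-miR%03d", 500L + osaIdx)] <- new_tag()
  }
  for (d in 1:10) genome[sprintf("win_decoy_%02d", d)] <- random_dna(60L)

  ## contaminant decoy records; regenerated if a planted tag lands inside
  contaminants <- character(0)
  allTags <- plan$seq
  for (cls in CONTAMINANT_CLASSES) {
    for (r in 1:3) {
      repeat {
        rec <- random_dna(sample(150:250, 1L))
        if (!any(vapply(allTags, grepl, logical(1), x = rec, fixed = TRUE))) break
      }
      contaminants[sprintf("%s_%d", cls, r)] <- rec
    }
  }

  ## contaminant-derived inserts used to spike the libraries
  contamTags <- character(0)
  recNames <- names(contaminants)
  while (length(contamTags) < 30L) {
    rn <- sample(recNames, 1L)
    rec <- contaminants[[rn]]
    L <- sample(18:25, 1L)
    st <- sample(nchar(rec) - L + 1L, 1L)
    s <- substr(rec, st, st + L - 1L)
    if (tag_ok(s)) { claim(s); contamTags[s] <- sub("_\\d+$", "", rn) }
  }

  ## transcriptome with planted cleavage sites
  valRows <- which(plan$validated)
  valIds <- plan$id[valRows]
  kBase <- config@nValidatedTargets %/% max(config@nValidated, 1L)
  kExtra <- config@nValidatedTargets %% max(config@nValidated, 1L)
  perMiRNA <- rep(kBase, length(valIds)) +
    c(rep(1L, kExtra), rep(0L, length(valIds) - kExtra))
  transcripts <- character(0)
  txSite <- list()   # txId -> list(mirnaSeq or NA, site_start)
  pairs <- list()
  txIdx <- 0L
  build_tx <- function(mirnaSeq, s) {
    tx <- random_dna(config@transcriptLength)
    if (!is.na(mirnaSeq)) {
      substr(tx, s, s + nchar(mirnaSeq) - 1L) <- revcomp(mirnaSeq)
    }
    tx
  }
  plant_target <- function(mirnaSeq, mirnaId, libs) {
    txIdx <<- txIdx + 1L
    txId <- sprintf("TX%04d", txIdx)
    s <- sample(80:150, 1L)
    transcripts[txId] <<- build_tx(mirnaSeq, s)
    txSite[[txId]] <<- list(seq = mirnaSeq, s = s)
    ml <- nchar(mirnaSeq)
    for (lib in libs) {
      pairs[[length(pairs) + 1L]] <<- data.frame(
        mirna_id = mirnaId, transcript_id = txId,
        site_start = s, cleavage_pos = s + ml - 10L,
        library = lib, stringsAsFactors = FALSE)
    }
    txId
  }
  for (k in seq_along(valIds)) {
    i <- valRows[k]
    for (tcount in seq_len(perMiRNA[k])) {
      plant_target(plan$seq[i], plan$catalog_id[i], "DM")
    }
  }
  ## a couple of decoy signals for non-candidate miRNAs in every library
  ddRows <- which(plan$role == "dd_only")
  if (length(ddRows) >= 2L) {
    for (i in ddRows[1:2]) {
      plant_target(plan$seq[i], plan$catalog_id[i], c("CG", "DD", "DM"))
    }
  }
  for (d in seq_len(config@nDecoyTranscripts)) {
    txIdx <- txIdx + 1L
    txId <- sprintf("TX%04d", txIdx)
    transcripts[txId] <- build_tx(NA_character_, 1L)
    txSite[[txId]] <- list(seq = NA_character_, s = 1L)
  }
  ## no planted miRNA tag may sit (sense) inside a transcript, or the mRNA
  ## contaminant filter would eat it; rebuild the rare offender
  repeat {
    bigtx <- paste(transcripts, collapse = "#")
    hit <- allTags[vapply(allTags, grepl, logical(1), x = bigtx, fixed = TRUE)]
    if (!length(hit)) break
    for (txId in names(transcripts)) {
      if (any(vapply(hit, grepl, logical(1), x = transcripts[[txId]],
                     fixed = TRUE))) {
        info <- txSite[[txId]]
        transcripts[txId] <- build_tx(info$seq, info$s)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               site_start = integer(0), cleavage_pos = integer(0),
               library = character(0))

  ## GO/KEGG annotation map: stress terms concentrated on planted targets
  goTerms <- data.frame(
    term = c("GO:0006355", "GO:0006351", "GO:0003677", "GO:0005634",
             "GO:0009734", "GO:0009737", "GO:0006950", "GO:0009414"),
    label = c("regulation of transcription, DNA-templated",
              "transcription, DNA-templated", "DNA binding", "nucleus",
              "auxin-activated signaling pathway",
              "response to abscisic acid", "response to stress",
              "response to water deprivation"),
    namespace = c("BP", "BP", "MF", "CC", "BP", "BP", "BP", "BP"),
    stringsAsFactors = FALSE)
  keggTerms <- data.frame(
    term = c("ko00500", "ko00330", "ko04075", "ko03040"),
    label = c("Starch and sucrose metabolism",
              "Arginine and proline metabolism",
              "Plant hormone signal transduction", "Spliceosome"),
    namespace = "pathway", stringsAsFactors = FALSE)
  termTable <- rbind(goTerms, keggTerms)
  stressTerms <- c("GO:0006355", "GO:0009737", "GO:0006950", "GO:0009414",
                   "ko00500", "ko00330")
  targetTx <- unique(pairs$transcript_id[pairs$library == "DM"])
  ann <- lapply(names(transcripts), function(tx) {
    pool <- if (tx %in% targetTx) stressTerms else termTable$term
    data.frame(gene = tx, term = sample(pool, 2L), stringsAsFactors = FALSE)
  })
  annotation <- do.call(rbind, ann)
  annotation <- merge(annotation, termTable, by = "term", sort = FALSE)
  annotation <- annotation[order(annotation$gene, annotation$term),
                           c("gene", "term", "label", "namespace")]
  rownames(annotation) <- NULL

  structure(list(mature = mature, precursor = precursor,
                 otherMature = otherMature, genome = genome,
                 contaminants = contaminants, contaminantTags = contamTags,
                 transcripts = transcripts, mirnas = plan, pairs = pairs,
                 annotation = annotation, windows = windowSpans,
                 preset = config@presetName),
            class = "MirnaReferenceBundle")
}

#' @export
print.MirnaReferenceBundle <- function(x, ...) {
  cat("MirnaReferenceBundle (", x$preset, "): ",
      nrow(x$mirnas), " planted miRNAs, ",
      length(x$mature), " wheat matures, ",
      length(x$transcripts), " transcripts, ",
      nrow(x$pairs), " planted cleavage rows\n", sep = "")
  invisible(x)
}

#' Ground truth of a scenario
#'
#' @param bundle a `MirnaReferenceBundle` from [makeReference()].
#' @param config the [ScenarioConfig-class] the bundle was built from.
#' @return A [GroundTruth-class] object.
#' @export
groundTruth <- function(bundle, config) {
  plan <- bundle$mirnas
  m <- expected_count_matrix(plan, config)
  rownames(m) <- plan$catalog_id
  truthTab <- plan[, c("catalog_id", "seq", "expected_group", "role",
                       "direction", "tp_dm", "tp_dd", "base",
                       "baseline_dir", "validated", "novel")]
  names(truthTab)[1:3] <- c("id", "seq", "group")
  rownames(truthTab) <- NULL
  new("GroundTruth", mirnas = truthTab, pairs = bundle$pairs,
      expectedCounts = m)
}

#' Write the reference bundle as FASTA/TSV files
#'
#' @param bundle a `MirnaReferenceBundle`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
writeReference <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mature = file.path(dir, "mature.fa"),
             precursor = file.path(dir, "precursor.fa"),
             other = file.path(dir, "other_species_mature.fa"),
             genome = file.path(dir, "genome_windows.fa"),
             contaminants = file.path(dir, "contaminants.fa"),
             transcripts = file.path(dir, "transcripts.fa"),
             annotation = file.path(dir, "annotation.tsv"))
  write_fasta(bundle$mature, paths[["mature"]])
  write_fasta(bundle$precursor, paths[["precursor"]])
  write_fasta(bundle$otherMature, paths[["other"]])
  write_fasta(bundle$genome, paths[["genome"]])
  write_fasta(bundle$contaminants, paths[["contaminants"]])
  write_fasta(bundle$transcripts, paths[["transcripts"]])
  utils::write.table(bundle$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate the 33 small RNA FASTQ libraries
#'
#' Reads follow the layout insert + 3' adapter + UMI, padded to the
#' configured read length.  Every molecule gets a unique UMI; PCR duplicates
#' (identical insert + UMI) are injected at `duplicationRate`.  Each library
#' is spiked with contaminant-derived inserts, adapter-less junk reads and
#' low-quality reads.  In `"acceptance"` noise mode molecule counts equal
#' the expected counts exactly; in `"realistic"` mode they are drawn from a
#' negative binomial with coefficient of variation `cv`.
#'
#' @param bundle a `MirnaReferenceBundle`.
#' @param config the matching [ScenarioConfig-class].
#' @param outdir directory for the FASTQ files (one per library).
#' @return The [GroundTruth-class]; written files are named
#'   `<GROUP>_<T>h_r<R>.fastq`.
#' @export
makeSrnaLibraries <- function(bundle, config, outdir) {
  set.seed(config@seed + 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- groundTruth(bundle, config)
  expected <- truth@expectedCounts
  libs <- colnames(expected)
  adapter <- config@adapter
  rl <- config@readLength
  ul <- config@umiLength
  goodQ <- strrep("I", rl)
  lowQ <- strrep("#", rl)

  ctags <- names(bundle$contaminantTags)
  nCT <- length(ctags)
  ccounts <- rep(config@contaminantReads %/% nCT, nCT)
  extra <- config@contaminantReads %% nCT
  if (extra > 0L) ccounts[seq_len(extra)] <- ccounts[seq_len(extra)] + 1L

  for (lib in libs) {
    counts <- expected[, lib]
    if (config@noiseMode == "realistic") {
      counts <- stats::rnbinom(length(counts), mu = counts,
                               size = 1 / max(config@cv^2, 1e-8))
    }
    inserts <- c(rep(bundle$mirnas$seq, counts), rep(ctags, ccounts))
    nMol <- length(inserts)
    umis <- encode_dna(seq_len(nMol), ul)
    nDup <- round(nMol * config@duplicationRate /
                  (1 - config@duplicationRate))
    dupIdx <- if (nDup > 0L) sample.int(nMol, nDup, replace = TRUE) else integer(0)
    ins <- c(inserts, inserts[dupIdx])
    umi <- c(umis, umis[dupIdx])
    pad <- strrep("A", rl - nchar(ins) - nchar(adapter) - ul)
    reads <- paste0(ins, adapter, umi, pad)
    quals <- rep(goodQ, length(reads))

    ## low-quality reads (valid layout, rejected by the mean-quality gate)
    if (config@lowQualityReads > 0L) {
      lqIns <- rep(ctags[1L], config@lowQualityReads)
      lqUmi <- encode_dna(nMol + seq_len(config@lowQualityReads), ul)
      lq <- paste0(lqIns, adapter, lqUmi,
                   strrep("A", rl - nchar(lqIns) - nchar(adapter) - ul))
      reads <- c(reads, lq)
      quals <- c(quals, rep(lowQ, length(lq)))
    }
    ## junk reads with no adapter hit
    nJunk <- config@junkReads
    while (nJunk > 0L) {
      j <- random_dna(rep(rl, nJunk))
      ok <- is.na(adapter_seed_pos(j, adapter))
      reads <- c(reads, j[ok])
      quals <- c(quals, rep(goodQ, sum(ok)))
      nJunk <- nJunk - sum(ok)
    }
    ids <- sprintf("%s_%06d", lib, seq_along(reads))
    write_fastq(ids, reads, quals, file.path(outdir, paste0(lib, ".fastq")))
  }
  truth
}

#' Simulate the three pooled degradome FASTQ libraries
#'
#' For every planted (miRNA, transcript) pair the library receives
#' `peakReads` reads whose 5' end sits exactly at the cleavage position
#' (opposite miRNA nucleotide 10), and every transcript receives
#' `backgroundSites` scattered single reads, so planted sites are unique
#' T-plot maxima (category 0) and background positions are category 4.
#'
#' @inheritParams makeSrnaLibraries
#' @param outdir directory for `CG.fastq`, `DD.fastq`, `DM.fastq`.
#' @return The [GroundTruth-class].
#' @export
makeDegradomeLibraries <- function(bundle, config, outdir) {
  set.seed(config@seed + 2L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rl <- 50L
  txs <- bundle$transcripts
  for (lib in c("CG", "DD", "DM")) {
    pp <- bundle$pairs[bundle$pairs$library == lib, , drop = FALSE]
    seqs <- character(0)
    for (r in seq_len(nrow(pp))) {
      tx <- txs[[pp$transcript_id[r]]]
      p <- pp$cleavage_pos[r]
      seqs <- c(seqs, rep(substr(tx, p, min(p + rl - 1L, nchar(tx))),
                          config@peakReads))
    }
    peakByTx <- split(pp$cleavage_pos, pp$transcript_id)
    for (txId in names(txs)) {
      tx <- txs[[txId]]
      maxStart <- nchar(tx) - rl + 1L
      forbidden <- peakByTx[[txId]]
      pool <- setdiff(seq_len(maxStart), forbidden)
      bg <- sample(pool, min(config@backgroundSites, length(pool)))
      seqs <- c(seqs, substr(rep(tx, length(bg)), bg, bg + rl - 1L))
    }
    ids <- sprintf("deg_%s_%05d", lib, seq_along(seqs))
    write_fastq(ids, seqs, rep(strrep("I", rl), length(seqs)),
                file.path(outdir, paste0(lib, ".fastq")))
  }
  groundTruth(bundle, config)
}

#' Simulate a full scenario to disk
#'
#' Runs [makeReference()], [makeSrnaLibraries()] and
#' [makeDegradomeLibraries()] and writes references, reads and ground-truth
#' tables under `outdir` (subdirectories `ref/`, `srna/`, `degradome/`,
#' `truth/`).  Byte-identical output for identical config.
#'
#' @param config a [ScenarioConfig-class].
#' @param outdir output directory.
#' @return A list with `bundle`, `truth` and the directory paths.
#' @export
simulateScenario <- function(config, outdir) {
  bundle <- makeReference(config)
  refdir <- file.path(outdir, "ref")
  writeReference(bundle, refdir)
  truth <- makeSrnaLibraries(bundle, config, file.path(outdir, "srna"))
  makeDegradomeLibraries(bundle, config, file.path(outdir, "degradome"))
  tdir <- file.path(outdir, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(truth@mirnas, file.path(tdir, "mirnas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth@pairs, file.path(tdir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(truth@expectedCounts),
                                truth@expectedCounts,
                                check.names = FALSE),
                     file.path(tdir, "expected_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(bundle = bundle, truth = truth,
       refdir = refdir, srnadir = file.path(outdir, "srna"),
       degradomedir = file.path(outdir, "degradome"), truthdir = tdir)
}
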