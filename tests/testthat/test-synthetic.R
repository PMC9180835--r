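test_that("references embed every planted mature in a folding precursor", {
  sc <- small_scenario()
  b <- sc$bundle
  cfg <- sc$cfg
  # wheat matures/precursors pair 1:1 under the naming convention
  expect_identical(length(b$mature), length(b$precursor))
  expect_setequal(memomiR:::precursor_name_of(names(b$mature)),
                  names(b$precursor))
  for (nm in names(b$mature)) {
    pre <- b$precursor[[memomiR:::precursor_name_of(nm)]]
    pos <- regexpr(b$mature[[nm]], pre, fixed = TRUE)
    expect_gte(pos, 1)
    hp <- predictHairpin(pre, c(pos, pos + nchar(b$mature[[nm]]) - 1L))
    expect_true(hp$passed, info = nm)
  }
  # every planted degradome pair references an existing transcript carrying
  # the reverse complement of its miRNA at the planted site
  truth <- sc$truth
  seqs <- setNames(truth@mirnas$seq, truth@mirnas$id)
  for (r in seq_len(nrow(truth@pairs))) {
    p <- truth@pairs[r, ]
    tx <- b$transcripts[[p$transcript_id]]
    mi <- seqs[[p$mirna_id]]
    expect_identical(substr(tx, p$site_start, p$site_start + nchar(mi) - 1L),
                     memomiR:::revcomp(mi))
    expect_identical(p$cleavage_pos, p$site_start + nchar(mi) - 10L)
  }
  # the requested number of distinct validated target transcripts exists
  dmPairs <- truth@pairs[truth@pairs$library == "DM" &
                         truth@pairs$mirna_id %in%
                           truth@mirnas$id[truth@mirnas$validated], ]
  expect_identical(length(unique(dmPairs$transcript_id)),
                   as.integer(cfg@nValidatedTargets))
})

test_that("planted tags survive the contaminant and mRNA filters", {
  sc <- small_scenario()
  b <- sc$bundle
  big <- paste(c(b$contaminants, b$transcripts), collapse = "#")
  hit <- vapply(b$mirnas$seq, grepl, logical(1), x = big, fixed = TRUE)
  expect_false(any(hit))
  expect_true(all(memomiR:::max_base_fraction(b$mirnas$seq) <= 0.8))
  # contaminant spike-in tags do sit inside contaminant records
  expect_true(all(vapply(names(b$contaminantTags), grepl, logical(1),
                         x = paste(b$contaminants, collapse = "#"),
                         fixed = TRUE)))
})

test_that("small RNA FASTQ libraries parse and follow the read layout", {
  cfg <- scenarioConfig(seed = 29L, junkReads = 5L, lowQualityReads = 3L)
  dir <- withr::local_tempdir()
  b <- makeReference(cfg)
  truth <- makeSrnaLibraries(b, cfg, dir)
  files <- list.files(dir, pattern = "fastq$", full.names = TRUE)
  expect_length(files, ncol(truth@expectedCounts))  # 33 libraries
  rd <- memomiR:::read_fastq_df(files[1])
  expect_true(all(nchar(rd$seq) == cfg@readLength))
  expect_true(all(nchar(rd$qual) == cfg@readLength))
  # trimming a planted read recovers a planted insert
  tr <- trimAndExtract(rd$seq[1], rd$qual[1], cfg@adapter, cfg@umiLength)
  expect_true(tr$insert %in% c(b$mirnas$seq, names(b$contaminantTags)))
  expect_identical(nchar(tr$umi), as.integer(cfg@umiLength))
})

test_that("degradome libraries pile planted signals at the cleavage site", {
  sc <- small_scenario()
  cfg <- sc$cfg
  dir <- withr::local_tempdir()
  truth <- makeDegradomeLibraries(sc$bundle, cfg, dir)
  mp <- mapTags(file.path(dir, "DM.fastq"), sc$bundle$transcripts)
  dmPairs <- truth@pairs[truth@pairs$library == "DM", ]
  for (r in seq_len(nrow(dmPairs))) {
    p <- dmPairs[r, ]
    prof <- mp$profiles[[p$transcript_id]]
    expect_identical(prof[p$cleavage_pos], as.integer(cfg@peakReads))
    # strictly dominant peak: category-0 signal by construction
    expect_true(all(prof[-p$cleavage_pos] < prof[p$cleavage_pos]))
  }
  # background-only transcripts never exceed single-read coverage
  bg <- setdiff(names(mp$profiles), dmPairs$transcript_id)
  for (tx in bg) expect_lte(max(mp$profiles[[tx]]), 1L)
})

test_that("identical configurations yield byte-identical outputs", {
  cfg <- scenarioConfig(seed = 41L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateScenario(cfg, d1)
  simulateScenario(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("duplication follows the configured rate arithmetic", {
  # duplicationRate r over m molecules yields about m/(1-r) reads
  cfg <- scenarioConfig(seed = 13L, duplicationRate = 0.5,
                        contaminantReads = 0L, junkReads = 0L,
                        lowQualityReads = 0L)
  dir <- withr::local_tempdir()
  b <- makeReference(cfg)
  truth <- makeSrnaLibraries(b, cfg, dir)
  lib <- colnames(truth@expectedCounts)[1]
  nMol <- sum(truth@expectedCounts[, lib])
  rd <- memomiR:::read_fastq_df(file.path(dir, paste0(lib, ".fastq")))
  expect_equal(nrow(rd), 2 * nMol, tolerance = 0.01)
})
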