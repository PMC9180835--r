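ADPT <- "TGGAATTCTCGG"

make_read <- function(insert, umi = strrep("G", 12), len = 50L,
                      adapter = ADPT) {
  r <- paste0(insert, adapter, umi)
  paste0(r, strrep("A", max(0L, len - nchar(r))))
}

test_that("trimAndExtract recovers insert and UMI from the read layout", {
  ins <- "ACGTGCATGCATCGATCGATC"  # 21 nt
  umi <- "ACGTACGTACGT"
  r <- make_read(ins, umi)
  out <- trimAndExtract(r, strrep("I", nchar(r)), ADPT)
  expect_identical(out$insert, ins)
  expect_identical(out$umi, umi)

  # one mismatch in the adapter's first 8 nt is tolerated
  r2 <- r
  substr(r2, nchar(ins) + 3L, nchar(ins) + 3L) <- "C"   # TGGAATTC -> TGCAATTC
  out2 <- trimAndExtract(r2, strrep("I", nchar(r2)), ADPT)
  expect_identical(out2$insert, ins)
})

test_that("rejection reasons cover quality, adapter, length and empty insert", {
  ins <- "ACGTGCATGCATCGATCGATC"
  r <- make_read(ins)
  lowq <- trimAndExtract(r, strrep("#", nchar(r)), ADPT)
  expect_true(lowq$rejected)
  expect_identical(lowq$reason, "low_quality")

  noad <- trimAndExtract(strrep("CA", 25), strrep("I", 50), ADPT)
  expect_identical(noad$reason, "no_adapter")

  # adapter at position 1: empty insert
  r0 <- make_read("")
  expect_identical(trimAndExtract(r0, strrep("I", nchar(r0)), ADPT)$reason,
                   "empty_insert")

  # raw length gate 30-80
  short <- substr(make_read(ins), 1, 29)
  expect_identical(trimAndExtract(short, strrep("I", 29), ADPT)$reason,
                   "length_gate")
  long <- paste0(make_read(ins, len = 50L), strrep("A", 40))
  expect_identical(trimAndExtract(long, strrep("I", nchar(long)), ADPT)$reason,
                   "length_gate")
})

test_that("UMI deduplication collapses identical (insert, UMI) molecules", {
  m <- data.frame(insert = c("AAAA", "AAAA", "CCCC", "CCCC"),
                  umi = c("GG", "GG", "TT", "TT"))
  dd <- dedupUmi(m)
  expect_identical(nrow(dd$unique), 2L)
  expect_identical(dd$duplicationRatio, 0.5)

  # distinct UMIs on the same insert are distinct molecules
  m2 <- data.frame(insert = rep("AAAA", 3), umi = c("GG", "GT", "TG"))
  expect_identical(nrow(dedupUmi(m2)$unique), 3L)

  empty <- dedupUmi(data.frame(insert = character(0), umi = character(0)))
  expect_identical(nrow(empty$unique), 0L)
  expect_identical(empty$duplicationRatio, 0)
})

test_that("collapseTags counts molecules per library and conserves totals", {
  mols <- list(
    lib1 = data.frame(insert = c("AAAA", "AAAA", "CCCC")),
    lib2 = data.frame(insert = c("CCCC")))
  tags <- collapseTags(mols)
  expect_setequal(tags$seq, c("AAAA", "CCCC"))
  expect_identical(tags$lib1[tags$seq == "AAAA"], 2L)
  expect_identical(tags$lib1[tags$seq == "CCCC"], 1L)
  expect_identical(tags$lib2[tags$seq == "AAAA"], 0L)
  expect_identical(sum(tags$lib1), 3L)
  expect_identical(sum(tags$lib2), 1L)
})

test_that("contaminant filtering removes substring, low-complexity and off-length tags", {
  rrna <- paste0("GGTT", "ACGTGCATGCATCGATCGATC", "CCAA")
  cont <- c(rRNA_1 = rrna, tRNA_1 = strrep("GCAT", 30))
  tags <- data.frame(
    seq = c("ACGTGCATGCATCGATCGATC",          # inside rRNA_1
            strrep("A", 21),                  # low complexity
            "GATTACAGATTACAGATTACAGATTA",     # 26 nt, clean
            "TCAGGCTAACGTTCGAATCAG"),         # clean 21-mer
    n = c(5L, 2L, 7L, 3L))
  out <- filterContaminants(tags, cont)
  expect_identical(out$tags$seq, "TCAGGCTAACGTTCGAATCAG")
  expect_setequal(out$removed$class, c("rRNA", "low_complexity"))
  expect_identical(out$offLength$seq, "GATTACAGATTACAGATTACAGATTA")
  expect_error(filterContaminants(tags, character(0)), "empty")
})

test_that("measured duplication ratio approaches the planted rate", {
  cfg <- scenarioConfig(seed = 19L, duplicationRate = 0.3,
                        contaminantReads = 0L, junkReads = 0L,
                        lowQualityReads = 0L)
  dir <- withr::local_tempdir()
  bundle <- makeReference(cfg)
  makeSrnaLibraries(bundle, cfg, dir)
  one <- preprocessLibrary(file.path(dir, "CG_0h_r1.fastq"), cfg@adapter)
  expect_lt(abs(one$stats[["duplication_ratio"]] - 0.3), 0.02)
  # conservation: accepted + rejected = raw reads
  s <- one$stats
  expect_identical(unname(s["molecules"] + s["length_gate"] + s["low_quality"] +
                          s["no_adapter"] + s["empty_insert"] +
                          s["umi_truncated"]),
                   unname(s["raw_reads"]))
})
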