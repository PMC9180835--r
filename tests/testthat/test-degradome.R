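rc <- memomiR:::revcomp

test_that("duplex scoring applies the match/wobble/mismatch penalty scheme", {
  mi <- "ACGTACGTACGTACGTACGTA"          # 21 nt
  expect_identical(scoreDuplex(mi, rc(mi)), 0)

  # G:U wobble opposite miRNA position 5 (inside the doubled 2-13 region):
  # 0.5 * 2 = 1.0.  miRNA pos 5 = A; make it G and pair it with T.
  mi2 <- mi
  substr(mi2, 5, 5) <- "G"
  site <- rc(mi2)
  sitePos <- nchar(mi2) + 1 - 5
  substr(site, sitePos, sitePos) <- "T"
  expect_identical(scoreDuplex(mi2, site), 1)

  # mismatch opposite position 20 (outside the doubled region): 1.0
  site3 <- rc(mi)
  p3 <- nchar(mi) + 1 - 20                # site base opposite miRNA pos 20
  stopifnot(substr(mi, 20, 20) == "T")    # T:C is a mismatch, not a wobble
  substr(site3, p3, p3) <- "C"
  expect_identical(scoreDuplex(mi, site3), 1)
  expect_error(scoreDuplex(mi, "ACGT"), "length")
})

test_that("candidate sites report the cleavage position opposite nucleotide 10", {
  set.seed(4)
  mi <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  tx <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  substr(tx, 491, 511) <- rc(mi)
  hits <- findCandidateSites(mi, tx, scoreMax = 4)
  expect_true(491 %in% hits$site_start)
  expect_identical(hits$cleavage_pos[hits$site_start == 491], 502L)
  expect_identical(hits$score[hits$site_start == 491], 0)
  # sliding-window scores agree with scoreDuplex on each window
  for (s in c(1L, 100L, 491L)) {
    expect_identical(memomiR:::score_windows(mi, tx, s),
                     scoreDuplex(mi, substr(tx, s, s + 20L)))
  }
  # an unrelated random transcript yields no site at threshold 4
  tx2 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  expect_identical(nrow(findCandidateSites(mi, tx2, scoreMax = 4)), 0L)
})

test_that("T-plot categories follow the peak definitions", {
  prof <- integer(50)
  prof[c(10, 20, 30)] <- c(10L, 4L, 1L)
  expect_identical(categorizeSite(prof, 10), 0L)   # unique maximum
  expect_identical(categorizeSite(prof, 20), 3L)   # 4 <= mean(10,4,1)=5
  expect_identical(categorizeSite(prof, 30), 4L)   # single read
  expect_true(is.na(categorizeSite(prof, 40)))     # uncovered

  prof2 <- integer(10); prof2[c(2, 7)] <- 5L; prof2[4] <- 1L
  expect_identical(categorizeSite(prof2, 2), 1L)   # two maxima
  expect_identical(categorizeSite(prof2, 7), 1L)

  prof3 <- integer(10); prof3[c(1, 2, 3, 4)] <- c(9L, 5L, 2L, 1L)
  expect_identical(categorizeSite(prof3, 2), 2L)   # 5 > mean 4.25, below max
  expect_error(categorizeSite(prof3, 11), "position")
})

test_that("category assignment matches the brute-force classifier on random profiles", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    prof <- integer(n)
    covered <- sample(n, sample(1:min(8, n), 1))
    prof[covered] <- rpois(length(covered), 3) + 1L
    pos <- sample(n, 1)
    expect_identical(categorizeSite(prof, pos), bf_category(prof, pos),
                     info = paste(i))
  }
})

test_that("categories are exhaustive and exclusive over covered positions", {
  set.seed(12)
  for (i in 1:50) {
    prof <- integer(30)
    covered <- sample(30, 6)
    prof[covered] <- rpois(6, 4) + 1L
    cats <- vapply(seq_len(30), function(p) categorizeSite(prof, p),
                   integer(1))
    expect_true(all(!is.na(cats[covered])))
    expect_true(all(is.na(cats[-covered])))
    expect_true(all(cats[covered] %in% 0:4))
  }
})

test_that("target validation finds exactly the planted cleavage signals", {
  run <- small_run()
  truth <- run$truth
  dmHits <- run$hits[run$hits$library == "DM", ]
  planted <- truth@pairs[truth@pairs$library == "DM", ]
  planted <- planted[planted$mirna_id %in% candidates(run$callSet), ]
  got <- unique(dmHits[, c("mirna_id", "transcript_id", "cleavage_pos")])
  expect_identical(nrow(got), nrow(planted))
  key <- function(d) sort(paste(d$mirna_id, d$transcript_id, d$cleavage_pos))
  expect_identical(key(got), key(planted))
  expect_true(all(dmHits$category == 0L))
  expect_true(all(dmHits$reads_at_site > 1L))
})

test_that("tightening score or category thresholds never adds hits", {
  run <- small_run()
  sc <- small_scenario()
  mp <- mapTags(file.path(file.path(tempdir(), "memomir-small-run"),
                          "degradome", "DM.fastq"),
                sc$bundle$transcripts)
  base <- validateTargets(setNames(sc$truth@mirnas$seq, sc$truth@mirnas$id),
                          mp$profiles, sc$bundle$transcripts,
                          scoreMax = 4, categoryMax = 3)
  tight1 <- validateTargets(setNames(sc$truth@mirnas$seq, sc$truth@mirnas$id),
                            mp$profiles, sc$bundle$transcripts,
                            scoreMax = 2, categoryMax = 3)
  tight2 <- validateTargets(setNames(sc$truth@mirnas$seq, sc$truth@mirnas$id),
                            mp$profiles, sc$bundle$transcripts,
                            scoreMax = 4, categoryMax = 0)
  key <- function(d) paste(d$mirna_id, d$transcript_id, d$cleavage_pos)
  expect_true(all(key(tight1) %in% key(base)))
  expect_true(all(key(tight2) %in% key(base)))
})

test_that("degradome mapping increments profiles at exact prefix matches", {
  txs <- c(t1 = paste(rep("ACGT", 75), collapse = ""))
  txs["t2"] <- txs["t1"]   # identical transcript: multi-mapping tag
  read <- substr(txs["t1"], 100, 149)
  mp <- mapTags(c(read, read, "TTTT"), txs)
  expect_identical(mp$profiles$t1[100], 2L)
  expect_identical(mp$profiles$t2[100], 2L)   # counts once per locus
  expect_identical(unname(mp$stats["short"]), 1L)
  expect_error(mapTags("ACGT", character(0)), "empty")
})
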