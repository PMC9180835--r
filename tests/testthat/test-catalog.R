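test_that("variant naming follows the L/R/ss suffix grammar", {
  ref <- "TAGCTAGCAAGCTAGCTAGCT"   # 21 nt
  expect_identical(nameVariant(ref, ref, "tae-miR531"), "tae-miR531")

  # 2-nt 5' trim
  expect_identical(nameVariant(substr(ref, 3, 21), ref, "tae-miR531"),
                   "tae-miR531_L-2")
  # 1-nt 3' extension and 1-nt 5' trim
  expect_identical(nameVariant(paste0(substr(ref, 2, 21), "A"), ref,
                               "tae-miR160a"),
                   "tae-miR160a_L-1R+1")
  # single substitution at position 21, reference G -> tag A
  ref2 <- paste0(substr(ref, 1, 20), "G")
  tag <- paste0(substr(ref2, 1, 20), "A")
  expect_identical(nameVariant(tag, ref2, "tae-MIR9676-p3"),
                   "tae-MIR9676-p3_1ss21GA")
  # two substitutions, each listed as <pos><ref><tag>
  tag2 <- ref
  substr(tag2, 6, 6) <- "C"; substr(tag2, 19, 19) <- "T"
  expect_identical(nameVariant(tag2, ref, "tae-MIR167a-p5"),
                   "tae-MIR167a-p5_2ss6AC19GT")
})

test_that("variant suffix operations regenerate the tag from the reference", {
  set.seed(5)
  apply_suffix <- function(ref, id, name) {
    suffix <- sub(paste0("^", name), "", id)
    tag <- ref
    if (grepl("L-([0-9]+)", suffix)) {
      k <- as.integer(sub(".*L-([0-9]+).*", "\\1", suffix))
      tag <- substr(tag, k + 1L, nchar(tag))
    }
    if (grepl("R-([0-9]+)", suffix)) {
      k <- as.integer(sub(".*R-([0-9]+).*", "\\1", suffix))
      tag <- substr(tag, 1L, nchar(tag) - k)
    }
    m <- regmatches(suffix, regexec("([0-9]+)ss(.*)$", suffix))[[1]]
    if (length(m)) {
      ops <- m[3]
      while (nzchar(ops)) {
        p <- regmatches(ops, regexec("^([0-9]+)([ACGT])([ACGT])", ops))[[1]]
        substr(tag, as.integer(p[2]), as.integer(p[2])) <- p[4]
        ops <- substr(ops, nchar(p[1]) + 1L, nchar(ops))
      }
    }
    tag
  }
  for (i in 1:20) {
    ref <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                 collapse = "")
    tag <- ref
    op <- sample(c("trim5", "trim3", "sub"), 1)
    if (op == "trim5") tag <- substr(tag, 2, 21)
    if (op == "trim3") tag <- substr(tag, 1, 19)
    if (op == "sub") {
      p <- sample(21, 1)
      substr(tag, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tag, p, p))[1]
    }
    id <- nameVariant(tag, ref, "x")
    expect_identical(apply_suffix(ref, id, "x"), tag, info = paste(op, ref))
  }
})

test_that("alignment fails beyond the 2-substitution / 2-nt-shift tolerance", {
  ref <- "TAGCTAGCAAGCTAGCTAGCT"
  expect_true(is.na(nameVariant(substr(ref, 6, 21), ref, "x")))  # 5-nt trim
  tag <- ref
  for (p in c(3, 9, 15)) {
    substr(tag, p, p) <- setdiff(c("A", "C", "G", "T"), substr(tag, p, p))[1]
  }
  expect_true(is.na(nameVariant(tag, ref, "x")))                  # 3 subs
})

test_that("the classification cascade recovers every planted group", {
  sc <- small_scenario()
  b <- sc$bundle
  truth <- sc$truth@mirnas
  for (i in seq_len(nrow(truth))) {
    cl <- classifyTag(truth$seq[i], b$mature, b$precursor,
                      b$otherMature, b$genome)
    expect_identical(cl$group, truth$group[i], info = truth$id[i])
    if (cl$group != "gp4") {
      expect_identical(cl$id, truth$id[i], info = truth$id[i])
    }
  }
})

test_that("tags with no reference support are unassigned", {
  sc <- small_scenario()
  b <- sc$bundle
  set.seed(99)
  for (i in 1:5) {
    tag <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                 collapse = "")
    cl <- classifyTag(tag, b$mature, b$precursor, b$otherMature, b$genome)
    expect_identical(cl$group, "unassigned")
  }
})

test_that("base composition is count-weighted and normalized", {
  bc <- baseComposition(c(strrep("T", 20)))
  expect_identical(bc$U[bc$position == 1], 1)
  bc2 <- baseComposition(c(paste0("T", strrep("C", 19)),
                           paste0("A", strrep("C", 19))),
                         weights = c(1, 1))
  expect_identical(bc2$U[bc2$position == 1], 0.5)
  expect_identical(bc2$A[bc2$position == 1], 0.5)
  # weighted: 3:1
  bc3 <- baseComposition(c(paste0("T", strrep("C", 19)),
                           paste0("A", strrep("C", 19))),
                         weights = c(3, 1))
  expect_identical(bc3$U[bc3$position == 1], 0.75)
  sums <- rowSums(bc3[, c("A", "C", "G", "U")])
  expect_true(all(abs(sums - 1) < 1e-12))
  # lengths with no tags are omitted
  expect_false(18 %in% baseComposition(strrep("A", 20))$length)
})
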