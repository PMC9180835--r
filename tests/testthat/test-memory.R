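test_that("unionDE pools significant ids across comparisons", {
  cmp <- function(ids, ps) data.frame(id = ids, p_value = ps)
  u <- unionDE(list(cmp(c("a", "b", "c"), c(0.01, 0.04, 0.9)),
                    cmp(c("a", "b", "c"), c(0.9, 0.01, 0.03))))
  expect_setequal(u, c("a", "b", "c"))
  expect_length(unionDE(list(cmp(c("a", "b"), c(0.5, 0.9)))), 0L)
  one <- cmp(c("a", "b"), c(0.01, 0.5))
  expect_identical(unionDE(list(one)), "a")
  expect_error(unionDE(list()), "no comparisons")
})

test_that("memory-candidate set logic reproduces hand-computed set algebra", {
  cs <- selectMemoryCandidates(dmUnion = c("a", "b", "c"),
                               ddUnion = c("b", "c", "d"),
                               dmVsDdUnion = c("c", "d"))
  expect_setequal(specificSet(cs), "a")
  expect_setequal(rescueSet(cs), "c")
  expect_setequal(candidates(cs), c("a", "c"))
  expect_setequal(sharedSet(cs), c("b", "c"))

  # empty DD union: everything DM-responsive is a candidate
  cs2 <- selectMemoryCandidates(letters[1:5], character(0), character(0))
  expect_setequal(candidates(cs2), letters[1:5])
})

test_that("the worked example with the reference cardinalities gives 195/186", {
  dm <- sprintf("mir%03d", 1:243)
  dd <- c(dm[1:57], sprintf("ddx%03d", 1:171))   # 57 shared, 228 total
  dmdd <- dm[1:9]                                 # 9 of the shared rescued
  cs <- selectMemoryCandidates(dm, dd, dmdd)
  expect_identical(length(sharedSet(cs)), 57L)
  expect_identical(length(specificSet(cs)), 186L)
  expect_identical(length(rescueSet(cs)), 9L)
  expect_identical(length(candidates(cs)), 195L)
})

test_that("candidate cardinality identity and monotonicity hold on random sets", {
  set.seed(31)
  for (i in 1:30) {
    uni <- sprintf("m%03d", 1:80)
    dm <- sample(uni, sample(5:60, 1))
    dd <- sample(uni, sample(5:60, 1))
    x <- sample(uni, sample(0:60, 1))
    cs <- selectMemoryCandidates(dm, dd, x)
    expect_identical(length(candidates(cs)),
                     length(cs@dmUnion) - length(cs@shared) +
                       length(cs@rescue))
    # enlarging the DM-vs-DD union never shrinks the candidate set
    x2 <- union(x, sample(uni, 10))
    cs2 <- selectMemoryCandidates(dm, dd, x2)
    expect_true(all(candidates(cs) %in% candidates(cs2)))
    # re-applying the selection with dd unchanged is idempotent
    cs3 <- selectMemoryCandidates(candidates(cs), dd, x)
    expect_setequal(candidates(cs3), candidates(cs))
    expect_identical(length(intersect(specificSet(cs), rescueSet(cs))), 0L)
  }
})

test_that("MemoryCallSet validity rejects inconsistent sets", {
  expect_error(new("MemoryCallSet", dmUnion = c("a", "b"), ddUnion = "b",
                   shared = "a", specific = "a", rescue = character(0),
                   candidates = "a", baselineUp = character(0),
                   baselineDown = character(0)),
               "shared")
})

test_that("baseline DE partitions significant calls by direction", {
  run <- small_run()
  se <- run$se
  bl <- baselineDE(se)
  sig <- bl$table[bl$table$significant, ]
  expect_setequal(c(bl$up, bl$down), sig$id)
  expect_length(intersect(bl$up, bl$down), 0L)
  truth <- run$truth@mirnas
  expect_setequal(bl$up, truth$id[truth$baseline_dir == "up"])
  expect_setequal(bl$down, truth$id[truth$baseline_dir == "down"])
})
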