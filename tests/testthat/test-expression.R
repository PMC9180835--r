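test_that("per-million normalization scales columns and preserves structure", {
  m <- matrix(c(5, 15, 0, 10), nrow = 2,
              dimnames = list(c("a", "b"), c("l1", "l2")))
  cpm <- normalizeCounts(m)
  expect_identical(cpm[, "l1"], c(a = 250000, b = 750000))
  expect_true(all(abs(colSums(cpm) - 1e6) < 1e-6))
  # already at 1e6 -> unchanged
  m2 <- matrix(c(4e5, 6e5), 2, 1, dimnames = list(NULL, "x"))
  expect_identical(normalizeCounts(m2), m2)
  # zero column passes through with a warning
  m3 <- cbind(m, l3 = c(0, 0))
  expect_warning(cpm3 <- normalizeCounts(m3), "zero")
  expect_identical(unname(cpm3[, "l3"]), c(0, 0))
  # zero pattern and within-column rank order are preserved
  set.seed(1)
  m4 <- matrix(rpois(60, 20), 10, 6)
  m4[sample(60, 10)] <- 0
  cpm4 <- normalizeCounts(m4)
  expect_identical(cpm4 == 0, m4 == 0)
  for (j in 1:6) expect_identical(order(cpm4[, j]), order(m4[, j]))
  expect_error(normalizeCounts(matrix(-1)), "non-negative")
})

test_that("expression levels partition at 10 reads and the dataset mean", {
  expect_identical(binExpression(5, 100), "low")
  expect_identical(binExpression(10, 100), "low")   # boundary -> low
  expect_identical(binExpression(11, 100), "medium")
  expect_identical(binExpression(100, 100), "medium")
  expect_identical(binExpression(150, 100), "high")
  expect_warning(binExpression(5, 8), "mean")
  expect_error(binExpression(-1, 100), "non-negative")
})

test_that("pooled t-test matches the hand-computed statistic and stats::t.test", {
  m <- rbind(x = c(8, 10, 12, 18, 20, 22))
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  de <- dePairwise(m, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(de$t, 6.123724, tolerance = 1e-6)
  expect_equal(de$p_value, 0.0036022, tolerance = 1e-4)
  ref <- stats::t.test(c(18, 20, 22), c(8, 10, 12), var.equal = TRUE)
  expect_equal(de$p_value, ref$p.value, tolerance = 1e-12)
  expect_identical(de$direction, "up")
  expect_equal(de$log2fc, log2(21 / 11), tolerance = 1e-12)
})

test_that("degenerate zero-variance groups use the p=0 / p=1 conventions", {
  m <- rbind(flat = rep(10, 6), jump = c(0, 0, 0, 50, 50, 50))
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  de <- dePairwise(m, paste0("a", 1:3), paste0("b", 1:3))
  expect_identical(de$p_value[de$id == "flat"], 1)
  expect_identical(de$direction[de$id == "flat"], "flat")
  expect_identical(de$p_value[de$id == "jump"], 0)
  expect_identical(de$direction[de$id == "jump"], "up")
  expect_error(dePairwise(m, "a1", paste0("b", 1:3)), "replicates")
})

test_that("t-test p approximates the 20-permutation enumeration on exchangeable data", {
  set.seed(2024)
  ps <- t(replicate(200, {
    x <- rnorm(6, mean = 50, sd = 5)   # exchangeable null abundances
    a <- x[1:3]; b <- x[4:6]
    m <- rbind(v = c(a, b))
    colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
    de <- dePairwise(m, paste0("a", 1:3), paste0("b", 1:3))
    c(t = de$p_value, perm = bf_perm_p(a, b))
  }))
  # the 3+3 two-sided permutation p is discrete with step 1/10, so
  # agreement is bounded by that granularity plus small-sample t error
  expect_lt(mean(abs(ps[, "t"] - ps[, "perm"])), 0.1)
  expect_lt(max(abs(ps[, "t"] - ps[, "perm"])), 0.35)
  expect_gt(stats::cor(ps[, "t"], ps[, "perm"]), 0.95)
})

test_that("one-way ANOVA matches the linear-model oracle and degenerate rules", {
  groups <- list(a = c(8, 10, 12), b = c(18, 20, 22), c = c(9, 11, 10))
  m <- rbind(v = unlist(groups))
  colnames(m) <- paste0("s", 1:9)
  cols <- split(paste0("s", 1:9), rep(c("a", "b", "c"), each = 3))
  r <- deMultigroup(m, cols)
  expect_equal(r$p_value, bf_anova_p(groups), tolerance = 1e-10)

  m2 <- rbind(flat = rep(1, 9), jump = c(1, 1, 1, 1, 1, 1, 100, 100, 100))
  colnames(m2) <- paste0("s", 1:9)
  r2 <- deMultigroup(m2, cols)
  expect_identical(r2$p_value[r2$id == "flat"], 1)
  expect_identical(r2$p_value[r2$id == "jump"], 0)
  expect_error(deMultigroup(m2, cols[1]), "groups")
})

test_that("2^-ddCt fold changes follow the defining arithmetic", {
  expect_identical(ddct(20, 18, 22, 20), 1)    # ddCt = 0
  expect_identical(ddct(25, 20, 28, 20), 8)    # ddCt = -3
  expect_identical(ddct(21, 20, 20, 20), 0.5)  # ddCt = 1
  expect_error(ddct(NA, 1, 1, 1))
})

test_that("planted effects are perfectly recovered in acceptance mode", {
  run <- small_run()
  truth <- run$truth@mirnas
  cs <- run$callSet
  dmTruth <- truth$id[truth$role %in% c("specific", "shared", "rescue")]
  expect_setequal(cs@dmUnion, dmTruth)
  ddTruth <- truth$id[truth$role %in% c("dd_only", "shared", "rescue")]
  expect_setequal(cs@ddUnion, ddTruth)
  expect_setequal(union(cs@baselineUp, cs@baselineDown),
                  truth$id[truth$baseline_dir != "none"])
  # no flat null is ever called
  nulls <- truth$id[truth$role == "null"]
  expect_length(intersect(nulls, c(cs@dmUnion, cs@ddUnion,
                                   cs@baselineUp, cs@baselineDown)), 0L)
})
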