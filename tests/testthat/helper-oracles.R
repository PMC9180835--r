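# Independent oracles used across the suite.  Each re-derives the quantity
# by direct enumeration, not by calling the implementation under test.

# Hypergeometric upper tail P(X >= k) by enumerating every n-subset of a
# population of N genes whose first K carry the term.
bf_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Two-sided permutation p-value of the pooled-t statistic for a 3+3 design
# (all 20 relabelings, observed split included).
bf_perm_p <- function(a, b) {
  pooled_t <- function(x, y) {
    sp2 <- (stats::var(x) + stats::var(y)) / 2
    (mean(y) - mean(x)) / sqrt(sp2 * (2 / 3))
  }
  vals <- c(a, b)
  tObs <- abs(pooled_t(a, b))
  splits <- utils::combn(6, 3)
  tAll <- apply(splits, 2, function(ix) {
    abs(pooled_t(vals[ix], vals[-ix]))
  })
  mean(tAll >= tObs - 1e-12)
}

# T-plot category by a literal restatement of the definitions.
bf_category <- function(profile, pos) {
  c0 <- profile[pos]
  if (c0 == 0) return(NA_integer_)
  M <- max(profile)
  covered <- profile[profile >= 1]
  mu <- sum(covered) / length(covered)
  nMax <- sum(profile == M)
  if (c0 == 1) 4L
  else if (c0 == M && nMax == 1) 0L
  else if (c0 == M) 1L
  else if (c0 > mu) 2L
  else 3L
}

# Maximum number of admissible base pairs (A:T, G:C, G:T; loop >= 3) by
# exhaustive recursion over all secondary structures (n <= ~16).
bf_max_pairs <- function(seq, minLoop = 3L) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  canp <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i <= minLoop) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - minLoop - 1L)) {
      if (canp(s[k], s[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + 1L + rec(k + 1L, j - 1L))
      }
    }
    best
  }
  rec(1L, length(s))
}

# One-way ANOVA p-value through R's linear-model machinery.
bf_anova_p <- function(groups) {
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
}
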