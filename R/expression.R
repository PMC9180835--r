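## Expression analysis: per-million normalization, expression-level binning,
## t-test / ANOVA differential expression and the 2^-ddCt utility.
##
## The degenerate-variance conventions matter on deterministic synthetic
## counts: two zero-variance groups with equal means are maximally
## non-significant (p = 1), with unequal means maximally significant (p = 0).

## Accept either a SummarizedExperiment (assay "counts") or a plain matrix.
as_count_matrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    as.matrix(x)
  }
}

#' Normalize a count matrix to abundances per million
#'
#' Scales every library (column) so its total equals 1e6.  All-zero columns
#' pass through as zeros with a warning.
#'
#' @param x count matrix (miRNAs x libraries) or `SummarizedExperiment`
#'   with a `counts` assay.
#' @return Matrix of normalized abundances, or (for a
#'   `SummarizedExperiment` input) the object with an added `cpm` assay.
#' @examples
#' normalizeCounts(matrix(c(5, 15), 2, 1))  # 250000, 750000
#' @export
normalizeCounts <- function(x) {
  m <- as_count_matrix(x)
  if (any(m < 0)) stop("counts must be non-negative")
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning("library total is zero for: ",
            paste(colnames(m)[zero], collapse = ", "),
            "; column(s) passed through as zeros")
    tot[zero] <- 1
  }
  cpm <- sweep(m, 2L, tot, "/") * 1e6
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "cpm") <- cpm
    x
  } else {
    cpm
  }
}

#' Bin mean abundances into high/medium/low expression levels
#'
#' `low` when the abundance is at most 10 reads, `medium` above 10 but not
#' above the dataset mean, `high` above the dataset mean.
#'
#' @param x mean abundance(s), non-negative.
#' @param datasetMean mean abundance over the whole dataset; should exceed
#'   10 (otherwise the medium band is empty and a warning is thrown).
#' @return character vector of levels.
#' @export
binExpression <- function(x, datasetMean) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (datasetMean <= 10)
    warning("dataset mean <= 10: the medium band is empty")
  ifelse(x > datasetMean, "high", ifelse(x > 10, "medium", "low"))
}

## Vectorized pooled-variance two-sample t-test over matrix rows with the
## degenerate conventions above.
pooled_t_rows <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1L, stats::var)
  vB <- apply(B, 1L, stats::var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mB - mA) / se
  p <- 2 * stats::pt(abs(t), df = nA + nB - 2, lower.tail = FALSE)
  degen <- se == 0
  p[degen & mA == mB] <- 1
  p[degen & mA != mB] <- 0
  t[degen] <- NA_real_
  list(t = t, p = p, meanA = mA, meanB = mB)
}

#' Pairwise differential expression by pooled-variance t-test
#'
#' Two-sided two-sample Student's t-test per miRNA on normalized
#' abundances, group A being the reference.  `log2fc = log2((meanB + 1) /
#' (meanA + 1))`; direction is `up` when the B mean strictly exceeds the A
#' mean, `down` when strictly lower, else `flat`.  Degenerate rows (both
#' groups zero-variance) get p = 1 for equal means, p = 0 otherwise.
#'
#' @param x normalized abundance matrix or `SummarizedExperiment` (the
#'   `cpm` assay is used when present, else `counts`).
#' @param aLibs,bLibs column names (or indices) of the reference and test
#'   groups; each needs >= 2 replicates.
#' @param alpha significance threshold on the raw p-value.
#' @param adjust optional multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`, matching a plain p < alpha
#'   threshold); when not `"none"`, significance is called on the adjusted
#'   values.
#' @return data.frame: `id`, `mean_A`, `mean_B`, `log2fc`, `t`, `p_value`,
#'   (`p_adj`), `direction`, `significant`.
#' @examples
#' m <- rbind(x = c(8, 10, 12, 18, 20, 22))
#' colnames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")
#' dePairwise(m, c("a1", "a2", "a3"), c("b1", "b2", "b3"))$p_value
#' @export
dePairwise <- function(x, aLibs, bLibs, alpha = 0.05, adjust = "none") {
  m <- de_input_matrix(x)
  if (length(aLibs) < 2L || length(bLibs) < 2L)
    stop("need at least 2 replicates on each side of the contrast")
  A <- m[, aLibs, drop = FALSE]
  B <- m[, bLibs, drop = FALSE]
  r <- pooled_t_rows(A, B)
  direction <- ifelse(r$meanB > r$meanA, "up",
                      ifelse(r$meanB < r$meanA, "down", "flat"))
  out <- data.frame(id = rownames(m), mean_A = r$meanA, mean_B = r$meanB,
                    log2fc = log2((r$meanB + 1) / (r$meanA + 1)),
                    t = r$t, p_value = r$p, direction = direction,
                    stringsAsFactors = FALSE)
  if (!identical(adjust, "none")) {
    out$p_adj <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  rownames(out) <- NULL
  out
}

de_input_matrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    SummarizedExperiment::assay(x, if ("cpm" %in% nm) "cpm" else "counts")
  } else {
    as.matrix(x)
  }
}

#' Multi-group differential expression by one-way ANOVA
#'
#' One-way fixed-effects ANOVA per miRNA across the supplied groups, with
#' the same degenerate conventions as [dePairwise()]: zero within-group
#' variance gives p = 1 when all group means agree and p = 0 otherwise.
#'
#' @param x abundance matrix or `SummarizedExperiment`.
#' @param groups named list mapping group name -> column names/indices;
#'   >= 2 groups with >= 2 replicates each.
#' @return data.frame: `id`, `F`, `p_value`.
#' @export
deMultigroup <- function(x, groups) {
  m <- de_input_matrix(x)
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with >= 2 replicates each")
  mats <- lapply(groups, function(g) m[, g, drop = FALSE])
  k <- length(mats)
  ns <- vapply(mats, ncol, integer(1))
  N <- sum(ns)
  gm <- vapply(mats, rowMeans, numeric(nrow(m)))
  if (nrow(m) == 1L) gm <- matrix(gm, nrow = 1L)
  grand <- as.vector(gm %*% ns) / N
  ssb <- as.vector(sweep(gm, 1L, grand, "-")^2 %*% ns)
  sswM <- vapply(mats, function(g) {
    rowSums((g - rowMeans(g))^2)
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) sswM <- matrix(sswM, nrow = 1L)
  ssw <- rowSums(sswM)
  dfb <- k - 1L
  dfw <- N - k
  Fstat <- (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  degen <- ssw == 0
  p[degen & ssb <= 1e-12] <- 1
  p[degen & ssb > 1e-12] <- 0
  Fstat[degen] <- NA_real_
  data.frame(id = rownames(m), F = Fstat, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative expression by the 2^-ddCt method
#'
#' `fold = 2^-((ctTargetTreat - ctRefTreat) - (ctTargetCtrl - ctRefCtrl))`.
#'
#' @param ctTargetTreat,ctRefTreat Ct of target and reference gene in the
#'   treated sample.
#' @param ctTargetCtrl,ctRefCtrl Ct of target and reference gene in the
#'   control sample.
#' @return Fold change(s) relative to control.
#' @examples
#' ddct(25, 20, 28, 20)  # 8
#' @export
ddct <- function(ctTargetTreat, ctRefTreat, ctTargetCtrl, ctRefCtrl) {
  stopifnot(is.finite(ctTargetTreat), is.finite(ctRefTreat),
            is.finite(ctTargetCtrl), is.finite(ctRefCtrl))
  2^-((ctTargetTreat - ctRefTreat) - (ctTargetCtrl - ctRefCtrl))
}
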