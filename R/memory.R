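## Drought-memory candidate selection: set logic over per-contrast
## differential-expression results.

#' Union of significant ids over several DE comparisons
#'
#' @param comparisons list of data.frames from [dePairwise()] (each with
#'   `id` and `p_value`).
#' @param alpha significance threshold.
#' @return character vector of ids significant (p < alpha) in at least one
#'   comparison.
#' @export
unionDE <- function(comparisons, alpha = 0.05) {
  if (length(comparisons) == 0L) stop("no comparisons supplied")
  ids <- lapply(comparisons, function(cmp) {
    stopifnot(all(c("id", "p_value") %in% names(cmp)))
    cmp$id[cmp$p_value < alpha]
  })
  unique(unlist(ids))
}

#' Select drought-memory candidate miRNAs
#'
#' The memory-candidate set logic: miRNAs responding to renewed drought in
#' primed plants (`dmUnion`, DM-vs-CG over the post-stress timepoints) but
#' not in unprimed ones (`ddUnion`) are memory-specific; miRNAs shared by
#' both unions are discarded unless they additionally differ between the
#' primed and unprimed groups themselves (`dmVsDdUnion`), in which case they
#' are rescued.  Candidates are the union of specific and rescued miRNAs.
#'
#' @param dmUnion,ddUnion ids significant in DM-vs-CG / DD-vs-CG at one or
#'   more post-stress timepoints.
#' @param dmVsDdUnion ids significant between DM and DD at one or more
#'   post-stress timepoints.
#' @param baselineUp,baselineDown optional baseline (DM_0h vs CG_0h) calls
#'   carried along for reporting.
#' @return A [MemoryCallSet-class].
#' @examples
#' cs <- selectMemoryCandidates(dmUnion = c("a", "b", "c"),
#'                              ddUnion = c("b", "c", "d"),
#'                              dmVsDdUnion = c("c", "d"))
#' candidates(cs)  # "a" (specific) and "c" (rescued)
#' @export
selectMemoryCandidates <- function(dmUnion, ddUnion, dmVsDdUnion = character(0),
                                   baselineUp = character(0),
                                   baselineDown = character(0)) {
  dmUnion <- unique(as.character(dmUnion))
  ddUnion <- unique(as.character(ddUnion))
  dmVsDdUnion <- unique(as.character(dmVsDdUnion))
  shared <- intersect(dmUnion, ddUnion)
  specific <- setdiff(dmUnion, shared)
  rescue <- intersect(shared, dmVsDdUnion)
  new("MemoryCallSet",
      dmUnion = dmUnion, ddUnion = ddUnion, shared = shared,
      specific = specific, rescue = rescue,
      candidates = union(specific, rescue),
      baselineUp = unique(as.character(baselineUp)),
      baselineDown = unique(as.character(baselineDown)))
}

#' Baseline (pre-stress) differential expression
#'
#' DM_0h vs CG_0h contrast (CG as reference) with the calls partitioned by
#' direction.
#'
#' @param x abundance matrix or `SummarizedExperiment` whose column names
#'   follow the `GROUP_Th_rR` convention.
#' @param timepoint baseline timepoint (default 0).
#' @param alpha significance threshold.
#' @return list: `table` (the [dePairwise()] result), `up`, `down`
#'   (significant ids by direction).
#' @export
baselineDE <- function(x, timepoint = 0L, alpha = 0.05) {
  m <- de_input_matrix(x)
  meta <- parse_library_names(colnames(m))
  aLibs <- meta$library[meta$group == "CG" & meta$timepoint == timepoint]
  bLibs <- meta$library[meta$group == "DM" & meta$timepoint == timepoint]
  if (length(aLibs) < 2L || length(bLibs) < 2L)
    stop("CG and DM libraries at timepoint ", timepoint, " are required")
  de <- dePairwise(m, aLibs, bLibs, alpha = alpha)
  sig <- de[de$significant, , drop = FALSE]
  list(table = de,
       up = sig$id[sig$direction == "up"],
       down = sig$id[sig$direction == "down"])
}

#' All memory-relevant contrasts from a labelled abundance matrix
#'
#' Computes, for every post-stress timepoint, the DM-vs-CG, DD-vs-CG and
#' DM-vs-DD pairwise tests plus the baseline contrast, and applies
#' [selectMemoryCandidates()].
#'
#' @inheritParams baselineDE
#' @return list: `callSet` (a [MemoryCallSet-class]), `contrasts` (named
#'   list of [dePairwise()] tables), `baseline` (from [baselineDE()]).
#' @export
memoryAnalysis <- function(x, alpha = 0.05) {
  m <- de_input_matrix(x)
  meta <- parse_library_names(colnames(m))
  tps <- sort(unique(meta$timepoint))
  post <- tps[-1L]
  libs_of <- function(g, t) meta$library[meta$group == g & meta$timepoint == t]
  contrasts <- list()
  for (t in post) {
    contrasts[[sprintf("DM_%dh_vs_CG_%dh", t, t)]] <-
      dePairwise(m, libs_of("CG", t), libs_of("DM", t), alpha = alpha)
    contrasts[[sprintf("DD_%dh_vs_CG_%dh", t, t)]] <-
      dePairwise(m, libs_of("CG", t), libs_of("DD", t), alpha = alpha)
    contrasts[[sprintf("DM_%dh_vs_DD_%dh", t, t)]] <-
      dePairwise(m, libs_of("DD", t), libs_of("DM", t), alpha = alpha)
  }
  dmUnion <- unionDE(contrasts[grep("^DM_\\d+h_vs_CG", names(contrasts))], alpha)
  ddUnion <- unionDE(contrasts[grep("^DD_\\d+h_vs_CG", names(contrasts))], alpha)
  dmVsDd <- unionDE(contrasts[grep("^DM_\\d+h_vs_DD", names(contrasts))], alpha)
  bl <- baselineDE(m, timepoint = tps[1L], alpha = alpha)
  cs <- selectMemoryCandidates(dmUnion, ddUnion, dmVsDd,
                               baselineUp = bl$up, baselineDown = bl$down)
  list(callSet = cs, contrasts = contrasts, baseline = bl)
}
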