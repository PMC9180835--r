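## Hypergeometric over-representation of validated target genes and the
## miRNA-gene-term association export.

#' Hypergeometric GO/KEGG over-representation
#'
#' For each term with K annotated genes in a population of N, and k of the
#' n selected genes carrying the term, computes the upper hypergeometric
#' tail p = P(X >= k).  By default the population is every gene with at
#' least one annotation in the map (standard ORA practice); pass a
#' `universe` to widen it.
#'
#' @param selected character vector of selected genes (must be inside the
#'   population).
#' @param annotation data.frame with columns `gene`, `term` and optionally
#'   `label`, `namespace`.
#' @param alpha significance threshold.
#' @param universe optional explicit population of genes; default is all
#'   annotated genes.
#' @param adjust multiple-testing correction for [stats::p.adjust()]
#'   (default `"none"`).
#' @return data.frame sorted by ascending p: `term`, `label`, `namespace`,
#'   `k`, `n`, `K`, `N`, `p_value`, `significant`.
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g3", "g4"),
#'                   term = c("T1", "T1", "T2", "T2"))
#' hypergeomEnrich(c("g1", "g2"), ann)
#' @export
hypergeomEnrich <- function(selected, annotation, alpha = 0.05,
                            universe = NULL, adjust = "none") {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  selected <- unique(as.character(selected))
  if (length(selected) == 0L) stop("selected gene set is empty")
  pop <- if (is.null(universe)) unique(annotation$gene) else unique(universe)
  if (!all(annotation$gene %in% pop))
    stop("every annotated gene must belong to the population")
  if (!all(selected %in% pop))
    stop("selected genes must be a subset of the population")
  N <- length(pop)
  n <- length(selected)
  byTerm <- split(unique(annotation[, c("gene", "term")])$gene,
                  unique(annotation[, c("gene", "term")])$term)
  rows <- lapply(names(byTerm), function(term) {
    genes <- byTerm[[term]]
    K <- length(genes)
    k <- length(intersect(genes, selected))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meta <- unique(annotation[, intersect(c("term", "label", "namespace"),
                                        names(annotation)), drop = FALSE])
  out <- merge(out, meta, by = "term", all.x = TRUE, sort = FALSE)
  if (!identical(adjust, "none")) {
    out$p_adj <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA-gene-term association edge list
#'
#' Exports the two-layer association used for network views: one edge per
#' validated (candidate miRNA -> target gene) pair and one edge per
#' (gene -> significantly enriched term) membership among those targets.
#'
#' @param callSet a [MemoryCallSet-class]; hits are restricted to its
#'   candidate miRNAs.
#' @param hits target-hit data.frame from [validateTargets()].
#' @param enrich enrichment table from [hypergeomEnrich()].
#' @param annotation the gene/term map used for the enrichment.
#' @return data.frame of edges: `from`, `to`, `type`
#'   (`"mirna-gene"`/`"gene-term"`).
#' @export
associationTable <- function(callSet, hits, enrich, annotation) {
  stopifnot(is(callSet, "MemoryCallSet"))
  hits <- hits[hits$mirna_id %in% candidates(callSet), , drop = FALSE]
  mg <- unique(hits[, c("mirna_id", "transcript_id")])
  edges <- data.frame(from = mg$mirna_id, to = mg$transcript_id,
                      type = "mirna-gene", stringsAsFactors = FALSE)
  sigTerms <- enrich$term[enrich$significant]
  if (length(sigTerms)) {
    ann <- unique(annotation[annotation$term %in% sigTerms &
                             annotation$gene %in% mg$transcript_id,
                             c("gene", "term")])
    if (nrow(ann)) {
      edges <- rbind(edges,
                     data.frame(from = ann$gene, to = ann$term,
                                type = "gene-term", stringsAsFactors = FALSE))
    }
  }
  rownames(edges) <- NULL
  edges
}
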