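## End-to-end pipeline: simulate -> preprocess -> catalog -> expression ->
## memory selection -> degradome validation -> enrichment, with a
## machine-readable run report.

#' Read a scenario configuration from a YAML file
#'
#' Field names mirror the arguments of [scenarioConfig()]; unknown fields
#' raise a configuration error naming the offending field.
#'
#' @param path YAML file.
#' @return A [ScenarioConfig-class].
#' @export
readScenarioConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenarioConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(scenarioConfig, vals)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(lapply(slotNames(config), function(s) slot(config, s)), file = f)
  unname(tools::md5sum(f))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full drought-memory pipeline on a simulated scenario
#'
#' Executes every stage in order, writing all intermediate tables under
#' `outdir` so each stage is independently inspectable, and returns a run
#' report whose cardinalities can be compared against the scenario's
#' [GroundTruth-class].  Deterministic given the configuration (which
#' includes the seed).
#'
#' @param config a [ScenarioConfig-class] or path to a YAML config
#'   (see [readScenarioConfig()]).
#' @param outdir output directory.
#' @param alpha DE and enrichment significance threshold.
#' @param scoreMax maximum duplex penalty for target validation.
#' @param categoryMax maximum T-plot category retained (default 2:
#'   categories below 3).
#' @return A `MemoryRunReport` (list) with per-stage statistics; also
#'   written as `report.json` under `outdir`.
#' @export
runPipeline <- function(config, outdir, alpha = 0.05, scoreMax = 4.0,
                        categoryMax = 2L) {
  if (is.character(config)) config <- readScenarioConfig(config)
  stopifnot(is(config, "ScenarioConfig"))
  validObject(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  message("[memomir] simulating scenario '", config@presetName, "'")
  sim <- simulateScenario(config, outdir)
  bundle <- sim$bundle

  message("[memomir] preprocessing ", ncol(sim$truth@expectedCounts),
          " libraries")
  fq <- list.files(sim$srnadir, pattern = "\\.fastq$", full.names = TRUE)
  names(fq) <- sub("\\.fastq$", "", basename(fq))
  pre <- preprocessLibraries(fq, adapter = config@adapter,
                             umiLen = config@umiLength)
  write_tsv(pre$stats, file.path(outdir, "preprocess_stats.tsv"))

  filt <- filterContaminants(pre$tags, bundle$contaminants,
                             mrna = bundle$transcripts)
  write_tsv(filt$tags, file.path(outdir, "tags.tsv"))

  message("[memomir] classifying ", nrow(filt$tags), " unique tags")
  cat0 <- buildCatalog(filt$tags, bundle$mature, bundle$precursor,
                       bundle$otherMature, bundle$genome)
  se <- normalizeCounts(cat0$se)
  rd <- SummarizedExperiment::rowData(se)
  catalogTab <- data.frame(id = rownames(se), seq = rd$seq, group = rd$group,
                           precursor = rd$precursorId,
                           stringsAsFactors = FALSE)
  write_tsv(catalogTab, file.path(outdir, "catalog.tsv"))

  message("[memomir] differential expression and memory selection")
  mem <- memoryAnalysis(se, alpha = alpha)
  for (nm in names(mem$contrasts)) {
    write_tsv(mem$contrasts[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))
  }
  write_tsv(mem$baseline$table, file.path(outdir, "de_baseline.tsv"))
  cs <- mem$callSet

  ## expression levels of the candidates (binned on mean normalized counts)
  cpm <- SummarizedExperiment::assay(se, "cpm")
  meanAb <- rowMeans(cpm)
  levels <- binExpression(meanAb, mean(meanAb))
  candLevels <- table(factor(levels[candidates(cs)],
                             levels = c("high", "medium", "low")))

  message("[memomir] degradome target validation")
  candSeqs <- setNames(rd$seq, rownames(se))[candidates(cs)]
  degFiles <- setNames(file.path(sim$degradomedir,
                                 paste0(c("CG", "DD", "DM"), ".fastq")),
                       c("CG", "DD", "DM"))
  hits <- list()
  degStats <- list()
  for (lib in names(degFiles)) {
    mp <- mapTags(degFiles[[lib]], bundle$transcripts)
    h <- validateTargets(candSeqs, mp$profiles, bundle$transcripts,
                         scoreMax = scoreMax, categoryMax = categoryMax,
                         library = lib)
    hits[[lib]] <- h
    degStats[[lib]] <- c(mp$stats,
                         validated_mirnas = length(unique(h$mirna_id)),
                         validated_transcripts = length(unique(h$transcript_id)))
  }
  allHits <- do.call(rbind, hits)
  write_tsv(allHits, file.path(outdir, "target_hits.tsv"))
  dmHits <- hits[["DM"]]
  validatedMirnas <- unique(dmHits$mirna_id)
  baselineIds <- union(cs@baselineUp, cs@baselineDown)
  validatedLevels <- table(factor(levels[validatedMirnas],
                                  levels = c("high", "medium", "low")))

  message("[memomir] enrichment of validated targets")
  selectedGenes <- unique(dmHits$transcript_id)
  enr <- if (length(selectedGenes)) {
    hypergeomEnrich(selectedGenes, bundle$annotation, alpha = alpha)
  } else {
    data.frame(term = character(0), significant = logical(0))
  }
  write_tsv(enr, file.path(outdir, "enrichment.tsv"))
  edges <- associationTable(cs, dmHits, enr, bundle$annotation)
  write_tsv(edges, file.path(outdir, "association_edges.tsv"))

  memberships <- data.frame(
    id = rownames(se),
    dm_union = rownames(se) %in% cs@dmUnion,
    dd_union = rownames(se) %in% cs@ddUnion,
    shared = rownames(se) %in% cs@shared,
    specific = rownames(se) %in% cs@specific,
    rescue = rownames(se) %in% cs@rescue,
    candidate = rownames(se) %in% cs@candidates,
    baseline_up = rownames(se) %in% cs@baselineUp,
    baseline_down = rownames(se) %in% cs@baselineDown,
    validated = rownames(se) %in% validatedMirnas)
  write_tsv(memberships, file.path(outdir, "memory_sets.tsv"))

  report <- list(
    preset = config@presetName,
    seed = config@seed,
    config_hash = config_hash(config),
    libraries = ncol(se),
    preprocess = list(
      raw_reads = sum(pre$stats$raw_reads),
      molecules = sum(pre$stats$molecules),
      unique_molecules = sum(pre$stats$unique_molecules),
      mean_duplication_ratio = mean(pre$stats$duplication_ratio)),
    tags = list(
      unique_tags = nrow(pre$tags),
      clean_tags = nrow(filt$tags),
      removed = as.list(filt$stats)),
    catalog = as.list(table(factor(rd$group, levels = MIRNA_GROUPS))),
    de = lapply(mem$contrasts, function(d) sum(d$significant)),
    baseline = list(total = length(baselineIds),
                    up = length(cs@baselineUp),
                    down = length(cs@baselineDown)),
    memory = list(dm_union = length(cs@dmUnion),
                  dd_union = length(cs@ddUnion),
                  shared = length(cs@shared),
                  specific = length(cs@specific),
                  rescue = length(cs@rescue),
                  candidates = length(cs@candidates)),
    candidate_levels = as.list(candLevels),
    degradome = lapply(degStats, as.list),
    validated = list(
      mirnas = length(validatedMirnas),
      transcripts = length(selectedGenes),
      baseline_and_validated = length(intersect(baselineIds, validatedMirnas)),
      novel = sum(rd$group[match(validatedMirnas, rownames(se))] == "gp4"),
      levels = as.list(validatedLevels)),
    enrichment = list(terms_tested = nrow(enr),
                      significant = sum(enr$significant)))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(c(report,
              list(callSet = cs, se = se, hits = allHits, truth = sim$truth)),
            class = "MemoryRunReport")
}

#' @export
print.MemoryRunReport <- function(x, ...) {
  cat("memomiR run ('", x$preset, "', seed ", x$seed, ")\n", sep = "")
  cat("  baseline DE: ", x$baseline$total, " (", x$baseline$up, " up, ",
      x$baseline$down, " down)\n", sep = "")
  cat("  DM union ", x$memory$dm_union, ", DD union ", x$memory$dd_union,
      ", shared ", x$memory$shared, "\n", sep = "")
  cat("  candidates: ", x$memory$candidates, " (", x$memory$specific,
      " specific + ", x$memory$rescue, " rescue)\n", sep = "")
  cat("  validated: ", x$validated$mirnas, " miRNAs over ",
      x$validated$transcripts, " transcripts (",
      x$validated$baseline_and_validated, " also baseline-responsive)\n",
      sep = "")
  cat("  enriched terms: ", x$enrichment$significant, "/",
      x$enrichment$terms_tested, "\n", sep = "")
  invisible(x)
}
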