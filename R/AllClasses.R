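#' @import methods
NULL

#' Scenario configuration for the synthetic drought-memory study
#'
#' A `ScenarioConfig` fixes everything the synthetic-data generator needs to
#' emulate a three-group (CG control, DD direct drought, DM drought memory)
#' by four-timepoint (0, 1, 6, 12 h) small RNA + degradome experiment with a
#' planted differential-expression structure.  [csMemoryScenario()] returns the
#' preset `cs-memory-v1` whose planted cardinalities mirror the reference
#' wheat drought-memory set structure; [scenarioConfig()] builds arbitrary
#' (e.g. desk-scale) scenarios.
#'
#' Planted set cardinalities (all counts of miRNAs unless noted):
#' `baselineUp`/`baselineDown` are differentially expressed in DM_0h vs CG_0h;
#' `nSpecific` respond to DM (vs CG) at one of 1/6/12 h but never to DD;
#' `nShared` respond to both DM and DD, of which `nRescue` additionally differ
#' between DM and DD (and so are rescued into the candidate set);
#' `nDdOnly` respond to DD only; `nNull` are flat everywhere.
#' `nValidated` candidates carry planted degradome cleavage signals over
#' `nValidatedTargets` distinct transcripts; `nBaselineValidated` of the
#' validated miRNAs are also baseline-responsive; `nNovelUnion` members of the
#' DM union are planted as novel (genome-only) miRNAs, `nValidatedNovel` of
#' them validated.
#'
#' @slot presetName character scenario label.
#' @slot nNull,baselineUp,baselineDown,nSpecific,nShared,nRescue,nDdOnly
#'   integer planted set cardinalities (see above).
#' @slot nValidated,nValidatedTargets,nBaselineValidated,nNovelUnion,nValidatedNovel
#'   integer degradome/novelty cardinalities.
#' @slot replicates integer biological replicates per group-timepoint.
#' @slot timepoints integer vector of sampling times (h); the first is the
#'   pre-stress baseline.
#' @slot effectFold numeric fold-change of planted effects (up: x fold,
#'   down: /fold).
#' @slot noiseMode `"acceptance"` (exact deterministic counts) or
#'   `"realistic"` (negative-binomial sampling around expected counts).
#' @slot cv numeric within-group coefficient of variation (realistic mode).
#' @slot seed integer RNG seed; all outputs are byte-identical given the
#'   same config.
#' @slot readLength,umiLength integer read layout parameters (nt).
#' @slot adapter character 3' adapter sequence placed after the insert.
#' @slot duplicationRate numeric fraction of reads that are PCR duplicates.
#' @slot matureLengths integer range of planted mature miRNA lengths.
#' @slot loopLength integer hairpin loop size of planted precursors (nt).
#' @slot transcriptLength integer planted transcript length (nt).
#' @slot nDecoyTranscripts integer transcripts without planted sites.
#' @slot peakReads integer degradome reads planted at each cleavage site.
#' @slot backgroundSites integer single-read background positions per
#'   transcript in each degradome library.
#' @slot contaminantReads,junkReads,lowQualityReads integer per-library counts
#'   of planted contaminant-derived, adapter-less and low-quality reads.
#' @slot nullBase integer baseline molecule count of null miRNAs.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig", representation(
  presetName = "character",
  nNull = "integer",
  baselineUp = "integer",
  baselineDown = "integer",
  nSpecific = "integer",
  nShared = "integer",
  nRescue = "integer",
  nDdOnly = "integer",
  nValidated = "integer",
  nValidatedTargets = "integer",
  nBaselineValidated = "integer",
  nNovelUnion = "integer",
  nValidatedNovel = "integer",
  replicates = "integer",
  timepoints = "integer",
  effectFold = "numeric",
  noiseMode = "character",
  cv = "numeric",
  seed = "integer",
  readLength = "integer",
  umiLength = "integer",
  adapter = "character",
  duplicationRate = "numeric",
  matureLengths = "integer",
  loopLength = "integer",
  transcriptLength = "integer",
  nDecoyTranscripts = "integer",
  peakReads = "integer",
  backgroundSites = "integer",
  contaminantReads = "integer",
  junkReads = "integer",
  lowQualityReads = "integer",
  nullBase = "integer"
))

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  nm <- object@nSpecific + object@nShared  # DM union
  if (object@nRescue > object@nShared)
    msg <- c(msg, "nRescue must be <= nShared (rescue is a subset of shared)")
  if (object@nValidated > object@nSpecific)
    msg <- c(msg, "nValidated must be <= nSpecific (validated miRNAs are planted among DM-specific ones)")
  if (object@nBaselineValidated > min(object@baselineUp, object@nValidated))
    msg <- c(msg, "nBaselineValidated must be <= min(baselineUp, nValidated)")
  if (object@nValidated > 0L && object@nValidatedTargets < object@nValidated)
    msg <- c(msg, "nValidatedTargets must be >= nValidated (every validated miRNA needs a target)")
  if (object@nNovelUnion > nm)
    msg <- c(msg, "nNovelUnion must be <= DM union size (nSpecific + nShared)")
  if (object@nValidatedNovel > min(object@nNovelUnion, max(object@nValidated - object@nBaselineValidated, 0L)))
    msg <- c(msg, "nValidatedNovel must fit inside both the novel set and the non-baseline validated set")
  if (!object@noiseMode %in% c("acceptance", "realistic"))
    msg <- c(msg, "noiseMode must be 'acceptance' or 'realistic'")
  if (object@effectFold <= 1)
    msg <- c(msg, "effectFold must be > 1")
  if (object@duplicationRate < 0 || object@duplicationRate >= 1)
    msg <- c(msg, "duplicationRate must be in [0, 1)")
  if (length(object@timepoints) < 2L)
    msg <- c(msg, "need at least a baseline and one post-stress timepoint")
  if (object@replicates < 2L)
    msg <- c(msg, "need >= 2 replicates per group-timepoint for t-tests")
  if (object@seed < 0L)
    msg <- c(msg, "seed must be a non-negative integer")
  if (nchar(object@adapter) < 8L)
    msg <- c(msg, "adapter must be at least 8 nt (mismatch-tolerant seed region)")
  if (object@readLength < max(object@matureLengths) + 8L + object@umiLength)
    msg <- c(msg, "readLength too short for insert + adapter seed + UMI")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated scenario
#'
#' Records what the generator planted: per-miRNA set memberships and base
#' counts, per-pair degradome cleavage sites, and the expected molecule-count
#' matrix each library should yield after UMI deduplication.
#'
#' @slot mirnas data.frame with one row per planted miRNA (id, seq, group,
#'   set, direction, timepoint, base count, membership flags).
#' @slot pairs data.frame of planted degradome signals (mirna_id,
#'   transcript_id, site_start, cleavage_pos, library).
#' @slot expectedCounts integer matrix, miRNAs x libraries, of expected
#'   deduplicated molecule counts.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  mirnas = "data.frame",
  pairs = "data.frame",
  expectedCounts = "matrix"
))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (nrow(object@mirnas) != nrow(object@expectedCounts))
    msg <- c(msg, "expectedCounts must have one row per miRNA")
  if (nrow(object@pairs) &&
      !all(object@pairs$mirna_id %in% object@mirnas$id))
    msg <- c(msg, "every planted pair must reference a planted miRNA")
  if (length(msg)) msg else TRUE
})

#' Drought-memory candidate call set
#'
#' Result of the memory-candidate set logic: `shared` is the intersection of
#' the DM-vs-CG and DD-vs-CG unions, `specific` the DM-only remainder,
#' `rescue` the shared miRNAs that additionally differ between DM and DD, and
#' `candidates = specific + rescue`.  The baseline slots carry the DM_0h vs
#' CG_0h calls split by direction.
#'
#' @slot dmUnion,ddUnion,shared,specific,rescue,candidates character id sets.
#' @slot baselineUp,baselineDown character id sets (may be empty when no
#'   baseline contrast was supplied).
#' @exportClass MemoryCallSet
setClass("MemoryCallSet", representation(
  dmUnion = "character",
  ddUnion = "character",
  shared = "character",
  specific = "character",
  rescue = "character",
  candidates = "character",
  baselineUp = "character",
  baselineDown = "character"
))

setValidity("MemoryCallSet", function(object) {
  msg <- character(0)
  if (!setequal(object@shared, intersect(object@dmUnion, object@ddUnion)))
    msg <- c(msg, "shared must equal dmUnion intersect ddUnion")
  if (!setequal(object@specific, setdiff(object@dmUnion, object@shared)))
    msg <- c(msg, "specific must equal dmUnion minus shared")
  if (!all(object@rescue %in% object@shared))
    msg <- c(msg, "rescue must be a subset of shared")
  if (!setequal(object@candidates, union(object@specific, object@rescue)))
    msg <- c(msg, "candidates must equal specific union rescue")
  if (length(intersect(object@baselineUp, object@baselineDown)))
    msg <- c(msg, "baseline up and down sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' @describeIn MemoryCallSet-class candidate miRNA ids
#' @param x,object a `MemoryCallSet`
#' @export
candidates <- function(x) {
  stopifnot(is(x, "MemoryCallSet"))
  x@candidates
}

#' @describeIn MemoryCallSet-class DM-specific miRNA ids
#' @export
specificSet <- function(x) {
  stopifnot(is(x, "MemoryCallSet"))
  x@specific
}

#' @describeIn MemoryCallSet-class rescued shared miRNA ids
#' @export
rescueSet <- function(x) {
  stopifnot(is(x, "MemoryCallSet"))
  x@rescue
}

#' @describeIn MemoryCallSet-class shared (DM-and-DD responsive) miRNA ids
#' @export
sharedSet <- function(x) {
  stopifnot(is(x, "MemoryCallSet"))
  x@shared
}

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig '", object@presetName, "'\n", sep = "")
  cat("  groups CG/DD/DM x timepoints ",
      paste(object@timepoints, collapse = "/"), " h x ",
      object@replicates, " replicates\n", sep = "")
  cat("  planted: baseline ", object@baselineUp, " up + ",
      object@baselineDown, " down; DM union ",
      object@nSpecific + object@nShared, " (", object@nSpecific,
      " specific, ", object@nShared, " shared, ", object@nRescue,
      " rescue); DD union ", object@nDdOnly + object@nShared, "\n", sep = "")
  cat("  degradome: ", object@nValidated, " validated miRNAs, ",
      object@nValidatedTargets, " target transcripts\n", sep = "")
  cat("  noise mode ", object@noiseMode, ", effect fold ", object@effectFold,
      ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "MemoryCallSet", function(object) {
  cat("MemoryCallSet:",
      length(object@candidates), "candidates =",
      length(object@specific), "specific +",
      length(object@rescue), "rescue;",
      "DM union", length(object@dmUnion), ";",
      "DD union", length(object@ddUnion), ";",
      "shared", length(object@shared), "\n")
  if (length(object@baselineUp) || length(object@baselineDown))
    cat("  baseline:", length(object@baselineUp), "up,",
        length(object@baselineDown), "down\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@mirnas), "planted miRNAs,",
      nrow(object@pairs), "planted cleavage pairs,",
      ncol(object@expectedCounts), "libraries\n")
})
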