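## Scenario construction: planted set structure, directions, timepoints and
## base counts for the synthetic drought-memory study.

UP_BASE <- 25L  # molecule count of every up-regulated planted miRNA at baseline

#' Build a scenario configuration
#'
#' Creates a [ScenarioConfig-class] describing a synthetic three-group
#' (CG/DD/DM) by four-timepoint small RNA + degradome experiment with planted
#' differential structure.  Defaults give a small desk-scale scenario; use
#' [csMemoryScenario()] for the full `cs-memory-v1` preset.
#'
#' Planted up-regulated miRNAs carry a fixed base count and are raised
#' `effectFold`-fold in their target libraries; down-regulated ones are
#' lowered `effectFold`-fold.  Within every (group, timepoint) the generator
#' chooses the up/down split and down-regulated base counts so the summed
#' planted change is exactly zero, keeping all library totals equal - a
#' requirement for exact planted recovery after per-million normalization
#' (see the package vignette).
#'
#' @param presetName label for the scenario.
#' @param nNull,baselineUp,baselineDown,nSpecific,nShared,nRescue,nDdOnly
#'   planted set cardinalities (see [ScenarioConfig-class]).
#' @param nValidated,nValidatedTargets,nBaselineValidated,nNovelUnion,nValidatedNovel
#'   degradome/novelty cardinalities.
#' @param replicates replicates per group-timepoint.
#' @param timepoints sampling times in hours; the first is the pre-stress
#'   baseline, the remainder feed the DE unions.
#' @param effectFold fold-change of planted effects.
#' @param noiseMode `"acceptance"` for exact deterministic counts,
#'   `"realistic"` for negative-binomial sampling.
#' @param cv within-group coefficient of variation (realistic mode only).
#' @param seed integer RNG seed (< 2^31).
#' @param readLength,umiLength,adapter,duplicationRate read layout: reads are
#'   insert + 3' adapter + UMI, padded to `readLength`.
#' @param matureLengths range of mature miRNA lengths (nt).
#' @param loopLength hairpin loop length of planted precursors (nt).
#' @param transcriptLength planted transcript length (nt).
#' @param nDecoyTranscripts transcripts without planted cleavage sites.
#' @param peakReads degradome reads planted at each cleavage site.
#' @param backgroundSites single-read background positions per transcript.
#' @param contaminantReads,junkReads,lowQualityReads per-library counts of
#'   planted contaminant, adapter-less and low-quality reads.
#' @param nullBase base molecule count of null miRNAs.
#' @return A validated [ScenarioConfig-class] object.
#' @examples
#' cfg <- scenarioConfig(seed = 7L)
#' cfg
#' @export
scenarioConfig <- function(presetName = "desk-scale",
                           nNull = 24L,
                           baselineUp = 8L, baselineDown = 4L,
                           nSpecific = 12L, nShared = 6L, nRescue = 2L,
                           nDdOnly = 9L,
                           nValidated = 5L, nValidatedTargets = 11L,
                           nBaselineValidated = 2L,
                           nNovelUnion = 4L, nValidatedNovel = 1L,
                           replicates = 3L,
                           timepoints = c(0L, 1L, 6L, 12L),
                           effectFold = 4,
                           noiseMode = c("acceptance", "realistic"),
                           cv = 0.05,
                           seed = 1L,
                           readLength = 50L,
                           umiLength = 12L,
                           adapter = "TGGAATTCTCGG",
                           duplicationRate = 0.1,
                           matureLengths = c(20L, 24L),
                           loopLength = 8L,
                           transcriptLength = 300L,
                           nDecoyTranscripts = 12L,
                           peakReads = 5L,
                           backgroundSites = 3L,
                           contaminantReads = 120L,
                           junkReads = 20L,
                           lowQualityReads = 10L,
                           nullBase = 10L) {
  noiseMode <- match.arg(noiseMode)
  if (seed >= 2^31 - 1000) stop("seed must stay below 2^31 - 1000")
  new("ScenarioConfig",
      presetName = presetName,
      nNull = as.integer(nNull),
      baselineUp = as.integer(baselineUp),
      baselineDown = as.integer(baselineDown),
      nSpecific = as.integer(nSpecific),
      nShared = as.integer(nShared),
      nRescue = as.integer(nRescue),
      nDdOnly = as.integer(nDdOnly),
      nValidated = as.integer(nValidated),
      nValidatedTargets = as.integer(nValidatedTargets),
      nBaselineValidated = as.integer(nBaselineValidated),
      nNovelUnion = as.integer(nNovelUnion),
      nValidatedNovel = as.integer(nValidatedNovel),
      replicates = as.integer(replicates),
      timepoints = as.integer(timepoints),
      effectFold = as.numeric(effectFold),
      noiseMode = noiseMode,
      cv = as.numeric(cv),
      seed = as.integer(seed),
      readLength = as.integer(readLength),
      umiLength = as.integer(umiLength),
      adapter = toupper(adapter),
      duplicationRate = as.numeric(duplicationRate),
      matureLengths = as.integer(range(matureLengths)),
      loopLength = as.integer(loopLength),
      transcriptLength = as.integer(transcriptLength),
      nDecoyTranscripts = as.integer(nDecoyTranscripts),
      peakReads = as.integer(peakReads),
      backgroundSites = as.integer(backgroundSites),
      contaminantReads = as.integer(contaminantReads),
      junkReads = as.integer(junkReads),
      lowQualityReads = as.integer(lowQualityReads),
      nullBase = as.integer(nullBase))
}

#' The `cs-memory-v1` scenario preset
#'
#' Returns the full-size scenario whose planted cardinalities reproduce the
#' wheat drought-memory set structure: a baseline (DM_0h vs CG_0h) contrast
#' with 123 up- and 75 down-regulated miRNAs, a DM-vs-CG union of 243
#' (186 DM-specific + 57 shared with the DD-vs-CG union of 228), 9 shared
#' miRNAs rescued by the DM-vs-DD contrast (so 195 candidates), 64 validated
#' candidate miRNAs covering 445 target transcripts, 19 of the validated
#' miRNAs also baseline-responsive, and 115 novel miRNAs inside the DM union
#' (8 of them validated).
#'
#' @return A [ScenarioConfig-class] with a fixed documented seed (20101).
#' @examples
#' csMemoryScenario()
#' @export
csMemoryScenario <- function() {
  scenarioConfig(presetName = "cs-memory-v1",
                 nNull = 100L,
                 baselineUp = 123L, baselineDown = 75L,
                 nSpecific = 186L, nShared = 57L, nRescue = 9L,
                 nDdOnly = 171L,
                 nValidated = 64L, nValidatedTargets = 445L,
                 nBaselineValidated = 19L,
                 nNovelUnion = 115L, nValidatedNovel = 8L,
                 nDecoyTranscripts = 155L,
                 seed = 20101L)
}

## Choose an up/down split for a balance cell of n planted effects so that
## all counts stay integral: up base UP_BASE, down base f*UP_BASE*n_up/n_dn,
## with the down base divisible by f.  Scans from the most balanced split
## towards all-up, honouring nForcedUp members that must be up-regulated.
choose_split <- function(n, nForcedUp, fold) {
  n <- as.integer(n)
  if (n == 0L) return(list(nUp = 0L, nDown = 0L, downBase = 0L))
  if (abs(fold * UP_BASE - round(fold * UP_BASE)) > 1e-9)
    stop("effectFold * base count must be integral for exact planting")
  start <- min(n %/% 2L, n - nForcedUp)
  if (start < 1L)
    stop("cannot balance an effect cell of ", n,
         " planted miRNAs with ", nForcedUp, " forced up-regulated members")
  for (nDown in seq(start, 1L)) {
    nUp <- n - nDown
    d <- fold * UP_BASE * nUp / nDown
    if (abs(d - round(d)) < 1e-9 && abs(d / fold - round(d / fold)) < 1e-9) {
      return(list(nUp = nUp, nDown = nDown, downBase = as.integer(round(d))))
    }
  }
  stop("no integral balanced up/down split exists for a cell of ", n)
}

## Down base for a cell whose up/down counts are fixed (the baseline contrast).
fixed_cell_down_base <- function(nUp, nDown, fold) {
  if (nUp == 0L && nDown == 0L) return(0L)
  if (nUp == 0L || nDown == 0L)
    stop("a planted contrast needs both up- and down-regulated members ",
         "to keep library totals balanced")
  d <- fold * UP_BASE * nUp / nDown
  if (abs(d - round(d)) > 1e-9 || abs(d / fold - round(d / fold)) > 1e-9)
    stop("baseline up/down cardinalities (", nUp, "/", nDown,
         ") do not admit integral balanced counts at fold ", fold)
  as.integer(round(d))
}

## Assign members to post-stress timepoints as evenly as possible (members
## are pre-shuffled, so the allocation is uniform at the scenario seed).
## Cells are kept at >= 2 members (using fewer timepoints when the set is
## small) so every cell admits a balanced up/down split.
allocate_timepoints <- function(members, tps) {
  out <- setNames(rep(list(character(0)), length(tps)), as.character(tps))
  n <- length(members)
  if (n == 0L) return(out)
  if (n == 1L)
    stop("a planted DE set of size 1 cannot be balanced; use >= 2 members")
  nCells <- max(1L, min(length(tps), n %/% 2L))
  idx <- sort(rep(seq_len(nCells), length.out = n))
  for (k in unique(idx)) out[[as.character(tps[k])]] <- members[idx == k]
  out
}

## Internal: full planting plan.  Returns a data.frame with one row per
## planted miRNA: id stem, role, direction, timepoints, base count, class
## group and flags.  Sequence generation happens later in makeReference().
plan_scenario <- function(config) {
  fold <- config@effectFold
  tps <- config@timepoints
  post <- tps[-1L]
  nPost <- length(post)

  ids <- function(prefix, n) if (n > 0L) paste0(prefix, seq_len(n)) else character(0)
  specific <- ids("SP", config@nSpecific)
  sharedSync <- ids("SH", config@nShared - config@nRescue)
  rescue <- ids("RS", config@nRescue)
  ddOnly <- ids("DO", config@nDdOnly)
  baseOnly <- ids("BL", config@baselineUp + config@baselineDown -
                        config@nBaselineValidated)
  nulls <- ids("NU", config@nNull)

  ## validated miRNAs live among the DM-specific set; nBaselineValidated of
  ## them double as baseline up-regulated miRNAs.
  specShuffled <- sample(specific)
  dual <- specShuffled[seq_len(config@nBaselineValidated)]
  validatedExtra <- specShuffled[config@nBaselineValidated +
                                 seq_len(config@nValidated - config@nBaselineValidated)]
  validated <- c(dual, validatedExtra)

  ## novel (genome-only, gp4) members of the DM union; the dual baseline
  ## members and the non-novel validated remainder stay as known miRNAs.
  novelValidated <- sample(validatedExtra, config@nValidatedNovel)
  novelPool <- setdiff(c(specific, sharedSync, rescue), c(dual, validated))
  novelRest <- sample(novelPool, config@nNovelUnion - config@nValidatedNovel)
  novel <- c(novelValidated, novelRest)

  ## timepoint allocation (uniform at seed)
  tpSpecific <- allocate_timepoints(sample(specific), post)
  tpShared <- allocate_timepoints(sample(sharedSync), post)
  tpDdOnly <- allocate_timepoints(sample(ddOnly), post)
  rescueTpDm <- post[rep(seq_len(nPost), length.out = length(rescue))]
  rescueTpDd <- post[(rep(seq_len(nPost), length.out = length(rescue)) %% nPost) + 1L]

  rows <- list()
  add <- function(id, role, dir, tpDm, tpDd, base, baselineDir) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, role = role, direction = dir,
      tp_dm = tpDm, tp_dd = tpDd, base = base,
      baseline_dir = baselineDir, stringsAsFactors = FALSE)
  }

  ## DM cells per timepoint: specific members plus the DM side of rescue.
  for (t in as.character(post)) {
    membersSp <- tpSpecific[[t]]
    membersRs <- rescue[rescueTpDm == as.integer(t)]
    cell <- c(membersSp, membersRs)
    forced <- union(intersect(membersSp, dual), membersRs)
    if (length(cell)) {
      sp <- choose_split(length(cell), length(forced), fold)
      free <- sample(setdiff(cell, forced))
      ups <- c(forced, free[seq_len(sp$nUp - length(forced))])
      downs <- setdiff(cell, ups)
      for (m in ups) {
        role <- if (m %in% rescue) "rescue" else "specific"
        tdd <- if (role == "rescue") rescueTpDd[match(m, rescue)] else NA_integer_
        add(m, role, "up", as.integer(t), tdd, UP_BASE,
            if (m %in% dual) "up" else "none")
      }
      for (m in downs) {
        add(m, "specific", "down", as.integer(t), NA_integer_, sp$downBase, "none")
      }
    }
  }

  ## shared (synchronized) cells: same effect in DM_t and DD_t.
  for (t in as.character(post)) {
    cell <- tpShared[[t]]
    if (length(cell)) {
      sp <- choose_split(length(cell), 0L, fold)
      cell <- sample(cell)
      ups <- cell[seq_len(sp$nUp)]
      downs <- setdiff(cell, ups)
      for (m in ups) add(m, "shared", "up", as.integer(t), as.integer(t), UP_BASE, "none")
      for (m in downs) add(m, "shared", "down", as.integer(t), as.integer(t), sp$downBase, "none")
    }
  }

  ## DD cells: DD-only members plus the DD side of rescue (rescue already
  ## recorded; only its count contributes to the split here).
  for (t in as.character(post)) {
    membersDo <- tpDdOnly[[t]]
    membersRs <- rescue[rescueTpDd == as.integer(t)]
    cell <- c(membersDo, membersRs)
    if (length(cell)) {
      sp <- choose_split(length(cell), length(membersRs), fold)
      free <- sample(membersDo)
      ups <- free[seq_len(sp$nUp - length(membersRs))]
      downs <- setdiff(membersDo, ups)
      for (m in ups) add(m, "dd_only", "up", NA_integer_, as.integer(t), UP_BASE, "none")
      for (m in downs) add(m, "dd_only", "down", NA_integer_, as.integer(t), sp$downBase, "none")
    }
  }

  ## baseline-only members: the baseline cell holds baselineUp (including the
  ## dual validated members, already planted as specific ups) and baselineDown.
  downBase <- fixed_cell_down_base(config@baselineUp, config@baselineDown, fold)
  nBaseOnlyUp <- config@baselineUp - config@nBaselineValidated
  baseOnly <- sample(baseOnly)
  for (m in baseOnly[seq_len(nBaseOnlyUp)]) {
    add(m, "baseline_only", "none", NA_integer_, NA_integer_, UP_BASE, "up")
  }
  for (m in baseOnly[nBaseOnlyUp + seq_len(config@baselineDown)]) {
    add(m, "baseline_only", "none", NA_integer_, NA_integer_, downBase, "down")
  }

  for (m in nulls) {
    add(m, "null", "none", NA_integer_, NA_integer_, config@nullBase, "none")
  }

  plan <- do.call(rbind, rows)
  plan$validated <- plan$id %in% validated
  plan$novel <- plan$id %in% novel

  ## classification classes: novels are gp4; a few nulls exercise the other
  ## branches of the classification cascade; everything else is wheat-known.
  plan$group <- ifelse(plan$novel, "gp4", "gp1a")
  nSpecial <- min(3L, config@nNull %/% 8L)
  if (nSpecial > 0L) {
    pool <- plan$id[plan$role == "null"]
    special <- matrix(pool[seq_len(5L * nSpecial)], nrow = 5L, byrow = TRUE)
    plan$group[match(special[1L, ], plan$id)] <- "gp1b"
    plan$group[match(special[2L, ], plan$id)] <- "gp2a"
    plan$group[match(special[3L, ], plan$id)] <- "gp2b"
    plan$group[match(special[4L, ], plan$id)] <- "gp3"
    plan$group[match(special[5L, ], plan$id)] <- "variant"
  }
  rownames(plan) <- plan$id
  plan
}

## Expected deduplicated molecule counts for every library, from a plan.
expected_count_matrix <- function(plan, config) {
  tps <- config@timepoints
  tp0 <- tps[1L]
  fold <- config@effectFold
  ## DD libraries start at the first post-stress timepoint: before the
  ## stress is applied the direct-drought group is indistinguishable from
  ## the control, so the design has 33 libraries, not 36.
  libs <- character(0)
  for (g in c("CG", "DD", "DM")) {
    for (t in tps) {
      if (g == "DD" && t == tp0) next
      for (r in seq_len(config@replicates)) {
        libs <- c(libs, library_name(g, t, r))
      }
    }
  }
  meta <- parse_library_names(libs)
  m <- matrix(rep(plan$base, length(libs)), nrow = nrow(plan),
              dimnames = list(plan$id, libs))
  f_of <- function(dir) ifelse(dir == "up", fold, 1 / fold)
  for (j in seq_along(libs)) {
    g <- meta$group[j]; t <- meta$timepoint[j]
    if (g == "DM") {
      hit <- !is.na(plan$tp_dm) & plan$tp_dm == t & plan$role %in% c("specific", "shared", "rescue")
      m[hit, j] <- plan$base[hit] * f_of(plan$direction[hit])
      if (t == tp0) {
        bl <- plan$baseline_dir != "none"
        m[bl, j] <- plan$base[bl] * f_of(plan$baseline_dir[bl])
      }
    } else if (g == "DD") {
      hit <- !is.na(plan$tp_dd) & plan$tp_dd == t & plan$role %in% c("shared", "dd_only")
      m[hit, j] <- plan$base[hit] * f_of(plan$direction[hit])
      rs <- !is.na(plan$tp_dd) & plan$tp_dd == t & plan$role == "rescue"
      m[rs, j] <- plan$base[rs] * fold  # rescue is up-regulated on the DD side
    }
  }
  if (max(abs(m - round(m))) > 1e-9)
    stop("planted counts are not integral; check effectFold and cardinalities")
  storage.mode(m) <- "integer"
  m
}
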