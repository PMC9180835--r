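---
title: "Identifying drought memory-related miRNAs from small RNA and degradome sequencing"
author: "memomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying drought memory-related miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memomiR)
```

## The problem

Plants that survive a mild drought often respond faster or more strongly to a
later, harsher one — a phenomenon called *drought (stress) memory*.  One layer
of this memory is post-transcriptional: microRNAs whose response to renewed
stress differs between *primed* plants (drought memory group, DM) and plants
meeting drought for the first time (direct drought, DD), both measured against
an unstressed control (CG).  memomiR implements the complete inference chain
for such a design:

1. **Preprocessing** of UMI-labelled small RNA reads: adapter trimming, UMI
   extraction, PCR-duplicate removal, tag collapsing, contaminant filtering.
2. **Cataloguing** of unique 18–25 nt tags into known (gp1a), precursor-variant
   (gp1b), conserved (gp2a/gp2b/gp3) and novel (gp4) miRNAs, with hairpin
   prediction and ACGT101-style variant naming.
3. **Expression analysis**: per-million normalization, high/medium/low
   binning, pairwise t-tests and one-way ANOVA.
4. **Memory-candidate selection** by set logic over the DE contrasts.
5. **Degradome (PARE) validation** of miRNA targets through T-plot
   categories and plant-miRNA duplex scoring.
6. **Hypergeometric over-representation** of validated targets and the
   miRNA–gene–term association export.

Because real libraries of this design are deposited as raw archives, the
package ships a first-class synthetic generator whose preset `cs-memory-v1`
plants the full reference set structure of the emulated wheat study (198 baseline calls with 75 down,
DM union 243, DD union 228, 57 shared, 9 rescued, 195 candidates, 64
degradome-validated miRNAs over 445 transcripts, 19 of them also
baseline-responsive, 115 novel miRNAs in the DM union).  Every stage is
therefore testable end to end against known truth.

## The memory-candidate set logic

For each post-stress timepoint $t \in \{1, 6, 12\}$ h the pairwise contrasts
DM$_t$ vs CG$_t$, DD$_t$ vs CG$_t$ and DM$_t$ vs DD$_t$ are tested per miRNA
(two-sided pooled-variance Student's *t*, $p < 0.05$, no multiplicity
correction — a BH option exists but is off by default to match the plain
threshold convention).  With

$$M = \bigcup_t \mathrm{DE}(\mathrm{DM}_t, \mathrm{CG}_t), \quad
  D = \bigcup_t \mathrm{DE}(\mathrm{DD}_t, \mathrm{CG}_t), \quad
  X = \bigcup_t \mathrm{DE}(\mathrm{DM}_t, \mathrm{DD}_t),$$

the calls are: shared $S = M \cap D$; memory-specific $M \setminus S$;
rescued $R = S \cap X$ (shared responders that nevertheless behave
differently in primed plants); candidates $= (M \setminus S) \cup R$, so
$|{\rm candidates}| = |M| - |S| + |R|$ always.

```{r}
cs <- selectMemoryCandidates(dmUnion = sprintf("m%03d", 1:243),
                             ddUnion = c(sprintf("m%03d", 1:57),
                                         sprintf("d%03d", 1:171)),
                             dmVsDdUnion = sprintf("m%03d", 1:9))
cs
```

Two conventions were genuinely open and are fixed here: the DM-vs-DD union
runs over the three post-stress timepoints (symmetrically with the other two
unions), and the 0 h timepoint is excluded from all unions — it feeds only
the baseline contrast DM$_0$ vs CG$_0$, whose calls are carried along split
by direction.  The design has 33 libraries, not 36: before stress the DD
group is indistinguishable from the control, so DD$_0$ libraries do not
exist.

## Differential expression on deterministic counts

Counts are normalized per library to one million (`normalizeCounts`),
the plainest member of the global-normalization family and the only one
that needs no tuning choices.
Expression levels split at 10 reads and at the dataset mean: low $\le 10 <$
medium $\le$ mean $<$ high, with the boundary value 10 assigned to low.

The *t*/ANOVA implementations add one convention that matters on synthetic
data: when both groups have exactly zero variance, the statistic is
undefined, and the p-value is set to 1 for equal means and 0 for unequal
means.  On deterministic acceptance-mode counts this makes planted-effect
recovery exact.  `log2fc` uses a pseudocount of 1; direction is defined by
the strict ordering of group means.

## The synthetic generator

`scenarioConfig()` fixes the design: three groups, timepoints 0/1/6/12 h,
three replicates, reads laid out *insert + 3' adapter + 12 nt UMI*, padded
to 50 nt.  The default adapter is the first 12 nt of the TruSeq small RNA 3'
adapter (`TGGAATTCTCGG`): a 25 nt insert plus the full 21 nt adapter plus a
12 nt UMI would not fit a 50 nt read, and 12 nt (with a one-mismatch
8-mer seed) is ample for unambiguous location.  Every planted tag is
screened so the composed read trims back to exactly the planted insert, is
not low-complexity, and is not a substring of any contaminant or transcript
record.  Each library also receives contaminant-derived inserts,
adapter-less junk reads and low-quality reads so the rejection paths are
exercised; every molecule gets a unique UMI and duplicates (same insert +
UMI) are injected at the configured rate (default 0.1).

**Balanced totals.**  Per-million normalization rescales each library by its
total, so a planted effect that changed a library's total would leak into
every null miRNA of that library.  The generator therefore solves the
up/down base counts inside every (group, timepoint) cell so the net planted
change is exactly zero: up-regulated miRNAs carry a base count of 25 (raised
fourfold), and the down-regulated base count is $f \cdot 25 \cdot
n_{up}/n_{down}$ with the split chosen so that both it and its quarter are
integers (for the baseline cell's fixed 123 up / 75 down this gives 164).
Shared miRNAs change identically in DM and DD at their timepoint; rescued
miRNAs rise in DM at one timepoint and in DD at another, so they sit in both
unions yet differ between DM and DD.  Validated miRNAs are planted among the
DM-specific set, with the 19 baseline-validated ones up-regulated in both
cells they occupy.

**Noise modes.**  In `"acceptance"` mode counts are exactly the expected
values in every replicate: nulls are flat (p = 1 by the degenerate rule) and
planted effects are exact fold changes (p = 0), so the planted cardinalities
are reproduced exactly — the property the preset exists for.  In
`"realistic"` mode counts are negative-binomially distributed around the
expected values with coefficient of variation `cv` (default 0.05), and
recovery is approximate: at a 5% type-I rate a few hundred nulls would
otherwise scatter into the unions, which is precisely why fixed reference counts
cannot be matched exactly under sampling noise.

**What the generator does not emulate**: real wheat genome content and
homology structure, sequencing-error profiles beyond clean reads,
quality-score variation, isomiR abundance spectra, or degradome noise with
structure (background tags are uniform singletons).  Passing tests therefore
demonstrate the correctness of the inference chain's logic, not robustness
to every artefact of real libraries.

## Hairpin prediction and the catalog

Windows are folded by Nussinov maximum base pairing (pairs A:U, G:C and the
G:U wobble; minimum loop 3 nt).  Maximum matching rather than free-energy
minimization keeps the fold deterministic and dependency-free; the traceback
prefers the outermost admissible pair, so perfect inverted repeats are
recovered as clean stems.  A window passes as a miRNA hairpin when the
mature lies entirely on one arm, at least 60% of its bases are paired, the
innermost loop spans at least 3 nt, and at least 45% of window bases are
paired.  A mature straddling the loop fails the arm condition by definition.

The classification cascade (gp1a → gp1b → gp2a/gp2b/gp3 → gp4) matches tags
against wheat matures with a tolerance of at most 2 substitutions and 2 nt
of end trimming/extension — mirroring variant ids like `_L-2` or
`_1ss21GA` — and maps them into precursors (2 mismatches allowed) or genome
windows (exact).  The gp2a/gp2b split follows the hairpin outcome of the
genome window; the gp-group labels come from the ACGT101 naming scheme,
whose precise internal definitions are proprietary, so this split is a
documented compatibility convention, not a claim of exact equivalence.  Novel (gp4) entries are named `PC-<arm>-<rank>` by the
lexicographic rank of the tag among novel tags, which is reproducible for
any fixed tag set.

## Degradome validation

Degradome reads mark uncapped 5' ends; a slicer-cleaved target shows a pileup
exactly opposite miRNA nucleotide 10.  `mapTags` assigns each read to every
transcript position matching its first 20 nt exactly and accumulates 5'-end
profiles.  Duplex scoring is the classic plant scheme — match 0, G:U wobble
0.5, mismatch 1, doubled opposite miRNA positions 2–13 — ungapped, with
default threshold 4.0 (CleaveLand-compatible conventions
with its conventional plant defaults).  T-plot
categories: 0 unique maximum (>1 read), 1 tied maximum, 2 above the mean of
covered positions, 3 at or below it, 4 single read.  The mean uses covered
positions only (an option switches to all positions).  Validation keeps
sites with category ≤ 2 ("categories < 3") and more than one read; the
alternative convention groups "categories 0–3", so the threshold is a
configurable argument rather than a constant.  `validateTargets` drives site
discovery from the peak positions (count > 1, category within threshold) and
scores the unique window placing miRNA position 10 on the peak — this is
equivalent to filtering the full sliding-window scan, because retained sites
must be peaks, and is what makes validating 195 candidates against hundreds
of transcripts fast.

## Enrichment

Validated target genes are tested per term with the hypergeometric upper
tail $P(X \ge k)$.  The population is every gene with at least one
annotation in the supplied map — the standard over-representation practice;
an explicit `universe`
argument overrides it.  No multiplicity correction is applied by default,
again matching the plain $p < 0.05$ usage; `adjust = "BH"` is available.

## Problem sizes and determinism

The preset `cs-memory-v1` carries 693 planted miRNAs across 33 libraries of
roughly 45–50k molecules each (about 1.6 M reads in total), 620 transcripts
of 300 nt and three pooled degradome libraries; a full `runPipeline` takes
under two minutes on one core, and the desk-scale default scenario a few
seconds.  Library depth is a free parameter of the design (only
non-redundant tag counts being fixed by the emulated design), and the preset uses the smallest
integral counts compatible with balanced totals.  All randomness flows from
the single scenario seed (the preset fixes seed 20101); identical
configurations produce byte-identical FASTA/FASTQ/TSV outputs and identical
run reports.

## Known limitations

- Contaminant matching is exact substring search, adequate for synthetic
  decoys but not a replacement for alignment against full Rfam/Repbase.
- The duplex scorer is ungapped; bulged plant target sites would need a
  gapped aligner.
- UMI deduplication is exact-match; directional-network UMI error
  correction is out of scope.
- Nussinov maximum pairing over-pairs relative to thermodynamic folding;
  the criteria (60%/45%/loop ≥ 3) are calibrated for it, and an
  energy-based backend could be substituted behind `predictHairpin`.
- The *t*-test is applied per miRNA without dispersion shrinkage; on three
  replicates of real data a negative-binomial framework would be more
  powerful.
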