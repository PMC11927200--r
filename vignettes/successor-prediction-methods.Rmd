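---
title: "Extrapolating per-site physicochemical trends along ancestral lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrapolating per-site physicochemical trends along ancestral lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssp)
```

## The idea

Ancestral sequence reconstruction (ASR) infers the protein sequences that sat
at the internal nodes of a phylogenetic tree. Reading the chain of nodes from
the root down to a modern target protein — the *main path* — gives, for every
alignment column, an ordered series of residues through evolutionary time.
If selection has been pushing a position in a consistent physicochemical
direction (heavier, more hydrophobic, more basic, ...), that push is visible
as a monotone trend when the residues are projected through a numeric
descriptor scale. This package fits that trend per site and per descriptor,
extrapolates it one evolutionary step beyond the target, and converts the
extrapolated descriptor value back into a concrete amino acid: a candidate
*successor* substitution that continues the lineage's historical drift, in
the spirit of what a round of laboratory evolution might select.

The unit of analysis is the triple (site, descriptor scale, tree). Results
are scored, ranked, averaged across trees, and bundled into agreement tiers
before reporting.

## Descriptor scales

Nine AAindex scales are embedded (`load_default_indices()`), chosen to cover
complementary physicochemical axes with little redundancy: molecular weight
(FASG760101) and residue volume (GOLD730102) for size, melting point
(FASG760102), hydrophobicity (WOLR790101), average flexibility (BHAR880101),
transfer free energy to the surface (BULH740101), localized electrical
effect (FAUJ880108), polarity (ZIMJ680103), and isoelectric point
(ZIMJ680104). Values are kept in raw AAindex units; every regression runs
within a single scale, so units never mix and no rescaling is needed.
`descriptor_correlation()` reproduces the redundancy diagnostic over the 20
residue values per scale; the two size-like scales are the only strongly
correlated pair and both are kept for their differing treatment of
individual residues.

Each scale is categorised (Size, MeltingPoint, Hydrophobicity, Flexibility,
TransferEnergy, ElectricEffect, Polarity, IsoelectricPoint) for bundled
reporting. The two size scales share the Size category, reflecting that they
measure the same axis two ways.

## From column to prediction

For an alignment column along the main path:

1. **Trajectory.** Residues are read root-first; gap characters are dropped
   (they carry no descriptor value) while surviving nodes keep their
   cumulative branch-length distances. Maximal runs of one residue collapse
   into *groups*; only boundaries between groups count as *transitions*, so
   a residue that persists across many ancestors is not over-weighted.
2. **Eligibility.** Sites with fewer than three transitions are excluded
   (the boundary is inclusive: exactly three is eligible). Transitions are
   counted after gap removal. A site where the target has a gap is also
   excluded.
3. **Featurisation.** One point per group: x = cumulative distance at the
   group's first node (substitutions/site), y = the group residue's scale
   value. Sample weights implement a recency emphasis,
   w_i = 1 + d_i / d_max, so the most recent group counts up to twice the
   root. The weighting is the mildest monotone scheme that realises
   "weighted by evolutionary distance from the root" without inventing
   magnitudes; `ssp_config(weighting = "uniform")` disables it.
4. **Normalisation.** The x-axis is divided by the trajectory's transition
   count before fitting (`normalize = TRUE` by default), so slope magnitudes
   are comparable between volatile and quiet sites. The extrapolation point
   is rescaled identically, which leaves the predicted value unchanged —
   only the slope's scale differs. Applying the normalisation to x (rather
   than to weights or to the final score) was a genuinely open choice; it is
   the only variant that affects cross-site slope comparability without
   touching the score semantics, and it is recorded in the output
   configuration echo.
5. **Trend fit and inversion.** Weighted least squares of y on x
   (`stats::lm.wfit`), extrapolated at x_last + step, where step is the
   mean branch length over *all* edges of the main path (`mean_step()`).
   The predicted value is mapped to the nearest residue on the scale
   (`nearest_residue()`; ties break alphabetically, deterministically).
   Fits with all x identical are degenerate and skipped. Predictions equal
   to the target's current residue are dropped from mutation output by
   default (`drop_self`), since reported results are substitutions.

## Scores

* **Sequentiality** (0–100): percentage of group transitions whose
  descriptor change has the same sign as the fitted slope. A perfectly
  monotone trajectory scores 100. With a zero slope only zero-change
  transitions count as consistent.
* **Fluctuation** (0–1]: distinct residues ÷ number of groups. 1 means the
  trajectory never revisits a residue; lower values flag oscillation.
* **Break trend**: whether the most recent transition's descriptor change
  opposes the fitted slope — the trend may already have reversed, making
  extrapolation suspect. Zero-change transitions are consistent (no break).
  The phrase "penultimate transition" admits two readings; the default
  inspects the transition between the last two groups, and
  `break_mode = "penultimate"` inspects the one before it. With a flat
  (zero-slope) trend any non-zero change at the inspected transition counts
  as a break.

Ranking is a total order: no-break first, then sequentiality descending,
fluctuation descending, and a deterministic (position, accession) tie-break.

## Aggregation and bundling

Predictions are expressed in 1-based positions on the ungapped target
sequence so they align across trees built from different sequence files;
tuples sharing (position, wild type, successor, scale) are merged with
arithmetically averaged scores and a supporting-tree count. A wild-type
mismatch at one position across trees indicates inconsistent alignments and
is an error, not a silent merge.

Bundling tiers: a mutation supported by ≥ 2 scales is a **MAP** (mutation
agreeing prediction) and is consolidated into one record; single-scale
mutations at a site where scales disagree on the residue are **SAP** (site
agreeing); a lone mutation at a site is a plain **Prediction**. A mutation
can be mutation-agreeing at a site that also carries conflicting residues;
MAP wins for that mutation while the conflicting singletons stay SAP, which
matches how multi-tier sites behave in practice.

## Dataset preparation

`filter_homologs()` applies the curation windows (identity to target within
30–90%, length within 80–120%, both inclusive): near-identical homologs
carry no trend information and distant ones align unreliably.
`pairwise_identity()` defaults to matches ÷ alignment length including
internal gaps over a global alignment; a shorter-sequence denominator is
available. `build_sequence_files()` implements the partitioning rules: one
sequence per cluster per file, the target in every file (appended if its
cluster's draw picked someone else, so a file can be one over nominal size),
within-cluster draws without replacement until exhausted, then the pool
reshuffles. The default file count is the size of the largest cluster, the
smallest number that exhausts every pool; with 150 singleton clusters each
file carries 150 sequences. Selection is seeded and reruns are
byte-identical. Search, clustering, alignment, tree inference and the
ancestral reconstruction itself are consumed as inputs (Newick with
labelled internal nodes plus aligned node FASTA), not recomputed.

## The synthetic generator, and what it does not show

`make_history()` builds a caterpillar tree whose spine is the main path,
with aligned gap-free node sequences. At planted sites the residue chain
walks a ladder of amino acids whose values on the chosen scale are strictly
monotone, with an exact number of transitions; the top quarter of the
ladder is left unused so a successor residue always exists beyond the
target. Optional Gaussian noise (in scale units) perturbs the intended
values before they snap back to residues. Background sites are constant by
default (hence ineligible — a clean negative control) or i.i.d. random.
Branch lengths are uniform on 0.05–0.3 substitutions/site, a typical range
for the deep, divergent homolog sets this kind of analysis uses.

The generator emulates the *geometry* the predictor consumes — monotone
descriptor drift down a lineage — not the process that produces real data:
there is no substitution-model simulation, no reconstruction uncertainty,
no gaps, no alignment error, and descriptor trends in real proteins are
never exactly linear. Passing tests therefore demonstrate that the
machinery recovers what it is defined to recover (planted direction and
slope, score semantics, determinism), not that real lineages contain such
trends.

Test problem sizes are deliberately small — paths of 8–12 nodes, tens of
columns, 200 noisy replicates at one site — which exercises every code path
in seconds while keeping the planted-recovery statistics stable.

## Enrichment evaluation

`compute_aac()` is the validation statistic for deep-mutational-scanning
style data: the arithmetic mean of enrichment values across all conditions
(e.g. antibiotics × concentrations), optionally restricted to a mutation
subset. Wild-type-like fitness sits near 1; a predicted set with AAC above
the full-table mean indicates the predictor preferentially proposes
enriched variants. `read_enrichment()` accepts a declarative column mapping
so differently laid-out tables can be consumed without editing.
`make_enrichment_table()` generates noiseless tables with closed-form AAC
for testing, and log-normal noise otherwise.

## Known limitations

* A linear trend in one descriptor is a deliberately simple model; sites
  under epistatic or oscillating selection violate it (the fluctuation and
  break-trend scores exist to flag exactly those).
* Trend direction is taken from the fitted slope's sign; very flat slopes
  make sequentiality and break-trend brittle, though such sites rarely
  survive self-prediction filtering.
* The method inherits every upstream artefact: alignment errors,
  reconstruction bias, and rooting mistakes all shift trajectories.
* Predictions require a deep homolog set; proteins with few homologs give
  short main paths with too few transitions for any site to be eligible.
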