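---
title: "Redesigning tandem-repeat coding sequences with silent mutations"
author: "trdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redesigning tandem-repeat coding sequences with silent mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdesign)
```

## The problem

Proteins built from tandem repeats (TRs) — near-identical contiguous
duplications of an amino-acid motif — are encoded by near-identical DNA.
That repetition defeats the PCR-based methods protein engineers rely on:
assembly PCR (aPCR) primers mis-prime across repeat copies, and
site-directed mutagenesis cannot address one copy without touching the
other.  Because the genetic code is degenerate (every residue except Met
and Trp has 2–6 codons), a TR gene can be rewritten with *silent*
substitutions so the protein is untouched while the repeat copies become
mutually dissimilar DNA.  `trdesign` implements that rewrite as a
deterministic, fully offline pipeline, and emits the validated
oligonucleotide set needed to build the gene by aPCR.

The bundled worked example is a single-chain repressor made of two copies
of the LacI DNA-binding domain (residues 1–89), in which residues 1–29 and
60–89 of each copy are redesigned while 30–59 stays wild type.

## The pipeline

1. **Segmentation** (`segmentRegion`): each redesign region is cut into
   contiguous peptide segments of 5–7 residues.  Short segments keep the
   synonymous search space enumerable (at most a few thousand sequences
   per segment) and match half the length of a typical aPCR primer.  An
   explicit partition table can override the automatic
   equal-as-possible partitioner.
2. **Enumeration** (`enumerateSynonymous`): every synonymous DNA
   realization of each segment is generated.  Codon lists are
   alphabetical, and enumeration is lexicographic in the per-residue
   codon list positions, so combination labels are stable across runs.
3. **Thermodynamic profiling and pruning** (`thermoProfile`,
   `filterCombinations`): each candidate F is scored with four two-state
   melting temperatures — self-dimer `t_ff` (F·F), reverse-complement
   self-dimer `t_rr` (R·R), the intended assembly duplex `t_fr` (F·R),
   and, when a wild-type CDS is supplied, cross-hybridization with the
   wild type `t_wt`.  Candidates are kept when `t_ff`, `t_rr`, `t_wt`
   fall at or below their 50th-percentile cutoffs (resolved per segment)
   and `t_fr` lies at or above its 10th-percentile cutoff, i.e. weak
   self-structure, weak wild-type cross-talk, strong intended duplex.
4. **Similarity grouping** (`identityMatrix`, `assignGroups`,
   `sampleGroups`): survivors are clustered by ungapped percent identity
   (join at ≥ 80%) refined by a cosine comparison (≥ 0.9975) of their
   identity profiles; four groups per segment are carried forward.
5. **Pair joining and path search** (`joinAdjacent`, `filterPairs`,
   `dfsPaths`): adjacent-segment combinations are concatenated, scored
   again, pruned (top 20% homodimerizers out; joined `t_fr` must reach a
   fixed 80 °C floor), and a depth-first search assembles up to 100
   full-length paths in which *every duplicated segment uses combinations
   from different similarity groups in different repeat copies* — the
   constraint that actually de-duplicates the repeat DNA.
6. **Rendering, evaluation and primers** (`renderTemplate`,
   `evaluateTemplate`, `partitionPrimers`, `validateAssembly`): the first
   path under the seeded search order becomes the template (all paths are
   kept for audit); the template is re-translated, annotated, scored
   per segment, and tiled with alternating-strand primers (≤ 44 nt,
   G/C 3′ termini, junction overlaps reaching 64 °C) whose all-vs-all
   cross-hybridization matrix is checked (adjacent pairs ≥ 70 °C,
   non-adjacent pairs ≤ 50 °C, no stable hairpins at 72 °C).

## The hybridization model

The engine is a local nearest-neighbor two-state calculator, replacing a
web service so the pipeline runs offline and deterministically.

* **Duplexes** (`duplexMFE`): the optimal antiparallel intermolecular
  pairing of two strands is found by dynamic programming over
  Watson–Crick stacks with bulge and internal-loop penalties (no
  mismatched pairs, no intramolecular structure inside the duplex, no
  multiloops — two-state hybridization semantics).  Stack ΔH/ΔS are the
  unified nearest-neighbor DNA set, shipped as an editable TSV, with
  per-end initiation terms that depend on the terminal base pair.
* **Melting temperature** (`twoStateTm`): \(T_m = 1000\,\Delta H /
  (\Delta S + R \ln (C_T/f))\), with \(f = 1\) plus a symmetry entropy
  for self-complementary duplexes and \(f = 4\) otherwise, then
  converted to °C.  Defaults are 1 M monovalent salt (where the entropic
  salt correction vanishes) and \(C_T = 1\) µM total strands; both are
  configurable on `nnParameters()`.
* **Hairpins** (`foldDG`): single-strand folding free energy from the
  same stack table, stems closed by loops of ≥ 3 nt.  Loop penalties
  (hairpin, bulge, internal) are tabulated as ΔG at 37 °C and treated as
  purely entropic, so ΔG(T) scales linearly in temperature; sizes beyond
  the table are extrapolated logarithmically.
* **Conventions**: temperatures are Kelvin internally and Celsius at all
  interfaces.  When no Watson–Crick pairing exists at all, Tm is
  reported as the sentinel −273.15 °C with a flag, so percentile filters
  remain monotone; a strand with no possible ≥ 3-nt-loop hairpin reports
  the unfolded reference ΔG = 0 and a "linear" flag.  Structures with
  unfavorable (positive) ΔG are still reported, because downstream
  filters need to *rank* candidates, not only accept them.

### Calibration

Published two-state predictions depend on unstated buffer, strand
concentration and parameter-version choices.  Rather than guess,
`calibrateTmOffset()` fits one additive constant — the median residual of
the engine's perfect-duplex Tm against a reference primer table — and
applies it to every reported Tm.  For the bundled repressor fixture the
reference set is the nine flanking primers, chosen because they lie
outside the redesign space; the fitted offset and per-primer residuals
are attached to the returned parameter object, so the calibration is a
reported constant, never a hidden per-sequence adjustment.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minSegLen`, `maxSegLen` | 5, 7 residues | segment length window |
| `qFF`, `qRR`, `qWT` | 0.50 | keep-at-or-below percentile for self-dimers and wild-type cross-talk |
| `qFR` | 0.10 | keep-at-or-above percentile for the intended duplex |
| `idCut`, `cosCut` | 80%, 0.9975 | similarity-group join thresholds |
| `kGroups` | 4 | groups carried per segment |
| `qHomo` | 0.20 | top homodimer fraction discarded at junctions |
| `tFrMin` | 80 °C | fixed joined-duplex floor |
| `nPaths` | 100 | design paths collected |
| `primerMaxLen` | 44 nt | primer length cap |
| `overlapTmMin` | 64 °C | junction-overlap duplex Tm floor |
| `adjacentMin`, `offtargetMax` | 70 °C, 50 °C | cross-hybridization acceptance |
| `sodium`, `ct` | 1 M, 1 µM | reaction conditions |

Two documented ambiguities are surfaced rather than resolved silently:
the intended-duplex percentile is 0.10 by default with the alternative
reported operating point 0.20 available as `designConfig(preset =
"results")`; and the junction list is all consecutive segment pairs by
default, with `junctionExclusions` available to reproduce runs that
omitted specific junctions.

## Design choices that were genuinely open

* **Percentiles** are linear interpolation between order statistics
  (`stats::quantile` type 7); every resolved cutoff is written to the run
  report so a threshold table can be regenerated from any run.
* **Cosine profile vectors** are the full identity-matrix row with the
  vector's own diagonal entry removed; the mutual entry of the two
  compared rows is retained.
* **Grouping closure** is transitive (connected components of the join
  graph) — the cheapest reading consistent with pairwise assignment; the
  strategy is isolated behind `assignGroups` and swappable.
* **Group ids** are the smallest member index, making the partition
  deterministic and order-insensitive.
* **Path selection**: the template is the first valid path under the
  seeded search order (survivors visited by descending `t_fr`, ties
  shuffled by the seed); all collected paths are emitted for audit.
* **"No duplex" sentinel** (−273.15 °C) keeps order statistics finite
  and filters monotone; it is flagged, never silently mixed with real
  temperatures.
* **3′ termini**: primer boundaries are adjusted by at most 3 nt to land
  a G or C at every 3′ end; an A/T-only stretch that cannot satisfy this
  raises an error naming the offending window.
* A single integer seed drives the only two stochastic steps (group
  sampling, DFS tie order), so a full run is byte-reproducible.

## The synthetic fixture generator

`generateToyTR()` emulates the worst case the method must solve: a random
peptide unit (draws dominated by the non-degenerate Met/Trp are
rejected), duplicated in tandem, with a back-translated "wild-type" CDS
built from first-listed codons — i.e. 100% DNA identity between repeat
copies before redesign.  It does **not** emulate codon-usage bias,
GC-skewed natural genes, or repeat copies that have already diverged;
passing tests on these fixtures therefore demonstrate the combinatorial
and thermodynamic machinery, not performance on any particular genome's
codon statistics.  The test suite runs the full pipeline on 10-residue
duplicated units (two segments per copy, a few hundred candidates per
segment), a size chosen so an end-to-end run takes seconds while still
exercising every stage, including the cross-copy group constraint.

## Known limitations

* The duplex model excludes mismatched base pairs, dangling ends and
  coaxial terms.  One visible consequence: the self-dimer optima of a
  strand and of its reverse complement are related by strand reversal,
  so the model's `t_ff` and `t_rr` coincide exactly, whereas engines
  with mismatch/dangle terms report them separately.  The filters only
  consume the two jointly (both must fall below their cutoffs), so the
  ranking behavior is preserved.
* Two-state means two-state: no partition-function melting curves, no
  multi-state ensembles, no RNA parameters.
* Codon-usage frequency is deliberately not a pruning criterion; the
  candidate data frames are exposed so a usage-based filter can be
  applied between enumeration and grouping if an expression host
  demands it.
* Absolute Tm agreement with any particular web service depends on its
  unstated settings; after the one-constant calibration the engine is
  intended for *ranking and envelope checks*, which is all the design
  procedure requires.

## Reproducing a design

```{r example, eval = FALSE}
toy <- generateToyTR(peptideLen = 10, nRepeats = 2, seed = 7)
cfg <- designConfig(tFrMin = 55, overlapTmMin = 55, adjacentMin = 55,
                    tFrEnvelope = c(40, 95), seed = 7)
run <- runDesign(toy$protein, list(c(1, 10)), nRepeats = 2,
                 wtCds = toy$wtCds, config = cfg)
identityReport(run$template)   # repeat-vs-repeat and vs-wild-type %
primers(run$primerSet)         # the order sheet
run$validation$pass
```

The repository's `scripts/acceptance.R` recomputes the calibrated
thermodynamic envelope of the bundled repressor primer set from scratch;
see the README for how to run it.
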