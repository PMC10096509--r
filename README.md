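# trdesign

Silent-mutation redesign of tandem-repeat coding sequences for assembly
PCR.

## The problem

Proteins containing tandem repeats (TRs) — near-identical contiguous
duplications of a sequence motif — are encoded by near-identical DNA,
which defeats the PCR techniques protein engineers depend on: assembly
PCR (aPCR) primers mis-prime across repeat copies, and site-directed
mutagenesis cannot target one copy selectively.  Because the genetic code
is degenerate, the same protein can be encoded by DNA rewritten with
*silent* codon substitutions so that the repeat copies become mutually
dissimilar.  `trdesign` performs that rewrite and emits a validated
oligonucleotide primer set, for anyone building or mutagenizing
TR-containing constructs (single-chain repressors, ankyrin/TPR-style
scaffolds, coiled-coils) without resorting to full gene synthesis.

## The method

For each repeat region the pipeline:

1. dissects the peptide into contiguous 5–7-residue segments;
2. enumerates **every** synonymous codon combination per segment;
3. scores each candidate F with a nearest-neighbor two-state
   hybridization engine: self-dimer melting temperatures T<sub>FF</sub>
   (F·F) and T<sub>RR</sub> (R·R, R = reverse complement), the intended
   assembly duplex T<sub>FR</sub> (F·R), and cross-hybridization with
   the wild-type gene T<sub>WT</sub>; the two-state temperature is
   T<sub>m</sub> = 1000·ΔH / (ΔS + R·ln(C<sub>T</sub>/f)), with ΔH/ΔS
   accumulated over the minimum-free-energy duplex found by dynamic
   programming over Watson–Crick stacks with bulge/internal-loop
   penalties;
4. prunes candidates with per-segment percentile thresholds (keep weak
   T<sub>FF</sub>/T<sub>RR</sub>/T<sub>WT</sub>, strong T<sub>FR</sub>);
5. clusters survivors into similarity groups (ungapped identity ≥ 80%
   and cosine ≥ 0.9975 over identity profiles, transitively closed) and
   samples four groups per segment;
6. joins adjacent-segment candidates, prunes pairs (top 20%
   homodimerizers out, joined T<sub>FR</sub> ≥ 80 °C), and runs a
   depth-first search for full-length paths in which **duplicated
   segments use different similarity groups in different repeat
   copies**;
7. renders the chosen path into the final template and partitions it
   into alternating-strand aPCR primers (≤ 44 nt, G/C 3′ termini,
   overlap T<sub>m</sub> ≥ 64 °C), validated by an all-vs-all
   cross-hybridization matrix and 72 °C hairpin screens.

Everything runs offline and is byte-reproducible from a single seed.
See the methods vignette (`vignettes/tandem-repeat-redesign.Rmd`) for
the model, its assumptions and the documented design choices.

## Worked example

Design a synthetic duplicated decapeptide and inspect what changed:

```r
library(trdesign)
toy <- generateToyTR(peptideLen = 10, nRepeats = 2, seed = 7)
toy$protein
#> [1] "LWHCRIDIRI"
cfg <- designConfig(tFrMin = 55, overlapTmMin = 55, adjacentMin = 55,
                    tFrEnvelope = c(40, 95), seed = 7)
run <- runDesign(toy$protein, list(c(1, 10)), nRepeats = 2,
                 wtCds = toy$wtCds, config = cfg)
toy$fullWtCds
#> [1] "CTATGGCACTGCAGAATAGACATAAGAATACTATGGCACTGCAGAATAGACATAAGAATA"
dnaSequence(run$template)
#> [1] "CTGTGGCACTGTCGCATCGACATCCGCATCTTGTGGCACTGTCGCATCGACATTCGCATC"
identityReport(run$template)
#> $repeatIdentity
#> [1] 93.33333
#> $wtIdentity
#> [1] 70.00000 66.66667
run$evaluation$silentMutations
#> copy1 copy2
#>     7     7
run$validation$pass
#> [1] TRUE
```

The starting gene encodes the two repeat copies with 100% identical DNA;
the redesigned template still translates to the same duplicated peptide
but carries 7 silent mutations per copy, drops repeat-vs-repeat DNA
identity to 93.3% (the 60-nt toy offers little codon freedom; the
bundled 89-residue repressor example reaches 65%) and to 66.7–70%
against the original gene, and tiles into a primer set whose
cross-hybridization validation passes.

The bundled fixture reproduces the published single-chain LacI
DNA-binding-domain repressor design from its printed primer table:

```r
reg <- redesignedRegions(dbdFixture(), variant = "DFT")
reg$identity
#> [1] 64.97175   # codon-aligned % identity between the two repeat copies
reg$nCodons
#> [1] 59
```

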