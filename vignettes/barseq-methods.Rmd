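---
title: "Barcoded in-frame deletions and BarSeq quantification: methods"
author: "BarSeqTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcoded in-frame deletions and BarSeq quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BarSeqTools)
```

## The scar model

Every barcoded deletion replaces a gene's internal span — everything
between the retained start codon and the retained last seven codons (six
amino acids plus the stop) — with a fixed-architecture scar. The unmarked
*bar* scar is 138 bp:

| component | length | role |
|---|---|---|
| ATG | 3 | the gene's own start codon, shared with the scar |
| LL | 32 | left linker, common priming/fusion homology |
| FRT | 34 | recombinase site left behind after cassette excision |
| spacer | 18 | left flank anchoring barcode extraction |
| barcode | 18 | six VNN codons, unique per strain |
| RL | 33 | right linker; its first 18 nt are the right flank |

The marked *erm-bar* precursor carries a full FRT–*erm*–FRT cassette in
place of the single FRT; simulated FLP excision (`flpExcise()`) collapses
it back to the *bar* scar, and the package asserts that round trip is
exact. The scar deliberately occupies a whole number of codons and the
barcode starts on a codon boundary (scar codons 30–35), so the fusion ORF
`ATG + scar + last seven codons` reads through without a premature stop —
`verifyInFrame()` checks exactly that on an assembled mutant genome.

Two modelling choices here were genuinely open:

* **The scar includes the start codon.** Only this reading makes the
  component sizes sum to 138 (3+32+34+18+18+33); the scar is therefore
  modelled as ATG-first, with the gene's ATG and the scar's ATG being the
  same three bases.
* **The FRT remnant.** The post-excision remnant's exact sequence is
  system-specific and not something this package can fix from first
  principles; 34 nt is the unique length consistent with the component
  sizes. We ship the canonical minimal FRT (13-bp repeat, 8-bp spacer,
  13-bp inverted repeat), verified to introduce no trimer-aligned stop in
  scar frame, and make it configurable via
  `defaultLinkerSet(frtRemnant =)`. The *erm* cassette is likewise a
  synthetic FRT–filler–FRT placeholder built in code: downstream logic
  depends only on its FRT ends and length, not its internal composition.

## Barcodes

Barcodes are drawn uniformly over the 48 VNN codons per position, the
forward-strand equivalent of NNB trimers on the reverse synthesis primer.
Because V excludes T, no trimer-aligned codon can be TAA, TAG or TGA; the
test suite proves this both by enumerating all 48 codons and over 10^5
seeded draws, and checks per-position codon usage is uniform to within
five standard errors.

`buildBarcodeLibrary()` assigns barcodes by rejection sampling with a
pairwise Hamming-distance floor, default 3. A floor of 3 means a single
sequencing substitution can never convert one library barcode into
another — with exact matching such a read falls into `_other` instead of
being miscounted. The floor is configurable down to 0 (plain uniqueness),
which reflects libraries assembled by picking sequenced clones rather
than by design. An unsatisfiable floor (e.g. pairwise distance 18, which
the three-letter codon-start alphabet caps at three barcodes) fails with
a clear message after an attempt budget.

## Oligo design

`designOligos()` emits the standard eight-oligo set per target: F1/R2
anneal 1 kb up- and downstream of the deletion junctions, R1 carries the
32-nt LL extension and anneals from the start codon going upstream, F2
carries RL and anneals at the last seven codons going downstream, FO/RO
sit 500 bp outside F1/R2, and FW/RW amplify an internal 500–1000-bp
fragment to assay gene absence. Defaults: anneal length 22 nt (bounds
18–30; no melting-temperature optimisation — primer thermodynamics is out
of scope), arm length 1000, outside offset 500. Genes whose internal span
cannot host a 500-bp FW/RW product fall back to the full span with a
warning. Minus-strand genes are handled by designing in coding
orientation and mapping anneal intervals back to the forward strand;
oligo sequences are always written 5'→3' as synthesized.

Coordinates are 1-based inclusive everywhere, matching
Biostrings/GenomicRanges convention and the user-facing tables.

`soeJoin()` models SOE-PCR as a string operation: adjacent fragments merge
at their terminal overlap of at least `minOverlap` (default 15) nt. All
admissible overlap lengths are enumerated; none is a no-overlap error and
more than one is an ambiguous-overlap error, since a polymerase-extension
junction with two self-consistent registers is not a clean join. A
property test reconstructs 200 randomly fragmented sequences with planted
overlaps.

## The synthetic-data generator

The generator exists so counting and statistics can be tested against a
known truth. It emulates:

* a set of barcoded strains at chosen input frequencies (default equal,
  as for OD-normalised mixing — `mixVolume()` implements the
  (1.25/OD600)×50 µL rule);
* deterministic exponential growth, strain *i*'s weight scaling as
  fitness_i^generations, with the default 15 generations corresponding to
  two serial 1:181 dilution/regrowth rounds
  (`generationsFromDilution(181, 2)` ≈ 15);
* an optional single multinomial bottleneck (e.g. host colonisation);
* dual-indexed amplicons whose strain-variable part is exactly the
  barcode interval, read at 250 nt (a 2 × 250 bp kit's read length) with
  i.i.d. per-base substitution errors and a configurable
  reverse-complement fraction (default 0.5).

It does **not** model PCR amplification bias, chimeras, index hopping,
quality-score structure (qualities are constant placeholders; nothing
downstream reads them), indels (available as a non-default in principle,
substitutions only by default), or paired-end merging. Passing tests
therefore demonstrate correctness of the counting and CI arithmetic under
clean multinomial sampling, not robustness to every MiSeq artefact; the
flank-mismatch tolerance below is the single knob exposed for real-data
noise. The amplicon's adapter/priming sequences outside the scar fragment
are synthetic placeholders — counting never depends on them.

Everything is deterministic under the scenario seed; identical scenarios
produce byte-identical FASTQ.

## Counting

A candidate barcode is the exact 18-nt window between the spacer (left
flank) and the first 18 nt of RL (right flank). Defaults: exact literal
flank matching (`maxFlankMismatches = 0`), matching the constant-sequence
design; a small per-flank substitution tolerance can be enabled for real
data and is guaranteed never to decrease the number of flank-bearing
reads. Both read orientations are searched by default because either
mate of a 2 × 250 bp run can present the locus in either orientation. A
read with several candidate windows contributes only its first and the
event is tallied, so reads are never double-counted. Candidates
containing N cannot match a library barcode and fall into `_other`.

`countSample()` streams FASTQ in chunks (constant memory in read count,
gzip accepted) and errors on malformed records with the record index.
Technical replicates are merged by summation before frequency
computation — count-level pooling of triplicate plates — not by averaging
frequencies.

## Relative frequencies and competitive index

RF excludes `_other` from numerator and denominator by default: the
quantity of interest is each library strain's share of classifiable
reads. The CI uses the arithmetic mean of the wild-type reference RFs
(the natural reading of "average"), and wild-type strains themselves
receive CIs against that mean, providing neutrality controls.

A mutant absent from an output sample has no finite CI. The default
policy is censoring: the reported value is computed with a 0.5-count
pseudocount and flagged `censored = TRUE`, to be read as "at or below
this level"; a flag switches to plain unflagged pseudocount CIs. We
deliberately do not derive a limit of detection — it depends on read
depth and experiment design in ways the package cannot know — so any LOD
is a user-supplied reporting threshold.

Numerical properties asserted in tests: CI equals an independently coded
one-line arithmetic oracle to 1e-12 on 1000 random tables; CI is
invariant to per-sample count scaling; and in an end-to-end simulation (7
strains, 3 wild-type references, 5 × 10^4 error-free reads per sample) a
strain of fitness 1.2 over 15 generations is recovered at
CI = 15·log10(1.2) within three delta-method standard deviations of the
multinomial read-sampling noise, while neutral strains stay within
|CI| < 0.05. These problem sizes mirror a realistic MiSeq sample's usable
depth while keeping the suite quick to run.

The RT-qPCR polarity ratio is a pure computation:
rel(g,s) = 2^−(Ct(g,s) − Ct(ref,s)) per gene and strain, fold changes
mutant/wild-type per gene, and the ratio fold(downstream)/fold(upstream).
A ratio near 1 indicates the deletion is non-polar.

## Pipeline and reproducibility

`runPipeline()` wires the modules into five subcommands (design, barcode,
simulate, count, ci) driven by one flat YAML config; explicit overrides
win over the file. Every stochastic subcommand requires a seed, outputs
carry a provenance comment header (tool version, config checksum, seed),
and identical config + seed reruns are byte-identical. The CLI wrapper
(`inst/scripts/barseq-cli.R`) is a thin optparse shell over the same
function and emits single-line machine-parsable error classes.

## Known limitations

* Construct design checks structure, not chemistry: no Tm, secondary
  structure or off-target priming screens.
* The FRT remnant and *erm* cassette are configurable placeholders, not
  the plasmid-specific sequences of any particular system.
* The simulator's error model is substitution-only and uniform; counting
  accuracy under structured error profiles is untested.
* CI reporting stops at per-sample values and censoring flags; summary
  statistics and hypothesis testing across host replicates are left to
  the analysis layer.
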