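---
title: "panforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures behind each stage of
the pipeline, the parameters that matter, the numerical conventions,
and the design choices made where the methodology was genuinely open.
It also describes what the synthetic strain-panel generator does and
does not emulate, and therefore what a passing test suite does and does
not establish about real data.

## The analysis problem

A panel of draft genomes from many strains of one bacterial species is
compared at the gene-family level. The units of comparison are ortholog
groups (OGs): clusters of genes across strains descending from one
ancestral gene. The OG × strain presence/absence matrix supports the
classical pan-genome quantities — the pan-genome (union of OGs), the
core genome (OGs in every strain), and the variome (their difference) —
as well as strain trees, island detection, plasmid and CRISPR
characterization, and gene-trait matching against growth phenotypes.

## Consensus gene calling

Draft genomes are annotated by several ab initio ORF callers whose
calls agree on stop codons far more than on start codons. The caller
therefore identifies a gene by *(contig, strand, stop coordinate)*;
calls sharing this key are one candidate whose interval is taken from
the longest supporter.

* **Vote threshold.** "Majority" is read strictly: a candidate needs
  support from more than `n_predictors * min_support_fraction`
  predictors (default fraction 0.5, so 3 of 4). The threshold is a
  configuration knob because the identity notion and the cutoff for a
  vote among four tools admit several readings.
* **Overlap rule.** Accepted genes may overlap by at most 100 bp
  (inclusive: exactly 100 bp is tolerated). Offending pairs are
  processed in descending overlap size and the shorter member is
  discarded; equal lengths discard the later start. Processing order
  and tie-breaks are fixed purely for determinism.
* **Coordinates.** All internal coordinates are 1-based inclusive — the
  native convention of GFF3 and of the Bioconductor ranges stack this
  package is built on. Overlap length is `min(end) - max(start) + 1`,
  computed on nucleotide intervals irrespective of strand.

## Ortholog inference

All-vs-all protein comparison is made desk-sized by a prefilter: only
pairs sharing at least `min_shared_kmers` (default 8) distinct amino
acid 4-mers are aligned. Related proteins at the divergence levels of
a species panel share dozens of 4-mers, while unrelated pairs share
almost none, so the prefilter is effectively lossless at these scales.
Surviving pairs get a Smith–Waterman score (BLOSUM62, gap open 10,
extension 0.5); an edge is kept when the score reaches 50 or the pair
shows at least 40% identity over at least half of the shorter sequence.
These conservative defaults sit between the generator's within-family
(10%) and between-family (at least 60%) divergence bands and are
exposed in the configuration.

The orthology graph keeps an inter-strain edge only if it is a
reciprocal best hit — each endpoint scores at least as high as the
endpoint strain's best alternative (ties kept) — and an intra-strain
edge only if it scores at least both endpoints' best inter-strain
score, the usual in-paralog criterion. Edge weights are scores divided
by the maximum retained score. This global normalization replaces the
per-species normalization of the classical OrthoMCL recipe; on panels
of conspecific strains with comparable proteomes the two coincide in
practice, and the simplification keeps the graph construction
transparent.

**Markov clustering.** The weighted adjacency matrix (self-loops set to
each node's maximum incident weight; 1 for isolated nodes) is made
column-stochastic and iterated: expansion (matrix squaring), inflation
(entry-wise power, default 1.5, then re-normalization), pruning of
entries below 1e-6, until the largest entry change is below 1e-8 or 200
iterations (non-convergence warns and flags the result). Clusters are
the connected components of the converged matrix's support. Connected
components of the input graph are processed independently — MCL can
only refine them — which also bounds the dense-matrix work by the
largest family, not the panel.

## Presence/absence matrix and accumulation curves

Presence is binary regardless of copy number; copy counts are kept as
metadata. OGs with a single gene in a single genome ("singletons") are
excluded from pan-genome counting by default, the usual convention for
accumulation curves, and retained but flagged otherwise. Curves are
computed over 100 random genome orderings (seeded): pan(n) is the union
and core(n) the intersection over the first n genomes; means, standard
deviations and the per-permutation values are all reported, since a
single cumulative ordering hides the ordering variance.

Variable regions are maximal runs of at least `min_run` (default 10)
consecutive OGs — in reference-projected rank order — each present in
at most `max_presence` (default 0.9) of strains. A cassette (a named
OG set, e.g. one such region) is called present in a strain when at
least `cassette_min_fraction` (default 0.8) of its OGs are present;
completeness rules for cassettes vary in the literature, so the
threshold is exposed.

## Pseudo-assembly and GC tracks

Each query gene is matched to a reference gene by reciprocal best hit
(the same alignment engine, restricted to strain-vs-reference); the
anchor is the midpoint `(start + stop) / 2` of the reference gene,
a symmetric, strand-free reading of "mean start/stop coordinate".
Contigs are sorted by their mean anchor; ties prefer the longer contig,
then the lexicographically smaller id. Anchorless contigs (typically
plasmids) go to an unplaced bin in input order. For a circular
reference, a contig whose anchors span more than half the reference has
its smaller coordinates unwrapped by one reference length before
averaging. Contig orientation is not inferred — ordering only — which
is a documented limitation.

GC tracks are sliding windows (default 5 kb window, 1 kb step; contigs
shorter than a window yield one whole-contig window) with ambiguous
bases excluded from numerator and denominator. Phage regions planted at
GC 0.40 against a 0.46 background are recovered within ±0.01.

## Plasmid criteria

The four criteria and their desk-scale thresholds: (1) fewer than 20%
of the contig's genes have a reference-chromosome ortholog; (2) any
gene annotation matches the plasmid keyword set (replication initiator,
repA/B, mobA/B, traA–Z, relaxase, parA/parB, toxin–antitoxin), with
word boundaries so that e.g. "transporter" never matches "tra"; (3) at
least 50% of the contig aligns to a known plasmid at ≥ 80% identity,
using seed-gated local alignment (pairs must share exact 15-mers before
alignment is attempted, the usual seed-and-extend economy); (4) an
exact terminal repeat of at least 50 bp, found with the classic border
(failure-function) scan in linear time. The thresholds are not fixed by
the methodology this follows; they are configuration with conservative
defaults. Two or more criteria give a `plasmid` call, exactly one a
`putative_plasmid`, zero `chromosomal` — the two-tier confidence is
this package's convention for the qualitative "one or preferably more".
Circularity is exact-match by default because terminal overlaps are
assembler artifacts whose fidelity varies; a mismatch-tolerant scan is
available.

## Strain trees

The sequence tree uses single-copy core OGs only. Per OG, the distance
between two strains is one minus the fractional identity (matches over
aligned residue pairs) of a global alignment of their member proteins;
strain distances are alignment-length-weighted means over OGs, so long
well-aligned genes count more than short ones. The tree is canonical
neighbor joining (Q-criterion, as in ape), with negative branch lengths
— possible on non-additive input — clamped to zero with a warning.
Neighbor joining on pairwise-identity distances replaces a
concatenated-alignment maximum-likelihood tree here: it removes two
heavyweight external dependencies while preserving the claim the
package tests — that the sequence tree and the gene-content tree are
two different views of the panel.

The content tree is agglomerative clustering (average linkage by
default; complete and single exposed) on Jaccard distances between OG
presence vectors, computed exactly by `dist(method = "binary")`. The
clustering metric and linkage behind published content dendrograms are
often unstated; average linkage on Jaccard is the transparent default
here, not a claim about any particular study's settings.

## CRISPR arrays

Detection is seed-and-extend: 12-mers recurring at spacings compatible
with a repeat+spacer period (repeat 23–47 bp, spacer 20–50 bp by
default) nucleate candidates; the repeat is extended column by column
while at most `max_repeat_mismatch` (default 1) instances deviate from
the column majority; boundary columns are then trimmed to perfect
conservation, so a chance near-agreement in the flanks cannot shift the
repeat boundary. Arrays need at least 3 repeats; spacers are the
inter-repeat segments. Overlapping candidates (one array found from
several seeds) resolve to the highest repeat count. An array abutting
a contig end within one repeat length is flagged truncated — in real
draft assemblies repeats often break contigs, so truncation is the
expected failure mode.

Spacers are catalogued reverse-complement aware (canonical form = the
lexicographic minimum of a spacer and its reverse complement). A
strain's CRISPR type is its ordered spacer set, orientation-insensitive;
strains without an array are type 0, and type ids follow first
appearance. Subset relations between types (candidate ancestral
arrays) are reported as metadata rather than merged, a conservative
reading of typing by "number and identity" of spacers.

## Gene-trait matching

Growth calls: a strain grows on a sugar iff its blank-corrected OD
exceeds 0.8 at any reading — strictly, so a peak of exactly 0.8 is no
growth. Curves are read every 20 minutes over 24 h (73 points).

Per trait, a Random Forest is trained on OG presence vectors with a
stratified bootstrap (each tree samples both classes equally at the
minority class size — important on small, imbalanced strain panels).
Importance is the mean decrease in Gini impurity, normalized to sum to
one over features; OGs above 0.005 are reported, ranked, and coloured
by presence among growth-class strains (> 75% green, < 25% red, else
black). Constant OGs are removed before training and always report
zero importance. Strains with a missing label are dropped for that
trait only; single-class traits are refused with a message.

Two calibration notes. First, the 0.005 threshold is meaningful
relative to matrix size: on a pan-genome-scale matrix (~4000 OGs) it is
~20× the mean importance and the permutation null selects almost
nothing, while on a very small matrix the same absolute threshold sits
near the null mean. The test suite therefore probes the permutation
null at the ~4000-OG scale the threshold was designed for. Second, the
original GTM tool's "minor adjustments" to Random Forest are not
documented in the source this follows; standard bagged-tree Gini
importance is used, with the threshold and colour semantics kept
verbatim. Whether the reported presence fraction is computed among the
positive class only (default) or as a positive-vs-negative contrast is
a flag.

## The synthetic generator

`simulate_pangenome()` plants, per panel: a core (one gene per family
in every strain); accessory families, some grouped into all-or-none
islands (cassettes) and one contiguous phage block, the rest
independent Bernoulli draws; plasmid replicons (rep + cargo genes,
shared across strains, an exact terminal repeat, and a nucleotide-level
reference that doubles as the "known plasmid" set); one CRISPR array
per strain from a small pool of spacer-set types (some strains none);
and binary phenotypes equal to island presence XOR label noise.

Protein families are a random ancestor mutated per strain
(substitutions only, default 10%); family ancestors are drawn
independently, which puts between-family identity near the random
background, far below any within-family value. Indels are excluded to
keep alignment scoring interpretable; this is a deliberate
simplification. Nucleotide genes are back-translated with synonymous
codon choice steered (greedy quota correction) to a per-gene GC target,
which is what makes the phage GC contrast a recoverable, testable
signal. Intergenic spacers are drawn at the local GC target. Plasmid
sequences are derived from the replicon reference by codon swaps at
mutated residues plus ~2% point mutations in spacers, so
contig-vs-known-plasmid identity behaves like real plasmid
conservation. Predictor tracks are derived from truth by independent
Bernoulli gene drops, Poisson spurious ORFs in intergenic space, and
±jitter of the start coordinate only (in codon steps; the stop is
fixed, matching the stop-anchored vote). Contig breakpoints fall only
in intergenic gaps — genes are never split — and never inside the
phage block or the CRISPR array.

Scale: sequences default to ~120-aa genes and panels to tens of
families per category, so genomes are tens of kilobases rather than
megabases and family counts are in the hundreds rather than thousands.
A `detail = "presence"` mode stops after family presence and phenotype
labels, for matrix-level experiments (e.g. gene-trait matching over
many replicate panels, where matrices of ~4000 OGs are generated
without sequences). The problem sizes used by the test suite — e.g. 10
strains × 150 families for family recovery, 30 strains × ~4100 OGs ×
20 replicates for GTM — were chosen as the smallest panels on which
the planted structure is unambiguous.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: sequencing error and assembly chimeras;
indel evolution and domain shuffling (alignment identity on real
proteins is noisier); genuinely ambiguous orthology (expanded paralog
families, promiscuous domains) where MCL granularity actually matters;
rearrangements beyond island presence/absence, so pseudo-assembly
faces no true synteny breaks; repeat-induced assembly fragmentation
(contig breaks here avoid genes by construction); and phenotypes whose
genetic basis is polygenic, regulatory or epistatic rather than a
single cassette. Results on real panels depend on upstream assembly
and annotation quality in ways the synthetic route cannot probe.

## Determinism and degenerate inputs

Every stochastic step takes an explicit seed (the pipeline derives
per-stage seeds from the master seed), and a rerun under the same
configuration reproduces output checksums byte for byte; deterministic
tie-breaks (lexicographic or positional) are fixed throughout.
Degenerate inputs have defined behavior: empty accessory sets yield
core-only matrices, strains absent from the OG universe yield zero
columns with a warning, empty OD curves yield `missing` phenotype
calls, non-convergent MCL warns and flags, and configuration
validation rejects unknown keys by name together with out-of-range
parameters.

## Known limitations

Beyond the generator's idealizations: the caller cannot recover genes
missed by a majority of predictors (by design); contig orientation is
not inferred; plasmid copy number is invisible without coverage data;
cas genes are not detected, so CRISPR arrays are typed without
locus classification; no multiple-testing correction is applied across
GTM traits (matching the screening character of the original
procedure); and the alignment engine, while exact, is not a substitute
for a profile-aware search on divergent real proteomes.
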