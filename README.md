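# panforge

Comparative pan-genomics for bacterial strain panels, in R.

`panforge` is aimed at microbial genomicists who work with draft genomes
of many strains of one species — the kind of panel produced when a
lactic-acid bacterium such as *Lactobacillus paracasei* is sequenced
across dairy, plant and gut isolates — and who want to go from gene
calls to a genotype–phenotype answer with every intermediate step
testable. It covers:

* **Consensus gene calling** from several ORF-predictor tracks: calls
  sharing (contig, strand, stop codon) are merged, accepted by a strict
  majority vote over predictors, and screened so that no two genes
  overlap by more than 100 bp (the shorter gene of an offending pair is
  discarded).
* **Ortholog groups (OGs)**: a shared-k-mer prefilter prunes the
  all-vs-all protein pair space, surviving pairs are scored by local
  alignment (BLOSUM62, affine gaps), inter-strain reciprocal best hits
  plus intra-strain in-paralog edges form an orthology graph, and Markov
  clustering (inflation 1.5) yields the OG partition.
* **Pan/core analysis**: the OG × strain presence/absence matrix, with
  pan- and core-genome accumulation curves over permuted genome
  orderings, single-copy-core extraction, and detection of variable
  regions (islands) in reference order.
* **Pseudo-assembly**: contigs of each draft genome are ordered along a
  finished circular reference by the mean midpoint of their genes'
  reciprocal-best reference hits, with sliding-window GC tracks that
  expose low-GC phage regions.
* **Plasmid classification** by four criteria: poor mapping to the
  reference chromosome, plasmid-function keywords (rep/mob/tra,
  relaxase, parAB, toxin–antitoxin), similarity to known plasmids, and
  apparent circularity (exact terminal repeat). One criterion gives a
  putative plasmid, two or more a plasmid call.
* **Strain trees**: a neighbor-joining tree from length-weighted
  single-copy-core protein distances, and a gene-content dendrogram
  from Jaccard distances between OG presence vectors
  (average linkage).
* **CRISPR typing**: seed-and-extend detection of direct-repeat/spacer
  arrays (~36-nt repeats), a reverse-complement-aware spacer catalogue,
  and strain types defined by ordered spacer identity.
* **Gene-trait matching (GTM)**: growth/no-growth calls from OD curves
  (blank-corrected OD > 0.8), Random-Forest importance ranking of OGs
  per trait (importance > 0.005 reported), and the classic colour code —
  presence > 75% in the growth class green, < 25% red, otherwise black.

Because the real analysis needs heavyweight all-vs-all alignment over
dozens of genomes, the package ships a **synthetic strain-panel
generator** (`simulate_pangenome()`) that plants a known pan-genome
structure — core and accessory families, accessory islands, plasmids
with circular overlaps and rep genes, phage regions at GC 0.40 against a
0.46 background, CRISPR arrays, and phenotypes causally tied to island
presence — and returns the full ground truth. Every stage is validated
by recovering what was planted.

## Worked example

```r
library(panforge)

sim <- simulate_pangenome(sim_config(n_strains = 6, seed = 1))
ogs <- infer_orthologs(sim$proteins,
                       annotations = setNames(sim$genes$annotation,
                                              sim$genes$gene_id))
pm  <- build_matrix(ogs)
curves <- accumulation_curves(pm, n_permutations = 100, seed = 1)
cat("pan-genome OGs:", nrow(pm$mat),
    "| core OGs:", sum(rowSums(pm$mat) == ncol(pm$mat)),
    "| single-copy core:", length(single_copy_core(pm)), "\n")
#> pan-genome OGs: 145 | core OGs: 103 | single-copy core: 103
print(tail(curves$summary, 3), digits = 3)
#>   n_genomes pan_mean pan_sd core_mean core_sd
#> 4         4      144   1.97       103    2.36
#> 5         5      145   0.00       103    0.00
#> 6         6      145   0.00       103    0.00
```

The pan-genome grows as genomes are added while the core shrinks to the
set present in all strains; 103 core OGs here are the 100 planted core
families plus the three plasmid-replicon families carried by every
strain. Gene-trait matching against simulated growth curves then points
straight at the planted sugar cassette:

```r
od   <- simulate_growth_curves(sim$truth, seed = 2)
phen <- call_growth(od)                   # growth iff corrected OD > 0.8
res  <- gene_trait_match(pm, phen, "galactose", n_trees = 1000, seed = 3,
                         annotation = setNames(ogs$og$annotation,
                                               ogs$og$og_id))
head(res$selected[, c("og_id", "importance", "pos_fraction",
                      "color", "annotation")], 5)
#>     og_id importance pos_fraction color                              annotation
#> 1 OG00145      0.066            1 green       sugar-binding periplasmic protein
#> 2 OG00144      0.065            1 green                     glycoside hydrolase
#> 3 OG00142      0.057            1 green                            sugar kinase
#> 4 OG00143      0.056            1 green PTS system sugar-specific IIB component
#> 5 OG00148      0.055            1 green   LacI family transcriptional regulator
```

Each reported OG is present in 100% of galactose-growing strains
(green), with importance far above the 0.005 reporting threshold — the
signature of a sugar-utilization cassette.

The whole pipeline, from predictor tracks to manifest, runs as:

```r
res <- run_all(run_config(seed = 1, out_dir = "run1"))
```

which writes the matrix, curves, both strain trees (Newick), plasmid
evidence, CRISPR arrays/types, GTM reports and a manifest with MD5
checksums; a rerun with the same seed reproduces the checksums exactly.
A thin command-line wrapper is available at
`inst/scripts/panforge.R`.

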