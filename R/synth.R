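#' Configuration for the synthetic strain-panel generator
#'
#' Builds and validates the parameter set for [simulate_pangenome()].  The
#' defaults emulate, at desk scale, a draft-genome panel of a lactic-acid
#' bacterium: a conserved core of gene families present in every strain,
#' accessory families that are strain-variable (some clustered into
#' contiguous "islands", e.g. sugar-utilization cassettes), small plasmids
#' with a circular terminal overlap and replication genes, phage regions
#' with GC content shifted below the chromosomal background, CRISPR arrays
#' of 36-nt direct repeats with unique spacers, and binary growth
#' phenotypes causally linked to island presence plus label noise.
#'
#' Sequence scale is reduced relative to real genomes (genes default to
#' ~120 aa rather than ~300 aa, and family counts are in the hundreds
#' rather than thousands) so that all-vs-all protein comparison runs in
#' seconds; the *structure* (core/accessory/island/plasmid/phage/CRISPR) is
#' what downstream stages are tested against.
#'
#' @param n_strains number of strains in the panel.
#' @param n_core_families gene families present in every strain.
#' @param n_accessory_families strain-variable families (includes island
#'   and phage families).
#' @param accessory_presence_prob per-strain presence probability of each
#'   accessory family (islands are drawn all-or-none per strain with
#'   `island_presence_prob`).
#' @param n_islands number of contiguous accessory blocks (cassettes).
#' @param island_size families per island.
#' @param island_presence_prob per-strain presence probability of each
#'   island; defaults to `accessory_presence_prob`.
#' @param n_phage_families families forming one contiguous phage block.
#' @param phage_presence_prob per-strain presence probability of the phage
#'   block.
#' @param mean_gene_len mean protein length (amino acids).
#' @param within_family_divergence expected fraction of substituted
#'   residues between a strain's copy and the family ancestor.
#' @param between_family_min_divergence required minimum divergence between
#'   families (ancestors are drawn independently, which exceeds this for
#'   any realistic setting; the config is rejected if
#'   `within_family_divergence >= between_family_min_divergence`).
#' @param n_plasmids_per_strain plasmid replicons carried by each strain.
#' @param n_plasmid_cargo_families cargo families per plasmid replicon (in
#'   addition to the replication-initiator family).
#' @param plasmid_terminal_overlap length (bp) of the exact terminal repeat
#'   that makes a plasmid contig "appear circular".
#' @param phage_gc GC fraction of phage genes and internal spacers.
#' @param background_gc GC fraction elsewhere.
#' @param fragmentation chromosomal contigs per genome.
#' @param predictor_error list with `miss_rate`, `spurious_rate`,
#'   `boundary_jitter_bp` applied independently per simulated predictor.
#' @param n_predictors number of simulated gene-prediction tracks.
#' @param crispr list with `repeat_len`, `n_repeats`, `spacer_len`,
#'   `n_types` (distinct spacer sets circulating in the panel) and
#'   `p_no_array` (probability a strain lacks a CRISPR locus).
#' @param phenotypes optional list of
#'   `list(sugar = name, causal_islands = island indices)`. The default
#'   assigns one sugar per island, named after the growth sugars of the
#'   phenotyping assay.
#' @param label_noise_rate probability that a strain's phenotype label is
#'   flipped relative to its causal genotype.
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param detail `"full"` generates sequences, genomes and predictor
#'   tracks; `"presence"` stops after family presence and phenotype
#'   labels (fast mode for matrix-level experiments such as gene-trait
#'   matching at many replicates).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_strains = 10,
                       n_core_families = 100,
                       n_accessory_families = 50,
                       accessory_presence_prob = 0.3,
                       n_islands = 2,
                       island_size = 10,
                       island_presence_prob = NULL,
                       n_phage_families = 12,
                       phage_presence_prob = 0.7,
                       mean_gene_len = 120,
                       within_family_divergence = 0.10,
                       between_family_min_divergence = 0.60,
                       n_plasmids_per_strain = 1,
                       n_plasmid_cargo_families = 2,
                       plasmid_terminal_overlap = 150,
                       phage_gc = 0.40,
                       background_gc = 0.46,
                       fragmentation = 12,
                       predictor_error = list(miss_rate = 0,
                                              spurious_rate = 0,
                                              boundary_jitter_bp = 0),
                       n_predictors = 4,
                       crispr = list(repeat_len = 36, n_repeats = 5,
                                     spacer_len = 30, n_types = 3,
                                     p_no_array = 0.2),
                       phenotypes = NULL,
                       label_noise_rate = 0.05,
                       seed = 1,
                       detail = c("full", "presence")) {
  detail <- match.arg(detail)
  cfg <- list(n_strains = n_strains,
              n_core_families = n_core_families,
              n_accessory_families = n_accessory_families,
              accessory_presence_prob = accessory_presence_prob,
              n_islands = n_islands,
              island_size = island_size,
              island_presence_prob =
                if (is.null(island_presence_prob)) accessory_presence_prob
                else island_presence_prob,
              n_phage_families = n_phage_families,
              phage_presence_prob = phage_presence_prob,
              mean_gene_len = mean_gene_len,
              within_family_divergence = within_family_divergence,
              between_family_min_divergence = between_family_min_divergence,
              n_plasmids_per_strain = n_plasmids_per_strain,
              n_plasmid_cargo_families = n_plasmid_cargo_families,
              plasmid_terminal_overlap = plasmid_terminal_overlap,
              phage_gc = phage_gc,
              background_gc = background_gc,
              fragmentation = fragmentation,
              predictor_error = predictor_error,
              n_predictors = n_predictors,
              crispr = crispr,
              phenotypes = phenotypes,
              label_noise_rate = label_noise_rate,
              seed = seed,
              detail = detail)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$accessory_presence_prob, cfg$island_presence_prob,
             cfg$phage_presence_prob, cfg$phage_gc, cfg$background_gc,
             cfg$label_noise_rate, cfg$predictor_error$miss_rate,
             cfg$predictor_error$spurious_rate, cfg$crispr$p_no_array)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_core_families < 1) stop("n_core_families must be >= 1")
  if (cfg$crispr$repeat_len <= 0) stop("crispr repeat_len must be > 0")
  if (cfg$within_family_divergence >= cfg$between_family_min_divergence) {
    stop("families are not separable: within_family_divergence must be ",
         "smaller than between_family_min_divergence")
  }
  n_island_fam <- cfg$n_islands * cfg$island_size
  if (n_island_fam + cfg$n_phage_families > cfg$n_accessory_families) {
    stop("n_accessory_families must cover islands plus phage families")
  }
  if (cfg$n_strains < 1) stop("n_strains must be >= 1")
  if (cfg$fragmentation < 1) stop("fragmentation must be >= 1")
  invisible(cfg)
}

## ---- sequence primitives -------------------------------------------------

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# reverse codon table for the standard bacterial code (translation table 11
# shares the codon->AA map of the standard code; only start codons differ)
codon_tables <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  gcc <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")), 1L)
  by_aa <- split(seq_along(codons), gc)
  list(codons = codons, gcc = gcc, by_aa = by_aa)
})

random_protein <- function(len) {
  paste0(c("M", sample(AA20, len - 1, replace = TRUE)), collapse = "")
}

mutate_protein <- function(seq, divergence) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  if (n < 2 || divergence <= 0) return(seq)
  hit <- which(runif(n - 1) < divergence) + 1L
  for (i in hit) {
    aa[i] <- sample(setdiff(AA20, aa[i]), 1)
  }
  paste0(aa, collapse = "")
}

# back-translate a protein to DNA, steering codon choice so that the CDS
# (including its stop codon) hits the target GC fraction as closely as the
# amino-acid sequence permits
back_translate <- function(aa_seq, gc_target) {
  ct <- codon_tables
  aa <- strsplit(aa_seq, "")[[1]]
  stops <- ct$by_aa[["*"]]
  idx <- vapply(aa, function(a) {
    opts <- ct$by_aa[[a]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, 1L)
  idx <- c(idx, if (length(stops) == 1) stops else sample(stops, 1))
  len_nt <- 3L * length(idx)
  target <- round(gc_target * len_nt)
  cur <- sum(ct$gcc[idx])
  aa_all <- c(aa, "*")
  # greedy synonymous swaps toward the target GC count
  for (step in seq_len(len_nt)) {
    d <- target - cur
    if (d == 0L) break
    if (d > 0L) {
      cand <- which(vapply(seq_along(idx), function(i) {
        any(ct$gcc[ct$by_aa[[aa_all[i]]]] > ct$gcc[idx[i]])
      }, TRUE))
    } else {
      cand <- which(vapply(seq_along(idx), function(i) {
        any(ct$gcc[ct$by_aa[[aa_all[i]]]] < ct$gcc[idx[i]])
      }, TRUE))
    }
    if (length(cand) == 0) break
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    opts <- ct$by_aa[[aa_all[i]]]
    g <- ct$gcc[opts]
    if (d > 0L) {
      g_new <- min(g[g > ct$gcc[idx[i]]])
    } else {
      g_new <- max(g[g < ct$gcc[idx[i]]])
    }
    pick <- opts[g == g_new]
    idx[i] <- if (length(pick) == 1) pick else sample(pick, 1)
    cur <- sum(ct$gcc[idx])
  }
  paste0(ct$codons[idx], collapse = "")
}

# random DNA with an exact GC quota
random_dna <- function(len, gc_target) {
  n_gc <- round(gc_target * len)
  base <- character(len)
  gc_pos <- if (n_gc > 0) sample.int(len, n_gc) else integer(0)
  base[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  at_pos <- setdiff(seq_len(len), gc_pos)
  base[at_pos] <- sample(c("A", "T"), length(at_pos), replace = TRUE)
  paste0(base, collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste0(b, collapse = "")
}

# re-encode an ancestor CDS for a mutated protein: codons are kept where
# the residue is unchanged and re-drawn where it differs, so nucleotide
# identity between family members stays high (as in real genes)
recode_cds <- function(anc_cds, anc_aa, new_aa) {
  ct <- codon_tables
  codons <- substring(anc_cds, seq(1, nchar(anc_cds), 3),
                      seq(3, nchar(anc_cds), 3))
  a1 <- strsplit(anc_aa, "")[[1]]
  a2 <- strsplit(new_aa, "")[[1]]
  for (i in which(a1 != a2)) {
    opts <- ct$by_aa[[a2[i]]]
    pick <- if (length(opts) == 1) opts else sample(opts, 1)
    codons[i] <- ct$codons[pick]
  }
  paste0(codons, collapse = "")
}

## ---- generator -----------------------------------------------------------

#' Simulate a strain panel with known pan-genome structure
#'
#' Generates per-strain draft genomes (contig FASTA), per-predictor gene
#' tracks (GFF3-style tables), protein sets, a finished circular reference
#' genome, a known-plasmid sequence set, and the complete ground truth
#' (family of every gene, island composition, plasmid contigs, phage
#' intervals, CRISPR arrays, causal phenotype families and labels).
#'
#' Families are generated by mutating a random ancestor protein per family
#' (substitutions only); nucleotide genes are back-translated with codon
#' choice steered to the configured GC target, which plants the phage GC
#' contrast recoverable by [gc_profile()].  Contig breakpoints fall only in
#' intergenic space, so genes are never split across contigs.
#'
#' @param config a [sim_config()].
#' @return object of class `pan_sim`: list with `config`, `genomes` (list
#'   of [Biostrings::DNAStringSet] per strain), `genes` (truth gene table),
#'   `proteins` ([Biostrings::AAStringSet]), `tracks` (per strain, per
#'   predictor data.frames of predicted ORFs), `reference` (sequence, gene
#'   table, proteins), `known_plasmids`, `annotations` (family ->
#'   description) and `truth` (class `truth_set`).
#' @export
simulate_pangenome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  strains <- sprintf("S%02d", seq_len(cfg$n_strains))

  ## family universe ------------------------------------------------------
  core_fams <- sprintf("C%03d", seq_len(cfg$n_core_families))
  acc_fams <- sprintf("A%03d", seq_len(cfg$n_accessory_families))
  n_island_fam <- cfg$n_islands * cfg$island_size
  island_fams <- if (n_island_fam > 0) {
    split(acc_fams[seq_len(n_island_fam)],
          rep(seq_len(cfg$n_islands), each = cfg$island_size))
  } else list()
  phage_fams <- acc_fams[n_island_fam + seq_len(cfg$n_phage_families)]
  single_fams <- setdiff(acc_fams, c(unlist(island_fams), phage_fams))
  plasmid_fams <- list()
  for (j in seq_len(cfg$n_plasmids_per_strain)) {
    plasmid_fams[[j]] <- c(sprintf("P%drep", j),
                           sprintf("P%dcargo%d", j,
                                   seq_len(cfg$n_plasmid_cargo_families)))
  }
  all_fams <- c(core_fams, acc_fams, unlist(plasmid_fams))

  ## annotations -----------------------------------------------------------
  core_pool <- c("hypothetical protein", "DNA polymerase III subunit",
                 "50S ribosomal protein", "ABC transporter ATP-binding protein",
                 "cell division protein FtsZ", "elongation factor Tu",
                 "peptidase family protein", "two-component sensor kinase",
                 "tRNA ligase", "cell-envelope proteinase")
  island_pool <- c("PTS system sugar-specific IIB component",
                   "beta-galactosidase", "sugar kinase",
                   "LacI family transcriptional regulator",
                   "glycoside hydrolase", "sugar-binding periplasmic protein")
  phage_pool <- c("phage integrase", "phage major capsid protein",
                  "phage tail tape measure protein", "phage terminase",
                  "phage portal protein", "phage holin")
  annotations <- setNames(character(length(all_fams)), all_fams)
  annotations[core_fams] <- sample(core_pool, length(core_fams),
                                   replace = TRUE)
  annotations[unlist(island_fams)] <- sample(island_pool, n_island_fam,
                                             replace = TRUE)
  annotations[phage_fams] <- sample(phage_pool, length(phage_fams),
                                    replace = TRUE)
  annotations[single_fams] <- "hypothetical protein"
  for (j in seq_along(plasmid_fams)) {
    fams <- plasmid_fams[[j]]
    annotations[fams[1]] <- "replication initiator protein RepB"
    if (length(fams) > 1) {
      annotations[fams[-1]] <- rep(c("mobilization protein MobA",
                                     "hypothetical plasmid protein"),
                                   length.out = length(fams) - 1)
    }
  }

  ## ancestor proteins ------------------------------------------------------
  anc_len <- pmax(50L, round(rnorm(length(all_fams), cfg$mean_gene_len,
                                   0.15 * cfg$mean_gene_len)))
  ancestors <- setNames(vapply(anc_len, random_protein, ""), all_fams)

  ## reference order of chromosomal families -------------------------------
  # core backbone with islands, phage block and accessory singletons
  # inserted at fixed (seeded) positions; this order is shared by every
  # strain and by the finished reference genome
  blocks <- c(as.list(core_fams),
              unname(island_fams),
              if (length(phage_fams) > 0) list(phage_fams) else NULL,
              as.list(single_fams))
  block_is_core <- c(rep(TRUE, length(core_fams)),
                     rep(FALSE, length(blocks) - length(core_fams)))
  # islands/phage/singles are inserted between core genes at random slots
  n_acc_blocks <- sum(!block_is_core)
  slot <- sample.int(length(core_fams) - 1, n_acc_blocks, replace = TRUE)
  order_blocks <- list()
  acc_iter <- which(!block_is_core)[order(slot)]
  slot_sorted <- sort(slot)
  ci <- 1L
  ai <- 1L
  for (i in seq_len(length(core_fams))) {
    order_blocks <- c(order_blocks, list(core_fams[i]))
    while (ai <= n_acc_blocks && slot_sorted[ai] == i) {
      order_blocks <- c(order_blocks, blocks[acc_iter[ai]])
      ai <- ai + 1L
    }
  }
  ref_family_order <- unlist(order_blocks)
  is_phage_fam <- ref_family_order %in% phage_fams

  ## CRISPR spacer-set types ------------------------------------------------
  cr <- cfg$crispr
  crispr_repeat <- random_dna(cr$repeat_len, 0.5)
  n_spacers <- cr$n_repeats - 1L
  crispr_types <- lapply(seq_len(cr$n_types), function(t) {
    vapply(seq_len(n_spacers), function(i) random_dna(cr$spacer_len, 0.5), "")
  })
  strain_crispr_type <- ifelse(runif(cfg$n_strains) < cr$p_no_array, 0L,
                               sample.int(max(cr$n_types, 1L),
                                          cfg$n_strains, replace = TRUE))
  if (cr$n_types == 0) strain_crispr_type[] <- 0L

  ## per-strain family presence --------------------------------------------
  presence <- matrix(0L, cfg$n_strains, length(all_fams),
                     dimnames = list(strains, all_fams))
  presence[, core_fams] <- 1L
  island_present <- matrix(0L, cfg$n_strains, max(cfg$n_islands, 1))
  for (k in seq_len(cfg$n_islands)) {
    island_present[, k] <- as.integer(runif(cfg$n_strains) <
                                        cfg$island_presence_prob)
    presence[, island_fams[[k]]] <- island_present[, k]
  }
  phage_present <- as.integer(runif(cfg$n_strains) < cfg$phage_presence_prob)
  if (length(phage_fams) > 0) presence[, phage_fams] <- phage_present
  for (f in single_fams) {
    presence[, f] <- as.integer(runif(cfg$n_strains) <
                                  cfg$accessory_presence_prob)
  }
  for (j in seq_along(plasmid_fams)) {
    presence[, plasmid_fams[[j]]] <- 1L
  }

  ## phenotypes ------------------------------------------------------------
  sugar_names <- c("galactose", "cellobiose", "dulcitol", "mannitol",
                   "sorbose", "mannose", "saccharose", "sorbitol",
                   "trehalose", "maltose", "myoinositol", "ribose",
                   "xylose", "lactose", "glucose", "galactosamine",
                   "Ca-gluconate", "melezitose", "melibiose")
  phen <- cfg$phenotypes
  if (is.null(phen) && cfg$n_islands > 0) {
    phen <- lapply(seq_len(cfg$n_islands), function(k) {
      list(sugar = sugar_names[(k - 1) %% length(sugar_names) + 1],
           causal_islands = k)
    })
  }
  causal_families <- list()
  pheno_labels <- NULL
  if (!is.null(phen)) {
    pheno_labels <- matrix(0L, cfg$n_strains, length(phen),
                           dimnames = list(strains,
                                           vapply(phen, `[[`, "", "sugar")))
    for (p in seq_along(phen)) {
      ks <- phen[[p]]$causal_islands
      causal_families[[phen[[p]]$sugar]] <- unlist(island_fams[ks])
      geno <- as.integer(rowSums(island_present[, ks, drop = FALSE]) ==
                           length(ks))
      flip <- runif(cfg$n_strains) < cfg$label_noise_rate
      pheno_labels[, p] <- ifelse(flip, 1L - geno, geno)
    }
  }

  if (cfg$detail == "presence") {
    truth <- structure(list(
      family_of_gene = character(0),
      island_families = island_fams,
      plasmid_contigs = list(),
      phage_intervals = list(),
      causal_families = causal_families,
      crispr_arrays = list(),
      crispr_type = setNames(strain_crispr_type, strains),
      phenotype_labels = pheno_labels,
      family_presence = presence,
      ref_family_order = ref_family_order,
      phage_families = phage_fams,
      plasmid_families = plasmid_fams,
      chrom_contig_order = list(),
      core_families = core_fams), class = "truth_set")
    return(structure(list(config = cfg, strains = strains,
                          genomes = NULL, genes = NULL, proteins = NULL,
                          tracks = NULL, reference = NULL,
                          known_plasmids = NULL,
                          annotations = annotations, truth = truth),
                     class = "pan_sim"))
  }

  ## build genomes ----------------------------------------------------------
  genomes <- list()
  genes_list <- list()
  proteins <- character(0)
  tracks <- list()
  plasmid_contigs <- list()
  phage_intervals <- list()
  crispr_arrays <- list()
  chrom_contig_order <- list()
  family_of_gene <- character(0)

  igs_len <- function() sample(80:200, 1)

  ## plasmid replicon references: one nucleotide-level reference per
  ## replicon; strains carry mutated copies, so contig-vs-known-plasmid
  ## identity behaves like real plasmid conservation
  plasmid_ref <- list()
  for (j in seq_len(cfg$n_plasmids_per_strain)) {
    parts <- list(list(type = "igs",
                       seq = random_dna(igs_len(), cfg$background_gc)))
    for (f in plasmid_fams[[j]]) {
      parts <- c(parts,
                 list(list(type = "gene", family = f,
                           cds = back_translate(ancestors[[f]],
                                                cfg$background_gc))),
                 list(list(type = "igs",
                           seq = random_dna(igs_len(),
                                            cfg$background_gc))))
    }
    seqs <- vapply(parts, function(p)
      if (p$type == "igs") p$seq else p$cds, "")
    plasmid_ref[[j]] <- list(parts = parts,
                             seq = paste0(seqs, collapse = ""))
  }

  for (si in seq_along(strains)) {
    s <- strains[si]
    fams_here <- ref_family_order[presence[si, ref_family_order] == 1L]
    ## segment list: alternating igs / gene, igs GC follows flanking genes
    segs <- list()
    add_seg <- function(seg) segs[[length(segs) + 1L]] <<- seg
    prev_phage <- FALSE
    gi <- 0L
    for (f in fams_here) {
      phg <- f %in% phage_fams
      gc_igs <- if (phg && prev_phage) cfg$phage_gc else cfg$background_gc
      add_seg(list(type = "igs", seq = random_dna(igs_len(), gc_igs),
                   breakable = !(phg && prev_phage)))
      gi <- gi + 1L
      aa <- mutate_protein(ancestors[[f]], cfg$within_family_divergence)
      cds <- back_translate(aa, if (phg) cfg$phage_gc else cfg$background_gc)
      strand <- sample(c("+", "-"), 1)
      add_seg(list(type = "gene", family = f, aa = aa, strand = strand,
                   seq = if (strand == "+") cds else revcomp_chr(cds),
                   gene_id = sprintf("%s|g%04d", s, gi)))
      prev_phage <- phg
    }
    add_seg(list(type = "igs", seq = random_dna(igs_len(),
                                                cfg$background_gc),
                 breakable = FALSE))
    ## CRISPR array as its own segment, inserted after a breakable igs
    tt <- strain_crispr_type[si]
    if (tt > 0L) {
      spacers <- crispr_types[[tt]]
      array_seq <- crispr_repeat
      for (sp in spacers) array_seq <- paste0(array_seq, sp, crispr_repeat)
      ins_after <- which(vapply(segs, function(x) x$type == "igs" &&
                                  isTRUE(x$breakable), TRUE))
      pos <- if (length(ins_after) > 1) sample(ins_after, 1) else ins_after
      cr_seg <- list(type = "crispr", seq = array_seq,
                     spacers = spacers, repeat_seq = crispr_repeat)
      segs <- append(segs, list(cr_seg,
                                list(type = "igs",
                                     seq = random_dna(igs_len(),
                                                      cfg$background_gc),
                                     breakable = FALSE)),
                     after = pos)
    }
    ## fragmentation: pick breakable igs segments, split at midpoint
    seg_types <- vapply(segs, `[[`, "", "type")
    breakable <- which(seg_types == "igs" &
                         vapply(segs, function(x) isTRUE(x$breakable), TRUE))
    breakable <- setdiff(breakable, c(1L, length(segs)))
    n_breaks <- min(cfg$fragmentation - 1L, length(breakable))
    brk <- sort(if (n_breaks > 0) sample(breakable, n_breaks) else integer(0))
    ## assemble contigs in true chromosomal order
    n_contigs <- n_breaks + 1L
    labels <- sprintf("%s_k%02d", s, sample.int(n_contigs))
    contig_seqs <- setNames(vector("list", n_contigs), labels)
    cidx <- 1L
    buf <- character(0)
    gene_rows <- list()
    phage_span <- NULL  # (contig, start, end) of phage gene run
    crispr_rec <- NULL
    phage_first <- TRUE
    for (k in seq_along(segs)) {
      seg <- segs[[k]]
      if (seg$type == "igs" && k %in% brk) {
        half <- nchar(seg$seq) %/% 2L
        buf <- c(buf, substr(seg$seq, 1, half))
        contig_seqs[[cidx]] <- paste0(buf, collapse = "")
        cidx <- cidx + 1L
        buf <- substr(seg$seq, half + 1L, nchar(seg$seq))
        next
      }
      offset <- sum(nchar(buf))
      buf <- c(buf, seg$seq)
      if (seg$type == "gene") {
        st <- offset + 1L
        en <- offset + nchar(seg$seq)
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(gene_id = seg$gene_id, strain = s,
                     contig = labels[cidx], start = st, end = en,
                     strand = seg$strand, family = seg$family,
                     annotation = unname(annotations[seg$family]),
                     stringsAsFactors = FALSE)
        proteins[seg$gene_id] <- seg$aa
        family_of_gene[seg$gene_id] <- seg$family
        if (seg$family %in% phage_fams) {
          if (phage_first) {
            phage_span <- list(contig = labels[cidx], start = st, end = en)
            phage_first <- FALSE
          } else {
            phage_span$end <- en
          }
        }
      } else if (seg$type == "crispr") {
        crispr_rec <- list(contig = labels[cidx],
                           start = offset + 1L,
                           end = offset + nchar(seg$seq),
                           repeat_seq = seg$repeat_seq,
                           spacers = seg$spacers)
      }
    }
    contig_seqs[[cidx]] <- paste0(buf, collapse = "")
    chrom_contig_order[[s]] <- labels

    ## plasmids ------------------------------------------------------------
    p_labels <- character(0)
    for (j in seq_len(cfg$n_plasmids_per_strain)) {
      pl <- sprintf("%s_p%d", s, j)
      p_labels <- c(p_labels, pl)
      pbuf <- character(0)
      for (part in plasmid_ref[[j]]$parts) {
        if (part$type == "igs") {
          pbuf <- c(pbuf, mutate_dna(part$seq, 0.02))
          next
        }
        gi <- gi + 1L
        f <- part$family
        aa <- mutate_protein(ancestors[[f]], cfg$within_family_divergence)
        cds <- recode_cds(part$cds, ancestors[[f]], aa)
        gid <- sprintf("%s|g%04d", s, gi)
        st <- sum(nchar(pbuf)) + 1L
        pbuf <- c(pbuf, cds)
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(gene_id = gid, strain = s, contig = pl,
                     start = st, end = sum(nchar(pbuf)), strand = "+",
                     family = f, annotation = unname(annotations[f]),
                     stringsAsFactors = FALSE)
        proteins[gid] <- aa
        family_of_gene[gid] <- f
      }
      pseq <- paste0(pbuf, collapse = "")
      # exact terminal repeat => "appears circular"
      pseq <- paste0(pseq, substr(pseq, 1, cfg$plasmid_terminal_overlap))
      contig_seqs[[pl]] <- pseq
    }
    plasmid_contigs[[s]] <- p_labels

    genome <- Biostrings::DNAStringSet(
      vapply(contig_seqs, identity, "", USE.NAMES = TRUE))
    # store contigs in label order (shuffled relative to true order)
    genome <- genome[order(names(genome))]
    genomes[[s]] <- genome
    genes_s <- do.call(rbind, gene_rows)
    genes_list[[s]] <- genes_s
    if (!is.null(phage_span)) phage_intervals[[s]] <- phage_span
    if (!is.null(crispr_rec)) crispr_arrays[[s]] <- crispr_rec

    ## predictor tracks -----------------------------------------------------
    pe <- cfg$predictor_error
    jit3 <- (pe$boundary_jitter_bp %/% 3L)
    contig_len <- setNames(Biostrings::width(genome), names(genome))
    tracks[[s]] <- list()
    for (p in seq_len(cfg$n_predictors)) {
      pred <- sprintf("pred%d", p)
      keep <- runif(nrow(genes_s)) >= pe$miss_rate
      tg <- genes_s[keep, , drop = FALSE]
      if (nrow(tg) > 0 && jit3 > 0) {
        delta <- 3L * sample(seq(-jit3, jit3), nrow(tg), replace = TRUE)
        plus <- tg$strand == "+"
        ns <- ifelse(plus, tg$start + delta, tg$start)
        ne <- ifelse(plus, tg$end, tg$end - delta)
        ok <- ns >= 1 & ne <= contig_len[tg$contig] & (ne - ns + 1) >= 30
        tg$start <- ifelse(ok, ns, tg$start)
        tg$end <- ifelse(ok, ne, tg$end)
      }
      orfs <- data.frame(strain = s, contig = tg$contig, start = tg$start,
                         end = tg$end, strand = tg$strand,
                         predictor = pred, truth_gene = tg$gene_id,
                         stringsAsFactors = FALSE)
      n_spur <- rpois(1, pe$spurious_rate * nrow(genes_s))
      if (n_spur > 0) {
        sp_rows <- lapply(seq_len(n_spur), function(i) {
          ctg <- sample(names(genome), 1)
          len <- 3L * sample(10:30, 1)
          if (contig_len[ctg] <= len + 2) return(NULL)
          st <- sample.int(contig_len[ctg] - len, 1)
          data.frame(strain = s, contig = ctg, start = st,
                     end = st + len - 1L,
                     strand = sample(c("+", "-"), 1), predictor = pred,
                     truth_gene = NA_character_, stringsAsFactors = FALSE)
        })
        orfs <- rbind(orfs, do.call(rbind, sp_rows))
      }
      orfs$orf_id <- sprintf("%s|%s|o%04d", s, pred, seq_len(nrow(orfs)))
      tracks[[s]][[pred]] <- orfs
    }
  }

  genes <- do.call(rbind, genes_list)
  rownames(genes) <- NULL

  ## reference genome: ancestors in reference order, single circular seq ---
  ref_rows <- list()
  rbuf <- random_dna(150, cfg$background_gc)
  ref_prot <- character(0)
  for (i in seq_along(ref_family_order)) {
    f <- ref_family_order[i]
    aa <- ancestors[[f]]
    cds <- back_translate(aa, if (is_phage_fam[i]) cfg$phage_gc
                          else cfg$background_gc)
    strand <- sample(c("+", "-"), 1)
    sq <- if (strand == "+") cds else revcomp_chr(cds)
    gid <- sprintf("REF|g%04d", i)
    st <- nchar(rbuf) + 1L
    rbuf <- paste0(rbuf, sq)
    ref_rows[[i]] <- data.frame(gene_id = gid, strain = "REF",
                                contig = "REFCHR", start = st,
                                end = nchar(rbuf), strand = strand,
                                family = f,
                                annotation = unname(annotations[f]),
                                stringsAsFactors = FALSE)
    ref_prot[gid] <- aa
    rbuf <- paste0(rbuf, random_dna(igs_len(), cfg$background_gc))
  }
  reference <- list(seq = Biostrings::DNAStringSet(c(REFCHR = rbuf)),
                    genes = do.call(rbind, ref_rows),
                    proteins = Biostrings::AAStringSet(ref_prot),
                    circular = TRUE)

  ## known plasmids: the replicon reference sequences ----------------------
  kp <- vapply(plasmid_ref, `[[`, "", "seq")
  names(kp) <- sprintf("known_plasmid_%d", seq_along(plasmid_ref))

  truth <- structure(list(
    family_of_gene = family_of_gene,
    island_families = island_fams,
    plasmid_contigs = plasmid_contigs,
    phage_intervals = phage_intervals,
    causal_families = causal_families,
    crispr_arrays = crispr_arrays,
    crispr_type = setNames(strain_crispr_type, strains),
    phenotype_labels = pheno_labels,
    family_presence = presence,
    ref_family_order = ref_family_order,
    phage_families = phage_fams,
    plasmid_families = plasmid_fams,
    chrom_contig_order = chrom_contig_order,
    core_families = core_fams), class = "truth_set")

  structure(list(config = cfg, strains = strains, genomes = genomes,
                 genes = genes,
                 proteins = Biostrings::AAStringSet(proteins),
                 tracks = tracks, reference = reference,
                 known_plasmids = Biostrings::DNAStringSet(kp),
                 annotations = annotations, truth = truth),
            class = "pan_sim")
}

#' Simulate OD growth curves for the panel's phenotypes
#'
#' Produces a blank-included OD time series per strain and sugar, read
#' every 20 minutes over 24 h (73 time points).  Strains labelled positive
#' for a sugar plateau well above the 0.8 growth threshold after blank
#' correction; negative strains stay below it.  Labels (including any
#' noise applied at generation time) are taken from
#' `truth$phenotype_labels`.
#'
#' @param truth a `truth_set` with `phenotype_labels`.
#' @param od_params optional overrides: `plateau_pos`, `plateau_neg`
#'   (ranges), `rate`, `midpoint`, `blank`, `noise_sd`, `interval_min`,
#'   `duration_min`.
#' @param seed RNG seed for curve noise.
#' @return data.frame with columns `strain`, `sugar`, `minute`, `od`;
#'   blank wells appear as strain `"_blank"`.
#' @export
simulate_growth_curves <- function(truth, od_params = list(), seed = 1) {
  if (is.null(truth$phenotype_labels)) {
    stop("truth contains no phenotype labels")
  }
  p <- modifyList(list(plateau_pos = c(1.0, 1.3), plateau_neg = c(0.2, 0.5),
                       rate = c(0.008, 0.015), midpoint = c(300, 500),
                       blank = 0.05, noise_sd = 0.005,
                       interval_min = 20, duration_min = 1440), od_params)
  set.seed(seed)
  labels <- truth$phenotype_labels
  minutes <- seq(0, p$duration_min, by = p$interval_min)
  out <- list()
  for (sugar in colnames(labels)) {
    out[[length(out) + 1L]] <- data.frame(
      strain = "_blank", sugar = sugar, minute = minutes,
      od = p$blank + rnorm(length(minutes), 0, p$noise_sd / 2),
      stringsAsFactors = FALSE)
    for (s in rownames(labels)) {
      pos <- labels[s, sugar] == 1L
      K <- if (pos) runif(1, p$plateau_pos[1], p$plateau_pos[2])
           else runif(1, p$plateau_neg[1], p$plateau_neg[2])
      r <- runif(1, p$rate[1], p$rate[2])
      t0 <- runif(1, p$midpoint[1], p$midpoint[2])
      od <- p$blank + K / (1 + exp(-r * (minutes - t0))) +
        rnorm(length(minutes), 0, p$noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        strain = s, sugar = sugar, minute = minutes, od = od,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a simulated dataset to disk
#'
#' Lays out the dataset as the pipeline's input file tree: per-strain
#' contig FASTA, per-strain/per-predictor GFF3 tracks, protein FASTA,
#' reference FASTA + GFF3 + proteins, known-plasmid FASTA, OD table TSV,
#' and the ground truth as JSON.  [read_dataset()] restores the same
#' in-memory structure losslessly.
#'
#' @param sim a `pan_sim` from [simulate_pangenome()].
#' @param out_dir output directory (created if missing).
#' @param od optional OD table from [simulate_growth_curves()].
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(sim, out_dir, od = NULL) {
  dirs <- file.path(out_dir, c("genomes", "proteins", "tracks",
                               "reference", "plasmids", "phenotypes"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$strains) {
    write_fasta(sim$genomes[[s]], file.path(out_dir, "genomes",
                                            paste0(s, ".fna")))
    idx <- names(sim$proteins)[startsWith(names(sim$proteins),
                                          paste0(s, "|"))]
    write_fasta(sim$proteins[idx], file.path(out_dir, "proteins",
                                             paste0(s, ".faa")))
    for (pred in names(sim$tracks[[s]])) {
      tr <- sim$tracks[[s]][[pred]]
      write_gff3(data.frame(contig = tr$contig, start = tr$start,
                            end = tr$end, strand = tr$strand,
                            gene_id = tr$orf_id, source = pred,
                            stringsAsFactors = FALSE),
                 file.path(out_dir, "tracks",
                           paste0(s, "__", pred, ".gff3")))
    }
  }
  write_fasta(sim$reference$seq,
              file.path(out_dir, "reference", "reference.fna"))
  write_fasta(sim$reference$proteins,
              file.path(out_dir, "reference", "reference.faa"))
  write_gff3(cbind(sim$reference$genes[, c("contig", "start", "end",
                                           "strand", "gene_id")],
                   source = "reference"),
             file.path(out_dir, "reference", "reference.gff3"))
  write_fasta(sim$known_plasmids,
              file.path(out_dir, "plasmids", "known_plasmids.fna"))
  if (!is.null(od)) {
    write_tsv(od, file.path(out_dir, "phenotypes", "od.tsv"))
  }
  if (!is.null(sim$truth$phenotype_labels)) {
    lab <- as.data.frame(sim$truth$phenotype_labels)
    lab <- cbind(strain = rownames(lab), lab)
    write_tsv(lab, file.path(out_dir, "phenotypes", "labels.tsv"))
  }
  truth <- sim$truth
  tr_json <- list(
    family_of_gene = as.list(truth$family_of_gene),
    island_families = truth$island_families,
    plasmid_contigs = truth$plasmid_contigs,
    phage_intervals = truth$phage_intervals,
    causal_families = truth$causal_families,
    crispr_arrays = truth$crispr_arrays,
    crispr_type = as.list(truth$crispr_type),
    phenotype_labels = if (is.null(truth$phenotype_labels)) NULL else
      cbind(data.frame(strain = rownames(truth$phenotype_labels)),
            as.data.frame(truth$phenotype_labels)),
    family_presence =
      cbind(data.frame(strain = rownames(truth$family_presence)),
            as.data.frame(truth$family_presence)),
    ref_family_order = truth$ref_family_order,
    phage_families = truth$phage_families,
    plasmid_families = truth$plasmid_families,
    chrom_contig_order = truth$chrom_contig_order,
    core_families = truth$core_families,
    genes = sim$genes,
    annotations = as.list(sim$annotations))
  jsonlite::write_json(tr_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list of class `pan_dataset` mirroring the `pan_sim` layout
#'   (minus the config): `genomes`, `proteins`, `tracks`, `reference`,
#'   `known_plasmids`, `od` (or NULL), `annotations`, `genes`, `truth`.
#' @export
read_dataset <- function(dir) {
  gfiles <- list.files(file.path(dir, "genomes"), full.names = TRUE)
  strains <- sub("\\.fna$", "", basename(gfiles))
  genomes <- setNames(lapply(gfiles, read_fasta, type = "DNA"), strains)
  prot <- lapply(strains, function(s)
    read_fasta(file.path(dir, "proteins", paste0(s, ".faa")), type = "AA"))
  proteins <- do.call(c, prot)
  tracks <- list()
  for (s in strains) {
    tf <- list.files(file.path(dir, "tracks"),
                     pattern = paste0("^", s, "__"), full.names = TRUE)
    preds <- sub("\\.gff3$", "", sub("^.*__", "", tf))
    tracks[[s]] <- setNames(lapply(tf, function(f) {
      g <- read_gff3(f)
      data.frame(strain = s, contig = g$contig, start = g$start,
                 end = g$end, strand = g$strand, predictor = g$source,
                 truth_gene = NA_character_, orf_id = g$gene_id,
                 stringsAsFactors = FALSE)
    }), preds)
  }
  ref_genes <- read_gff3(file.path(dir, "reference", "reference.gff3"))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  genes <- tj$genes
  ref_tab <- data.frame(gene_id = ref_genes$gene_id, strain = "REF",
                        contig = ref_genes$contig, start = ref_genes$start,
                        end = ref_genes$end, strand = ref_genes$strand,
                        stringsAsFactors = FALSE)
  ref_tab$family <- NA_character_
  ord <- order(ref_tab$start)
  ref_tab <- ref_tab[ord, ]
  ref_tab$family <- tj$ref_family_order[seq_len(nrow(ref_tab))]
  df_to_mat <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$strain
    storage.mode(m) <- "integer"
    m
  }
  pl <- if (is.null(tj$phenotype_labels)) NULL else
    df_to_mat(tj$phenotype_labels)
  fp <- df_to_mat(tj$family_presence)
  truth <- structure(list(
    family_of_gene = unlist(tj$family_of_gene),
    island_families = tj$island_families,
    plasmid_contigs = tj$plasmid_contigs,
    phage_intervals = tj$phage_intervals,
    causal_families = tj$causal_families,
    crispr_arrays = tj$crispr_arrays,
    crispr_type = unlist(tj$crispr_type),
    phenotype_labels = pl,
    family_presence = fp,
    ref_family_order = tj$ref_family_order,
    phage_families = tj$phage_families,
    plasmid_families = tj$plasmid_families,
    chrom_contig_order = tj$chrom_contig_order,
    core_families = tj$core_families), class = "truth_set")
  od_path <- file.path(dir, "phenotypes", "od.tsv")
  od <- if (file.exists(od_path)) read_tsv(od_path) else NULL
  structure(list(strains = strains, genomes = genomes,
                 proteins = proteins, tracks = tracks,
                 reference = list(
                   seq = read_fasta(file.path(dir, "reference",
                                              "reference.fna"), "DNA"),
                   genes = ref_tab,
                   proteins = read_fasta(file.path(dir, "reference",
                                                   "reference.faa"), "AA"),
                   circular = TRUE),
                 known_plasmids = read_fasta(
                   file.path(dir, "plasmids", "known_plasmids.fna"), "DNA"),
                 od = od, annotations = unlist(tj$annotations),
                 genes = genes, truth = truth),
            class = "pan_dataset")
}
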