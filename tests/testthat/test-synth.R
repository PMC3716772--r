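test_that("every strain carries one gene from each core family", {
  sim <- small_panel()
  pres <- sim$truth$family_presence
  expect_true(all(pres[, sim$truth$core_families] == 1L))
  for (s in sim$strains) {
    fams <- sim$genes$family[sim$genes$strain == s]
    expect_true(all(sim$truth$core_families %in% fams))
    expect_true(all(table(fams[fams %in% sim$truth$core_families]) == 1))
  }
})

test_that("every emitted gene has exactly one family and a matching CDS", {
  sim <- small_panel()
  expect_setequal(names(sim$truth$family_of_gene), sim$genes$gene_id)
  expect_false(any(duplicated(names(sim$truth$family_of_gene))))
  # spot-check CDS -> protein consistency on a sample of genes
  set.seed(1)
  for (i in sample(nrow(sim$genes), 20)) {
    r <- sim$genes[i, ]
    cds <- Biostrings::subseq(sim$genomes[[r$strain]][[r$contig]],
                              r$start, r$end)
    if (r$strand == "-") cds <- Biostrings::reverseComplement(cds)
    aa <- as.character(Biostrings::translate(cds))
    expect_identical(substr(aa, 1, nchar(aa) - 1),
                     as.character(sim$proteins[[r$gene_id]]))
  }
})

test_that("generation and writing are byte-identical under a fixed seed", {
  cfg <- sim_config(n_strains = 2, n_core_families = 12,
                    n_accessory_families = 8, n_islands = 1,
                    island_size = 4, n_phage_families = 3,
                    fragmentation = 4, seed = 7)
  d1 <- file.path(tempdir(), "panforge_det1")
  d2 <- file.path(tempdir(), "panforge_det2")
  unlink(c(d1, d2), recursive = TRUE)
  write_dataset(simulate_pangenome(cfg), d1)
  write_dataset(simulate_pangenome(cfg), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  md1 <- unname(tools::md5sum(file.path(d1, f1)))
  md2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(md1, md2)
})

test_that("a written dataset reads back losslessly", {
  sim <- small_panel()
  od <- simulate_growth_curves(sim$truth, seed = 3)
  d <- file.path(tempdir(), "panforge_rt")
  unlink(d, recursive = TRUE)
  write_dataset(sim, d, od = od)
  ds <- read_dataset(d)
  expect_identical(lapply(sim$genomes, as.character),
                   lapply(ds$genomes, as.character))
  expect_identical(as.character(sim$proteins), as.character(ds$proteins))
  expect_identical(sim$truth$family_of_gene, ds$truth$family_of_gene)
  expect_identical(unname(sim$truth$phenotype_labels),
                   unname(ds$truth$phenotype_labels))
  expect_equal(sim$genes[, c("gene_id", "contig", "start", "end",
                             "strand", "family")],
               ds$genes[, c("gene_id", "contig", "start", "end",
                            "strand", "family")])
  # GFF3 coordinates are 1-based inclusive: a track row must equal the
  # jitter-free truth interval
  tr <- ds$tracks$S01$pred1
  key <- function(d) paste(d$contig, d$start, d$end, d$strand)
  expect_true(all(key(tr) %in% key(sim$genes[sim$genes$strain == "S01", ])))
})

test_that("accessory presence frequencies follow the configured rate", {
  cfg <- sim_config(n_strains = 30, n_core_families = 5,
                    n_accessory_families = 40, n_islands = 0,
                    island_size = 0, n_phage_families = 0,
                    accessory_presence_prob = 0.3,
                    n_plasmids_per_strain = 0, seed = 13,
                    detail = "presence")
  sim <- simulate_pangenome(cfg)
  acc <- grep("^A", colnames(sim$truth$family_presence), value = TRUE)
  k <- colSums(sim$truth$family_presence[, acc])
  lo <- qbinom(0.005, 30, 0.3)
  hi <- qbinom(0.995, 30, 0.3)
  expect_gte(mean(k >= lo & k <= hi), 0.95)
})

test_that("planted phage GC contrast is recoverable from the contigs", {
  sim <- small_panel()
  expect_gt(length(sim$truth$phage_intervals), 0)
  for (s in names(sim$truth$phage_intervals)) {
    pi <- sim$truth$phage_intervals[[s]]
    sub <- Biostrings::subseq(sim$genomes[[s]][[pi$contig]],
                              pi$start, pi$end)
    gc <- sum(Biostrings::letterFrequency(sub, c("G", "C"))) /
      (pi$end - pi$start + 1)
    expect_lt(abs(gc - sim$config$phage_gc), 0.01)
  }
})

test_that("within-family identity exceeds between-family identity", {
  sim <- small_panel()
  set.seed(1)
  fam <- sim$truth$family_of_gene
  pid <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      sim$proteins[[a]], sim$proteins[[b]], type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 0.5)
    nm <- Biostrings::nmatch(aln)
    nm / (nm + Biostrings::nmismatch(aln))
  }
  for (f in sample(unique(fam), 8)) {
    g <- names(fam)[fam == f]
    if (length(g) < 2) next
    other <- sample(names(fam)[fam != f], 1)
    expect_gt(pid(g[1], g[2]), pid(g[1], other))
  }
})

test_that("growth curves respect labels and the assay design", {
  sim <- small_panel()
  od <- simulate_growth_curves(sim$truth, seed = 5)
  labels <- sim$truth$phenotype_labels
  sugar <- colnames(labels)[1]
  one <- od[od$strain == "S01" & od$sugar == sugar, ]
  expect_equal(nrow(one), 73)           # 24 h at 20-min readings
  expect_equal(range(one$minute), c(0, 1440))
  for (s in rownames(labels)) {
    cur <- od[od$strain == s & od$sugar == sugar, ]
    bl <- od[od$strain == "_blank" & od$sugar == sugar, ]
    peak <- max(cur$od - bl$od[match(cur$minute, bl$minute)])
    if (labels[s, sugar] == 1L) expect_gt(peak, 0.8)
    else expect_lte(peak, 0.8)
  }
})

test_that("inseparable family configurations are rejected", {
  expect_error(sim_config(within_family_divergence = 0.7,
                          between_family_min_divergence = 0.6),
               "separable")
  expect_error(sim_config(accessory_presence_prob = 1.5), "probabilities")
  expect_error(sim_config(n_core_families = 0), "n_core_families")
})
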