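test_that("core-gene distances equal their definition", {
  # three strains, one single-copy OG; B differs from A at 10 of 100
  # residues, C is identical to A
  set.seed(31)
  base <- strsplit(random_aa(1, 100), "")[[1]]
  mutated <- base
  pos <- sample(100, 10)
  for (i in pos) mutated[i] <- sample(setdiff(panforge:::AA20,
                                              mutated[i]), 1)
  prot <- Biostrings::AAStringSet(c(
    "A|g" = paste0(base, collapse = ""),
    "B|g" = paste0(mutated, collapse = ""),
    "C|g" = paste0(base, collapse = "")))
  strain_of <- setNames(c("A", "B", "C"), names(prot))
  ogs <- make_ogs(setNames(rep(1L, 3), names(prot)), strain_of)
  d <- core_distance(ogs, prot, strain_of)
  expect_equal(d["A", "B"], 0.10)
  expect_equal(d["A", "C"], 0)
  expect_equal(d["B", "C"], 0.10)
  expect_true(isSymmetric(d))
})

test_that("multi-OG distances are the length-weighted mean", {
  set.seed(32)
  # OG1: 100 aa, A-B differ at 10; OG2: 50 aa, A-B differ at 20
  mk <- function(len, ndiff) {
    a <- strsplit(random_aa(1, len), "")[[1]]
    b <- a
    for (i in sample(len, ndiff)) b[i] <- sample(setdiff(panforge:::AA20,
                                                         b[i]), 1)
    c(paste0(a, collapse = ""), paste0(b, collapse = ""))
  }
  og1 <- mk(100, 10)
  og2 <- mk(50, 20)
  prot <- Biostrings::AAStringSet(c("A|1" = og1[1], "B|1" = og1[2],
                                    "A|2" = og2[1], "B|2" = og2[2],
                                    "C|1" = og1[1], "C|2" = og2[1]))
  strain_of <- setNames(c("A", "B", "A", "B", "C", "C"), names(prot))
  part <- setNames(c(1L, 1L, 2L, 2L, 1L, 2L), names(prot))
  ogs <- make_ogs(part, strain_of)
  d <- core_distance(ogs, prot, strain_of)
  # direct recomputation from per-OG distances and alignment lengths
  want <- (100 * 0.10 + 50 * 0.40) / 150
  expect_equal(d["A", "B"], want)
})

test_that("neighbor joining recovers additive matrices exactly", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    d <- cophenetic(tr)
    rec <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(cophenetic(rec)[rownames(d), colnames(d)] - d)),
              1e-9)
  }
})

test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  xa <- (d["A", "B"] + d["A", "C"] - d["B", "C"]) / 2
  got <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(unname(got["A"]), xa)
  expect_equal(unname(got["B"]), d["A", "B"] - xa)
  expect_equal(unname(got["C"]), d["A", "C"] - xa)
})

test_that("on ultrametric matrices NJ matches the UPGMA topology", {
  set.seed(34)
  for (rep in 1:10) {
    tr <- ape::rcoal(sample(4:8, 1))       # coalescent = ultrametric
    d <- cophenetic(tr)
    nj_t <- neighbor_joining(d)
    up_t <- ape::as.phylo(hclust(as.dist(d), method = "average"))
    expect_equal(ape::dist.topo(nj_t, ape::unroot(up_t)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative NJ branches are clamped with a warning", {
  # violated triangle inequality forces x_C = (1 + 1 - 10)/2 < 0
  d <- matrix(c(0, 10, 1,
                10, 0, 1,
                1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_warning(tr <- neighbor_joining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("content dendrogram equals a naive average-linkage replay", {
  set.seed(35)
  mat <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5,
                dimnames = list(sprintf("OG%02d", 1:40),
                                paste0("s", 1:5)))
  pm <- structure(list(mat = mat, counts = mat,
                       meta = data.frame(og_id = rownames(mat))),
                  class = "pan_matrix")
  hc <- content_tree(pm)
  want <- avg_linkage_oracle(as.matrix(dist(t(mat), method = "binary")))
  got <- hclust_merges(hc)
  key <- function(l) paste(paste(l$members, collapse = ","),
                           round(l$h, 10))
  expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  # row permutation invariance
  hc2 <- content_tree(structure(list(mat = mat[sample(40), ],
                                     counts = mat, meta = pm$meta),
                                class = "pan_matrix"))
  expect_setequal(vapply(hclust_merges(hc2), key, ""),
                  vapply(got, key, ""))
})

test_that("identical and disjoint content profiles hit the extremes", {
  mat <- cbind(s1 = c(1L, 1L, 0L, 0L), s2 = c(1L, 1L, 0L, 0L),
               s3 = c(0L, 0L, 1L, 1L))
  rownames(mat) <- paste0("OG", 1:4)
  d <- as.matrix(dist(t(mat), method = "binary"))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)
  pm <- structure(list(mat = mat, counts = mat,
                       meta = data.frame(og_id = rownames(mat))),
                  class = "pan_matrix")
  hc <- content_tree(pm)
  expect_equal(sort(hc$height)[1], 0)      # identical pair merges first
})

test_that("newick serialization round-trips, quoting where needed", {
  tr <- ape::rtree(2)
  tr$tip.label <- c("A", "B")
  expect_match(to_newick(tr), "^\\(A:[0-9.]+,B:[0-9.]+\\);$")
  t4 <- ape::rtree(4)
  t4$tip.label <- c("plain", "with space", "quote's", "colon:label")
  txt <- to_newick(t4)
  back <- from_newick(txt)
  expect_setequal(back$tip.label, t4$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(t4)), 0,
               ignore_attr = TRUE)
  # plain round trip preserves branch lengths
  t5 <- ape::rtree(6)
  b5 <- from_newick(to_newick(t5))
  expect_equal(cophenetic(b5)[t5$tip.label, t5$tip.label],
               cophenetic(t5), tolerance = 1e-8)
})

test_that("strains sharing an accessory profile cluster together", {
  # islands-only panel: with two 5-gene islands there are only four
  # possible accessory profiles, so profile sharing is guaranteed
  sim <- simulate_pangenome(sim_config(
    n_strains = 8, n_core_families = 20, n_accessory_families = 10,
    n_islands = 2, island_size = 5, n_phage_families = 0,
    accessory_presence_prob = 0.5, n_plasmids_per_strain = 0,
    label_noise_rate = 0, seed = 36, detail = "presence"))
  pm <- matrix_from_truth(sim$truth)
  hc <- content_tree(pm)
  m <- hclust_merges(hc)
  prof <- apply(sim$truth$family_presence[,
                  !colnames(sim$truth$family_presence) %in%
                    sim$truth$core_families, drop = FALSE], 1, paste,
                collapse = "")
  groups <- split(names(prof), prof)
  groups <- groups[lengths(groups) > 1]
  expect_gt(length(groups), 0)
  merge_height <- function(a, b) {
    min(vapply(m, function(x)
      if (all(c(a, b) %in% x$members)) x$h else Inf, 0))
  }
  for (g in groups) {
    # identical profiles merge at Jaccard distance 0 ...
    expect_equal(merge_height(g[1], g[2]), 0)
    # ... strictly below any merge with a different profile
    other <- setdiff(names(prof), g)[1]
    expect_gt(merge_height(g[1], other), 0)
  }
})
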