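test_that("identical proteins score as identity 1 and keep their edge", {
  set.seed(2)
  p <- random_aa(1, 100)
  prot <- setNames(c(p, p), c("A|g1", "B|g1"))
  e <- score_pairs(prot)
  expect_equal(nrow(e), 1)
  expect_equal(e$identity, 1)
  expect_equal(e$coverage, 1)
  expect_error(score_pairs(setNames(c("", "MK"), c("x", "y"))), "empty")
})

test_that("the k-mer prefilter prunes unrelated pairs", {
  set.seed(3)
  kmers <- function(x, k = 4) {
    n <- nchar(x)
    unique(substring(x, 1:(n - k + 1), k:n))
  }
  shared <- replicate(200, {
    length(intersect(kmers(random_aa(1, 100)), kmers(random_aa(1, 100))))
  })
  expect_gte(mean(shared < 8), 0.99)
  # and score_pairs itself reports no edge for unrelated pairs
  prot <- setNames(random_aa(20, 100), paste0("S", 1:20, "|g"))
  expect_equal(nrow(score_pairs(prot)), 0)
})

test_that("local alignment scores match a dynamic-programming oracle", {
  peptides <- c("MKVLATTHWQERNDFG", "MKVLSTTHWQGRNDFG",
                "HEAGAWGHEE", "PAWHEAE",
                "MADKLWQQNNRETSGA", "MADKWQQNNETSGA")
  pairs <- rbind(c(1, 2), c(3, 4), c(5, 6), c(1, 5))
  for (r in seq_len(nrow(pairs))) {
    a <- peptides[pairs[r, 1]]
    b <- peptides[pairs[r, 2]]
    got <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 0.5))
    expect_equal(got, sw_oracle(a, b), tolerance = 1e-9)
  }
})

test_that("reciprocal-best-hit and in-paralog rules shape the graph", {
  edges <- function(...) {
    d <- rbind(...)
    structure(data.frame(a = d[, 1], b = d[, 2],
                         score = as.numeric(d[, 3]), identity = 0.9,
                         coverage = 1, stringsAsFactors = FALSE),
              class = c("similarity_edges", "data.frame"))
  }
  # two strains, one family each -> single RBH edge
  g1 <- build_graph(edges(c("S1|a", "S2|b", 100)),
                    c("S1|a" = "S1", "S2|b" = "S2"))
  expect_equal(igraph::ecount(g1), 1)
  # A's best hit in strain 2 is B, but B's best in strain 1 is C
  g2 <- build_graph(edges(c("S1|A", "S2|B", 10), c("S1|C", "S2|B", 20)),
                    c("S1|A" = "S1", "S1|C" = "S1", "S2|B" = "S2"))
  el <- igraph::as_data_frame(g2)
  expect_equal(nrow(el), 1)
  expect_setequal(unlist(el[, c("from", "to")]), c("S1|C", "S2|B"))
  # recent duplicates above their cross-strain best keep their edge
  g3 <- build_graph(edges(c("S1|a1", "S1|a2", 50),
                          c("S1|a1", "S2|b", 30),
                          c("S1|a2", "S2|b", 28)),
                    c("S1|a1" = "S1", "S1|a2" = "S1", "S2|b" = "S2"))
  el3 <- igraph::as_data_frame(g3)
  has_edge <- function(el, x, y)
    any((el$from == x & el$to == y) | (el$from == y & el$to == x))
  expect_true(has_edge(el3, "S1|a1", "S1|a2"))
  expect_true(has_edge(el3, "S1|a1", "S2|b"))
  expect_false(has_edge(el3, "S1|a2", "S2|b"))
})

barbell_graph <- function(weak = 0.05) {
  el <- rbind(c("a1", "a2", 1), c("a1", "a3", 1), c("a2", "a3", 1),
              c("b1", "b2", 1), c("b1", "b3", 1), c("b2", "b3", 1),
              c("a3", "b1", weak))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2],
               weight = as.numeric(el[, 3])), directed = FALSE)
  g
}

test_that("MCL separates weakly joined cliques like the naive iteration", {
  g <- barbell_graph()
  part <- mcl_cluster(g, inflation = 1.5)
  expect_true(attr(part, "converged"))
  # oracle: dense whole-matrix iteration
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  oracle <- mcl_oracle(A, inflation = 1.5)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(oracle)), 2)
  same_cluster <- function(p, x, y) p[x] == p[y]
  for (pair in list(c("a1", "a2"), c("a1", "a3"), c("b1", "b2"))) {
    expect_equal(same_cluster(part, pair[1], pair[2]),
                 same_cluster(oracle, pair[1], pair[2]))
  }
  expect_false(same_cluster(part, "a1", "b1"))
})

test_that("MCL refines connected components and handles singletons", {
  # two disjoint triangles -> exactly their vertex sets
  el <- data.frame(from = c("a1", "a1", "a2", "b1", "b1", "b2"),
                   to = c("a2", "a3", "a3", "b2", "b3", "b3"),
                   weight = 1)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "lonely")
  part <- mcl_cluster(g)
  expect_equal(length(unique(part)), 3)
  expect_equal(length(unique(part[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(part[c("b1", "b2", "b3")])), 1)
  expect_false(part["a1"] == part["b1"])
  expect_equal(unname(table(part)[as.character(part["lonely"])]), 1L)
  # property: partitions refine components on random graphs
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    rg <- igraph::sample_gnp(n, 0.3)
    igraph::V(rg)$name <- paste0("v", seq_len(n))
    igraph::E(rg)$weight <- runif(igraph::ecount(rg), 0.2, 1)
    p <- mcl_cluster(rg)
    comp <- igraph::components(rg)$membership
    # genes in one MCL cluster always share a component
    for (cl in unique(p)) {
      expect_equal(length(unique(comp[names(p)[p == cl]])), 1)
    }
  }
  # determinism
  expect_identical(mcl_cluster(barbell_graph()),
                   mcl_cluster(barbell_graph()))
})

test_that("ortholog groups recover the planted families exactly", {
  sim <- small_panel()
  ogs <- infer_orthologs(sim$proteins,
                         annotations = setNames(sim$genes$annotation,
                                                sim$genes$gene_id))
  part <- setNames(rep(names(ogs$members), lengths(ogs$members)),
                   unlist(ogs$members))
  fam <- sim$truth$family_of_gene[names(part)]
  expect_equal(ari_oracle(part, fam), 1)
  # partition property: every protein in exactly one OG
  expect_setequal(names(part), names(sim$proteins))
  expect_false(any(duplicated(unlist(ogs$members))))
  # per-strain copy counts: small panel has single-copy families only
  expect_true(all(ogs$counts %in% c(0L, 1L)))
})

test_that("OG bookkeeping flags single-copy core and singleton groups", {
  strain_of <- c("S1|a" = "S1", "S2|a" = "S2", "S1|b" = "S1",
                 "S1|b2" = "S1", "S2|b" = "S2", "S1|c" = "S1")
  part <- c("S1|a" = 1L, "S2|a" = 1L, "S1|b" = 2L, "S1|b2" = 2L,
            "S2|b" = 2L, "S1|c" = 3L)
  ogs <- make_ogs(part, strain_of,
                  annotations = c("S1|a" = "x", "S2|a" = "x",
                                  "S1|b" = "y", "S1|b2" = "z",
                                  "S2|b" = "y", "S1|c" = "w"))
  expect_equal(nrow(ogs$og), 3)
  expect_equal(ogs$og$single_copy, c(TRUE, FALSE, FALSE))
  expect_equal(ogs$og$singleton, c(FALSE, FALSE, TRUE))
  expect_equal(ogs$counts["OG00002", "S1"], 2L)   # duplicate counted
  expect_equal(ogs$og$annotation[2], "y")         # majority annotation
  # empty partition -> empty OG set
  expect_equal(nrow(make_ogs(setNames(integer(0), character(0)),
                             strain_of)$og), 0)
})
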