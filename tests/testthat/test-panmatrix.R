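og_fixture <- function(counts) {
  og <- data.frame(og_id = rownames(counts),
                   n_genes = rowSums(counts),
                   n_strains = rowSums(counts > 0),
                   single_copy = apply(counts, 1, function(x) all(x == 1)),
                   singleton = rowSums(counts) == 1,
                   annotation = rep(NA_character_, nrow(counts)),
                   stringsAsFactors = FALSE)
  structure(list(og = og, members = list(), counts = counts),
            class = "og_set")
}

test_that("presence is binary and singleton rows follow the flag", {
  counts <- matrix(c(2L, 1L, 1L,
                     1L, 0L, 0L,
                     0L, 3L, 1L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("OG1", "OG2", "OG3"),
                                   c("s1", "s2", "s3")))
  ogs <- og_fixture(counts)
  pm <- build_matrix(ogs)
  expect_equal(pm$mat["OG1", "s1"], 1L)      # 2 copies -> presence 1
  expect_false("OG2" %in% rownames(pm$mat))  # singleton dropped
  pm2 <- build_matrix(ogs, include_singletons = TRUE)
  expect_true("OG2" %in% rownames(pm2$mat))
  # unknown strain -> zero column with warning
  expect_warning(pm3 <- build_matrix(ogs, strains = c("s1", "s2", "s3",
                                                      "s4")),
                 "absent")
  expect_equal(unname(pm3$mat[, "s4"]), rep(0L, nrow(pm3$mat)))
  # empty OG set -> 0-row matrix
  empty <- og_fixture(matrix(0L, 0, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(nrow(build_matrix(empty)$mat), 0)
})

test_that("accumulation curves are monotone and match set algebra", {
  sim <- small_panel()
  pm <- matrix_from_truth(sim$truth)
  curves <- accumulation_curves(pm, n_permutations = 50, seed = 4)
  # per-permutation monotonicity, not just means
  for (p in seq_len(nrow(curves$pan))) {
    expect_true(all(diff(curves$pan[p, ]) >= 0))
    expect_true(all(diff(curves$core[p, ]) <= 0))
    expect_equal(curves$pan[p, 1], curves$core[p, 1])  # pan(1) = core(1)
  }
  n <- ncol(pm$mat)
  # at n = all strains the curve equals the matrix row algebra
  expect_true(all(curves$pan[, n] == sum(rowSums(pm$mat) > 0)))
  expect_true(all(curves$core[, n] == sum(rowSums(pm$mat) == n)))
  # one fixed ordering replayed with a brute-force union/intersection
  set.seed(4)
  ord <- sample.int(n)
  pan_bf <- core_bf <- integer(n)
  for (i in seq_len(n)) {
    sub <- pm$mat[, ord[seq_len(i)], drop = FALSE]
    pan_bf[i] <- sum(rowSums(sub) > 0)
    core_bf[i] <- sum(rowSums(sub) == i)
  }
  expect_equal(unname(curves$pan[1, ]), pan_bf)
  expect_equal(unname(curves$core[1, ]), core_bf)
  expect_error(accumulation_curves(pm, n_permutations = 0), "permutations")
})

test_that("the inferred core matches the realized truth core", {
  sim <- small_panel()
  ogs <- infer_orthologs(sim$proteins)
  pm <- build_matrix(ogs)
  core_ogs <- rownames(pm$mat)[rowSums(pm$mat) == ncol(pm$mat)]
  # realized core: families the generator actually placed in all strains
  pres <- sim$truth$family_presence
  realized <- colnames(pres)[colSums(pres) == nrow(pres)]
  expect_equal(length(core_ogs), length(realized))
  expect_true(all(sim$truth$core_families %in% realized))
})

test_that("single-copy core selection demands exactly one copy everywhere", {
  counts <- matrix(c(1L, 1L, 1L,
                     2L, 1L, 1L,
                     1L, 0L, 1L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("OGa", "OGb", "OGc"),
                                   c("s1", "s2", "s3")))
  pm <- build_matrix(og_fixture(counts), include_singletons = TRUE)
  expect_equal(single_copy_core(pm), "OGa")
})

test_that("variable-region detection finds planted islands and respects
           the run-length boundary", {
  # 30 core OGs at presence 1 with a 12-OG island at presence 0.3
  n_strain <- 10
  core <- matrix(1L, 30, n_strain)
  island <- matrix(rbinom(12 * n_strain, 1, 0.3), 12, n_strain)
  mat <- rbind(core[1:15, ], island, core[16:30, ])
  rownames(mat) <- sprintf("OG%02d", seq_len(nrow(mat)))
  colnames(mat) <- paste0("s", seq_len(n_strain))
  pm <- structure(list(mat = mat, counts = mat,
                       meta = data.frame(og_id = rownames(mat))),
                  class = "pan_matrix")
  ranks <- setNames(seq_len(nrow(mat)), rownames(mat))
  reg <- find_variable_regions(pm, ranks, min_run = 10,
                               max_presence = 0.9)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$rank_start, 16)
  expect_equal(reg$rank_end, 27)
  expect_equal(reg$n_og, 12)
  # run one shorter than min_run is not reported
  reg2 <- find_variable_regions(pm, ranks, min_run = 13,
                                max_presence = 0.9)
  expect_equal(nrow(reg2), 0)
  # all-core ordering -> no regions
  pm_core <- structure(list(mat = core, counts = core,
                            meta = data.frame(og_id = 1:30)),
                       class = "pan_matrix")
  rownames(pm_core$mat) <- sprintf("C%02d", 1:30)
  expect_equal(nrow(find_variable_regions(
    pm_core, setNames(1:30, rownames(pm_core$mat)))), 0)
})

test_that("cassette presence follows the completeness threshold", {
  mat <- rbind(OGx = c(1L, 1L, 0L), OGy = c(1L, 0L, 0L),
               OGz = c(1L, 1L, 0L), OGw = c(1L, 1L, 1L))
  colnames(mat) <- c("s1", "s2", "s3")
  pm <- structure(list(mat = mat, counts = mat,
                       meta = data.frame(og_id = rownames(mat))),
                  class = "pan_matrix")
  cas <- cassette_presence(pm, list(lac = c("OGx", "OGy", "OGz")),
                           min_fraction = 0.8)
  expect_equal(unname(cas["lac", ]), c(1L, 0L, 0L))
  cas2 <- cassette_presence(pm, list(lac = c("OGx", "OGy", "OGz")),
                            min_fraction = 0.6)
  expect_equal(unname(cas2["lac", ]), c(1L, 1L, 0L))
})
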