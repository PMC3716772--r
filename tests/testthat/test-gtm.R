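test_that("growth calls apply the strict 0.8 threshold after blanking", {
  minutes <- seq(0, 1440, by = 20)
  mk <- function(strain, sugar, peak) {
    data.frame(strain = strain, sugar = sugar, minute = minutes,
               od = seq(0.05, peak, length.out = length(minutes)))
  }
  od <- rbind(
    data.frame(strain = "_blank", sugar = "lactose", minute = minutes,
               od = 0.05),
    mk("S1", "lactose", 1.00),   # corrected peak 0.95 -> growth
    mk("S2", "lactose", 0.85),   # corrected peak exactly 0.80 -> no
    mk("S3", "lactose", 0.50))
  ph <- call_growth(od)
  expect_equal(unname(ph["S1", "lactose"]), "growth")
  expect_equal(unname(ph["S2", "lactose"]), "no_growth")
  expect_equal(unname(ph["S3", "lactose"]), "no_growth")
  # strain with no readings for a sugar -> missing
  od2 <- rbind(od, mk("S4", "ribose", 1.2),
               data.frame(strain = "_blank", sugar = "ribose",
                          minute = minutes, od = 0.05))
  expect_message(ph2 <- call_growth(od2), "missing")
  expect_equal(unname(ph2["S1", "ribose"]), "missing")
  expect_equal(unname(ph2["S4", "ribose"]), "growth")
})

test_that("the colour rule matches its printed boundaries", {
  expect_equal(color_classify(0.80), "green")
  expect_equal(color_classify(0.20), "red")
  expect_equal(color_classify(0.50), "black")
  expect_equal(color_classify(0.75), "black")   # strictly greater
  expect_equal(color_classify(0.25), "black")   # strictly smaller
  expect_equal(color_classify(c(1, 0)), c("green", "red"))
  expect_error(color_classify(1.2))
})

gtm_fixture <- function(n_strain = 30, n_noise = 200, seed = 51) {
  set.seed(seed)
  strains <- sprintf("S%02d", seq_len(n_strain))
  causal <- rbinom(n_strain, 1, 0.5)
  mat <- matrix(rbinom(n_noise * n_strain, 1, 0.4), n_noise, n_strain,
                dimnames = list(sprintf("NOISE%03d", seq_len(n_noise)),
                                strains))
  mat <- rbind(CAUSAL = causal, ALWAYS = rep(1L, n_strain), mat)
  pm <- structure(list(mat = mat, counts = mat,
                       meta = data.frame(og_id = rownames(mat))),
                  class = "pan_matrix")
  phen <- matrix(ifelse(causal == 1, "growth", "no_growth"), n_strain, 1,
                 dimnames = list(strains, "lactose"))
  list(pm = pm, phen = phen, causal = causal)
}

test_that("a perfectly matching OG dominates the importance ranking", {
  fx <- gtm_fixture()
  res <- gene_trait_match(fx$pm, fx$phen, "lactose", n_trees = 500,
                          seed = 1)
  expect_equal(res$selected$og_id[1], "CAUSAL")
  expect_gt(res$selected$importance[1], 0.005)
  expect_equal(res$selected$color[1], "green")
  expect_equal(res$n_pos + res$n_neg, 30)
  # importances are a distribution over features
  expect_true(all(res$importance >= 0))
  expect_equal(sum(res$importance), 1, tolerance = 1e-9)
  # determinism under the seed
  res2 <- gene_trait_match(fx$pm, fx$phen, "lactose", n_trees = 500,
                           seed = 1)
  expect_identical(res$selected, res2$selected)
})

test_that("constant OGs carry zero importance and are never selected", {
  fx <- gtm_fixture()
  res <- gene_trait_match(fx$pm, fx$phen, "lactose", n_trees = 300,
                          seed = 2)
  expect_equal(unname(res$importance["ALWAYS"]), 0)
  expect_false("ALWAYS" %in% res$selected$og_id)
})

test_that("degenerate phenotype tables are refused", {
  fx <- gtm_fixture()
  mono <- fx$phen
  mono[, 1] <- "growth"
  expect_error(gene_trait_match(fx$pm, mono, "lactose"), "single")
  expect_error(gene_trait_match(fx$pm, fx$phen, "nosuchsugar"), "unknown")
  tiny <- fx$phen
  tiny[2:30, 1] <- "no_growth"
  expect_error(gene_trait_match(fx$pm, tiny, "lactose"), "2 strains")
})

test_that("permuted labels do not select more OGs than the real ones", {
  # the 0.005 importance threshold is calibrated for pan-genome-sized
  # matrices (~4000 OGs, where it is ~20x the mean importance), so the
  # permutation null is probed at that scale: a 10-OG causal cassette
  # among 4000 noise OGs
  set.seed(52)
  n_strain <- 30
  strains <- sprintf("S%02d", seq_len(n_strain))
  causal <- rbinom(n_strain, 1, 0.5)
  mat <- rbind(
    matrix(rep(causal, 10), 10, n_strain, byrow = TRUE,
           dimnames = list(sprintf("CAS%02d", 1:10), strains)),
    matrix(rbinom(4000 * n_strain, 1, 0.4), 4000, n_strain,
           dimnames = list(sprintf("N%04d", 1:4000), strains)))
  pm <- structure(list(mat = mat, counts = mat,
                       meta = data.frame(og_id = rownames(mat))),
                  class = "pan_matrix")
  phen <- matrix(ifelse(causal == 1, "growth", "no_growth"), n_strain, 1,
                 dimnames = list(strains, "lactose"))
  real <- gene_trait_match(pm, phen, "lactose", n_trees = 300, seed = 3)
  expect_true(startsWith(real$selected$og_id[1], "CAS"))
  expect_gte(sum(startsWith(real$selected$og_id, "CAS")), 8)
  set.seed(4)
  n_perm <- vapply(1:5, function(i) {
    ph <- phen
    ph[, 1] <- sample(ph[, 1])
    nrow(gene_trait_match(pm, ph, "lactose", n_trees = 300,
                          seed = 100 + i)$selected)
  }, 0L)
  expect_lte(median(n_perm), nrow(real$selected))
})

test_that("report generation skips uninformative traits and writes files", {
  fx <- gtm_fixture()
  phen <- cbind(fx$phen,
                matrix("growth", 30, 1,
                       dimnames = list(rownames(fx$phen), "glucose")))
  expect_message(rep <- gtm_report(fx$pm, phen, n_trees = 200, seed = 5),
                 "skipped")
  expect_named(rep, "lactose")
  out <- file.path(tempdir(), "gtm_out")
  unlink(out, recursive = TRUE)
  paths <- write_gtm_report(rep, out)
  expect_true(file.exists(file.path(out, "gtm_lactose.tsv")))
  expect_true(file.exists(file.path(out, "gtm_summary.html")))
  tab <- read_tsv(file.path(out, "gtm_lactose.tsv"))
  expect_equal(tab$og_id[1], "CAUSAL")
})
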