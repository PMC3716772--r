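#' Gene presence/absence matrix and pan/core statistics
#'
#' The presence/absence matrix has one row per ortholog group (OG) and one
#' column per strain; an entry is 1 iff the OG has at least one member
#' gene in that strain (copy number is kept separately as metadata).
#' Singleton OGs — one gene in a single genome — are excluded from
#' pan-genome counting by default, following the usual convention for
#' accumulation curves.
#'
#' @name panmatrix
NULL

#' Build the presence/absence matrix
#'
#' @param ogs an `og_set` from [make_ogs()].
#' @param strains strain universe (defaults to the OG set's strains; a
#'   strain named here but absent from the OGs yields an all-zero column
#'   with a warning).
#' @param include_singletons keep OGs with a single gene in a single
#'   genome (default FALSE).
#' @return object of class `pan_matrix`: `mat` (binary OG x strain),
#'   `counts` (copy numbers), `meta` (OG metadata incl. annotation).
#' @export
build_matrix <- function(ogs, strains = colnames(ogs$counts),
                         include_singletons = FALSE) {
  counts <- ogs$counts
  missing <- setdiff(strains, colnames(counts))
  if (length(missing) > 0) {
    warning("strain(s) absent from the OG universe: ",
            paste(missing, collapse = ", "))
    add <- matrix(0L, nrow(counts), length(missing),
                  dimnames = list(rownames(counts), missing))
    counts <- cbind(counts, add)
  }
  counts <- counts[, strains, drop = FALSE]
  keep <- if (include_singletons) rep(TRUE, nrow(ogs$og)) else
    !ogs$og$singleton
  counts <- counts[keep, , drop = FALSE]
  mat <- (counts > 0) + 0L
  structure(list(mat = mat, counts = counts,
                 meta = ogs$og[keep, , drop = FALSE]),
            class = "pan_matrix")
}

#' Pan- and core-genome accumulation curves
#'
#' For each of `n_permutations` random strain orderings, pan(n) is the
#' number of OGs present in at least one of the first n genomes and
#' core(n) the number present in all of them; means and standard
#' deviations over permutations are reported together with the
#' per-permutation values.
#'
#' @param pm a `pan_matrix`.
#' @param n_permutations number of random genome orderings.
#' @param seed RNG seed.
#' @return object of class `accumulation_curve`: `summary` (data.frame
#'   `n_genomes`, `pan_mean`, `pan_sd`, `core_mean`, `core_sd`), `pan`,
#'   `core` (permutation x n matrices), `n_permutations`, `seed`.
#' @export
accumulation_curves <- function(pm, n_permutations = 100, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  mat <- pm$mat
  n <- ncol(mat)
  if (n < 1) stop("at least one strain required")
  set.seed(seed)
  pan <- matrix(0L, n_permutations, n)
  core <- matrix(0L, n_permutations, n)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, nrow(mat))
    inall <- rep(TRUE, nrow(mat))
    for (i in seq_len(n)) {
      v <- mat[, ord[i]] > 0
      seen <- seen | v
      inall <- inall & v
      pan[p, i] <- sum(seen)
      core[p, i] <- sum(inall)
    }
  }
  summary <- data.frame(n_genomes = seq_len(n),
                        pan_mean = colMeans(pan),
                        pan_sd = apply(pan, 2, stats::sd),
                        core_mean = colMeans(core),
                        core_sd = apply(core, 2, stats::sd))
  structure(list(summary = summary, pan = pan, core = core,
                 n_permutations = n_permutations, seed = seed),
            class = "accumulation_curve")
}

#' Single-copy core OGs
#'
#' OGs with exactly one member gene in every strain — the substrate for
#' concatenated core-gene phylogenies.
#'
#' @param pm a `pan_matrix` (copy counts are taken from it).
#' @return character vector of OG ids.
#' @export
single_copy_core <- function(pm) {
  rownames(pm$counts)[apply(pm$counts, 1, function(x) all(x == 1L))]
}

#' Detect variable regions in pseudo-assembly order
#'
#' Orders OGs by their reference-projected rank (see
#' [pseudo_assemble()]) and reports maximal runs of at least `min_run`
#' consecutive OGs whose presence frequency across strains is at most
#' `max_presence` — the "highly variable regions" (islands) of the
#' pan-genome.
#'
#' @param pm a `pan_matrix`.
#' @param og_ranks named numeric vector OG id -> rank in reference order;
#'   OGs without a rank are ignored.
#' @param min_run minimum number of consecutive variable OGs.
#' @param max_presence maximum presence fraction for an OG to count as
#'   variable.
#' @return data.frame: `region`, `rank_start`, `rank_end`, `n_og`,
#'   `mean_presence`, `og_ids` (comma-joined).
#' @export
find_variable_regions <- function(pm, og_ranks, min_run = 10,
                                  max_presence = 0.9) {
  empty <- data.frame(region = integer(), rank_start = numeric(),
                      rank_end = numeric(), n_og = integer(),
                      mean_presence = numeric(), og_ids = character(),
                      stringsAsFactors = FALSE)
  ranked <- intersect(names(sort(og_ranks)), rownames(pm$mat))
  if (length(ranked) == 0) return(empty)
  pres <- rowMeans(pm$mat[ranked, , drop = FALSE])
  varflag <- pres <= max_presence
  r <- rle(varflag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_run) next
    idx <- starts[i]:ends[i]
    ogs <- ranked[idx]
    out[[length(out) + 1L]] <- data.frame(
      region = length(out) + 1L,
      rank_start = unname(og_ranks[ogs[1]]),
      rank_end = unname(og_ranks[ogs[length(ogs)]]),
      n_og = length(ogs),
      mean_presence = mean(pres[idx]),
      og_ids = paste(ogs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Presence/absence matrix straight from a generator TruthSet
#'
#' Parameter-recovery experiments that probe matrix-level stages (curves,
#' content trees, gene-trait matching) can skip gene calling and ortholog
#' inference and use the planted family presence directly: each planted
#' family becomes one OG row.
#'
#' @param truth a `truth_set`.
#' @param include_plasmids keep plasmid-replicon families as rows.
#' @return a `pan_matrix` whose rows are family ids.
#' @export
matrix_from_truth <- function(truth, include_plasmids = TRUE) {
  mat <- t(truth$family_presence)
  if (!include_plasmids && length(truth$plasmid_families) > 0) {
    mat <- mat[!rownames(mat) %in% unlist(truth$plasmid_families), ,
               drop = FALSE]
  }
  meta <- data.frame(og_id = rownames(mat),
                     n_strains = as.integer(rowSums(mat > 0)),
                     stringsAsFactors = FALSE)
  structure(list(mat = mat, counts = mat, meta = meta),
            class = "pan_matrix")
}

#' Phenotype table straight from a generator TruthSet
#'
#' @param truth a `truth_set` with `phenotype_labels`.
#' @return a `phenotype_table` (strain x sugar, `"growth"`/`"no_growth"`).
#' @export
phenotypes_from_truth <- function(truth) {
  if (is.null(truth$phenotype_labels)) stop("truth has no phenotype labels")
  lab <- truth$phenotype_labels
  out <- ifelse(lab == 1L, "growth", "no_growth")
  structure(out, class = c("phenotype_table", class(out)))
}

#' Cassette presence table
#'
#' A cassette (a named set of OGs, e.g. a sugar-utilization gene cluster)
#' is called present in a strain iff at least `min_fraction` of its OGs
#' are present there.
#'
#' @param pm a `pan_matrix`.
#' @param cassettes named list of OG id vectors.
#' @param min_fraction completeness threshold.
#' @return binary matrix cassette x strain.
#' @export
cassette_presence <- function(pm, cassettes, min_fraction = 0.8) {
  out <- matrix(0L, length(cassettes), ncol(pm$mat),
                dimnames = list(names(cassettes), colnames(pm$mat)))
  for (i in seq_along(cassettes)) {
    ogs <- intersect(cassettes[[i]], rownames(pm$mat))
    if (length(ogs) == 0) next
    frac <- colMeans(pm$mat[ogs, , drop = FALSE])
    out[i, ] <- as.integer(frac >= min_fraction)
  }
  out
}
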