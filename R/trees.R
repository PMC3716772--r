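#' Strain trees: core-gene distances and gene-content clustering
#'
#' Two complementary views of strain relatedness: (A) a sequence tree from
#' single-copy core genes — per-OG pairwise global alignment distances
#' (1 - fractional identity), length-weighted across OGs, then
#' neighbor-joining; and (B) a genome-content dendrogram — Jaccard
#' distance between OG presence/absence vectors with agglomerative
#' hierarchical clustering.  Congruence (or lack of it) between the two
#' is the classic signal for horizontal gene transfer and niche-driven
#' gene gain/loss.
#'
#' @name trees
NULL

#' Core-gene distance matrix
#'
#' For every single-copy core OG, pairwise distances between strains are
#' computed as 1 - fractional identity of a global (Needleman-Wunsch)
#' alignment of the two member proteins; the strain distance is the
#' alignment-length-weighted mean over OGs.
#'
#' @param ogs an `og_set`.
#' @param proteins [Biostrings::AAStringSet] covering all member genes.
#' @param strain_of named vector gene id -> strain.
#' @param og_ids which OGs to use; defaults to all single-copy core OGs.
#' @return symmetric distance matrix (class `dist` attributes not used;
#'   plain matrix with zero diagonal).
#' @export
core_distance <- function(ogs, proteins, strain_of,
                          og_ids = ogs$og$og_id[ogs$og$single_copy]) {
  strains <- sort(unique(unname(strain_of)))
  if (length(strains) < 3) stop("at least 3 strains required")
  if (length(og_ids) < 1) stop("at least one single-copy core OG required")
  n <- length(strains)
  acc <- matrix(0, n, n, dimnames = list(strains, strains))
  wsum <- matrix(0, n, n, dimnames = list(strains, strains))
  pr <- combn(n, 2)
  # one element-wise batch alignment over all (OG, strain pair) combos
  pat <- character(0)
  sub <- character(0)
  pi <- integer(0)
  pj <- integer(0)
  for (og in og_ids) {
    g <- ogs$members[[og]]
    so <- strain_of[g]
    g <- g[match(strains, so)]        # one gene per strain, strain order
    aa <- as.character(proteins[g])
    pat <- c(pat, aa[pr[1, ]])
    sub <- c(sub, aa[pr[2, ]])
    pi <- c(pi, pr[1, ])
    pj <- c(pj, pr[2, ])
  }
  chunk <- 5000L
  for (off in seq(1L, length(pat), by = chunk)) {
    idx <- off:min(off + chunk - 1L, length(pat))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pat[idx]),
      Biostrings::AAStringSet(sub[idx]), type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    w <- Biostrings::nchar(aln)        # alignment length incl. gaps
    d <- 1 - nm / (nm + nmm)
    ii <- cbind(pi[idx], pj[idx])
    for (r in seq_along(idx)) {
      acc[ii[r, 1], ii[r, 2]] <- acc[ii[r, 1], ii[r, 2]] + w[r] * d[r]
      wsum[ii[r, 1], ii[r, 2]] <- wsum[ii[r, 1], ii[r, 2]] + w[r]
    }
  }
  dm <- matrix(0, n, n, dimnames = list(strains, strains))
  up <- upper.tri(dm)
  dm[up] <- ifelse(wsum[up] > 0, acc[up] / wsum[up], 0)
  dm <- dm + t(dm)
  dm
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (Saitou-Nei Q-criterion, as implemented in
#' ape) on a symmetric distance matrix; negative branch lengths, which NJ
#' can produce on non-additive input, are clamped to zero with a warning.
#'
#' @param d symmetric distance matrix with strain labels.
#' @return unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (nrow(as.matrix(d)) < 3) stop("at least 3 taxa required")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Genome-content dendrogram
#'
#' Jaccard distance (1 - shared/union) between strains' OG presence
#' vectors, clustered agglomeratively (`average` linkage by default, i.e.
#' UPGMA on content distances).
#'
#' @param pm a `pan_matrix`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an `hclust` dendrogram (rooted, with merge heights).
#' @export
content_tree <- function(pm, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (ncol(pm$mat) < 2) stop("at least 2 strains required")
  d <- dist(t(pm$mat), method = "binary")   # exact Jaccard on 0/1 vectors
  hclust(d, method = linkage)
}

#' Serialize a tree as Newick text
#'
#' Handles both `phylo` (NJ) and `hclust` (content dendrogram) trees.
#' Labels containing characters outside the safe Newick set are
#' single-quoted so that they survive a parse round-trip.
#'
#' @param tree `phylo` or `hclust`.
#' @return single Newick string (with trailing `;`).
#' @export
to_newick <- function(tree) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) stop("unsupported tree object")
  labs <- tree$tip.label
  unsafe <- !grepl("^[A-Za-z0-9_.|-]+$", labs)
  if (any(unsafe)) {
    ph <- sprintf("PANFORGETIP%dX", seq_along(labs))
    tree$tip.label <- ifelse(unsafe, ph, labs)
    txt <- ape::write.tree(tree)
    for (i in which(unsafe)) {
      quoted <- paste0("'", gsub("'", "''", labs[i]), "'")
      txt <- sub(ph[i], quoted, txt, fixed = TRUE)
    }
    return(txt)
  }
  ape::write.tree(tree)
}

#' Parse Newick text
#'
#' Quoted labels (single quotes, `''` escaping an embedded quote) are
#' lexed out and restored after parsing, since ape's reader does not
#' handle them reliably.
#'
#' @param text Newick string.
#' @return `phylo` tree.
#' @export
from_newick <- function(text) {
  m <- gregexpr("'([^']|'')*'", text)[[1]]
  labs <- character(0)
  if (m[1] != -1) {
    tokens <- regmatches(text, gregexpr("'([^']|'')*'", text))[[1]]
    labs <- gsub("''", "'", substr(tokens, 2, nchar(tokens) - 1))
    for (i in seq_along(tokens)) {
      text <- sub(tokens[i], sprintf("PANFORGETIP%dX", i), text,
                  fixed = TRUE)
    }
  }
  tr <- ape::read.tree(text = text)
  if (length(labs) > 0) {
    for (i in seq_along(labs)) {
      ph <- sprintf("PANFORGETIP%dX", i)
      tr$tip.label[tr$tip.label == ph] <- labs[i]
      if (!is.null(tr$node.label)) {
        tr$node.label[tr$node.label == ph] <- labs[i]
      }
    }
  }
  tr
}
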