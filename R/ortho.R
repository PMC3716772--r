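#' Ortholog-group inference
#'
#' Desk-scale replacement for the classical BLASTP + OrthoMCL route: an
#' exact-k-mer prefilter prunes the all-vs-all pair space, surviving pairs
#' are scored by Smith-Waterman local alignment (BLOSUM62, affine gaps),
#' an orthology graph is built from reciprocal best hits between strains
#' plus in-paralog edges within strains, and Markov clustering (MCL) with
#' the customary inflation 1.5 partitions the graph into ortholog groups.
#'
#' @name ortho
NULL

protein_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

#' Score candidate protein pairs
#'
#' All-vs-all comparison with a shared-k-mer prefilter: only pairs sharing
#' at least `min_shared_kmers` distinct k-mers (default k = 4) are aligned.
#' Surviving pairs are scored with local alignment (BLOSUM62, affine gap
#' penalties); edges are kept when the score or the identity/coverage
#' criterion passes.
#'
#' Identity is computed over aligned residue pairs
#' (matches / (matches + mismatches)) and coverage as aligned residue
#' pairs relative to the shorter sequence.
#'
#' @param proteins named character vector or [Biostrings::AAStringSet].
#' @param k k-mer size of the prefilter.
#' @param min_shared_kmers prefilter threshold on shared distinct k-mers.
#' @param score_cutoff keep an edge if alignment score >= this, or
#' @param id_cutoff ... identity >= `id_cutoff` over coverage >=
#'   `cov_cutoff` of the shorter sequence.
#' @param cov_cutoff see `id_cutoff`.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return data.frame of class `similarity_edges`: `a`, `b` (canonical
#'   order `a < b`), `score`, `identity`, `coverage`.
#' @export
score_pairs <- function(proteins, k = 4, min_shared_kmers = 8,
                        score_cutoff = 50, id_cutoff = 0.4,
                        cov_cutoff = 0.5,
                        gap_opening = 10, gap_extension = 0.5) {
  if (methods::is(proteins, "XStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  if (length(proteins) == 0) stop("empty protein set")
  if (any(nchar(proteins) == 0)) stop("empty sequences are not allowed")
  ids <- names(proteins)
  kl <- lapply(proteins, protein_kmers, k = k)
  pool <- unique(unlist(kl, use.names = FALSE))
  ii <- rep.int(seq_along(kl), lengths(kl))
  jj <- match(unlist(kl, use.names = FALSE), pool)
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(kl), length(pool)))
  S <- Matrix::tcrossprod(X)
  S <- Matrix::triu(S, k = 1)
  hit <- Matrix::which(S >= min_shared_kmers, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(structure(data.frame(a = character(), b = character(),
                                score = numeric(), identity = numeric(),
                                coverage = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("similarity_edges", "data.frame")))
  }
  # element-wise batch alignment of all surviving pairs (chunked to keep
  # per-call memory modest)
  rows <- list()
  aa <- Biostrings::AAStringSet(proteins)
  chunk <- 5000L
  for (off in seq(1L, nrow(hit), by = chunk)) {
    idx <- off:min(off + chunk - 1L, nrow(hit))
    is <- hit[idx, 1]
    js <- hit[idx, 2]
    aln <- Biostrings::pairwiseAlignment(
      aa[is], aa[js], type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    sc <- Biostrings::score(aln)
    shorter <- pmin(nchar(proteins[is]), nchar(proteins[js]))
    idf <- ifelse(nm + nmm > 0, nm / (nm + nmm), 0)
    cov <- (nm + nmm) / shorter
    keep <- sc >= score_cutoff | (idf >= id_cutoff & cov >= cov_cutoff)
    if (any(keep)) {
      a <- ids[is][keep]; b <- ids[js][keep]
      swap <- a > b
      rows[[length(rows) + 1L]] <- data.frame(
        a = ifelse(swap, b, a), b = ifelse(swap, a, b),
        score = sc[keep], identity = idf[keep], coverage = cov[keep],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), score = numeric(),
               identity = numeric(), coverage = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("similarity_edges", "data.frame"))
}

#' Build the orthology graph from similarity edges
#'
#' Inter-strain edges are kept iff they are reciprocal best hits: each
#' endpoint's score equals its best score into the other endpoint's strain
#' (ties kept).  Intra-strain edges are kept as in-paralog edges iff their
#' score is at least both endpoints' best inter-strain score (genes
#' without any inter-strain hit keep all their intra-strain edges).
#' Edge weights are normalized to \[0, 1\] by the maximum retained score.
#'
#' @param edges `similarity_edges` from [score_pairs()].
#' @param strain_of named character vector gene id -> strain; its names
#'   define the node universe (isolated genes become singleton nodes).
#' @return [igraph] undirected graph with `weight` edge attribute.
#' @export
build_graph <- function(edges, strain_of) {
  genes <- names(strain_of)
  e <- as.data.frame(edges)
  if (nrow(e) > 0) {
    sa <- strain_of[e$a]
    sb <- strain_of[e$b]
    inter <- sa != sb
    # best score of each gene into each other strain
    keyA <- paste(e$a, sb, sep = "\r")
    keyB <- paste(e$b, sa, sep = "\r")
    best <- tapply(c(e$score[inter], e$score[inter]),
                   c(keyA[inter], keyB[inter]), max)
    best_inter <- tapply(c(e$score[inter], e$score[inter]),
                         c(e$a[inter], e$b[inter]), max)
    bi <- function(g) {
      v <- best_inter[g]
      ifelse(is.na(v), 0, v)
    }
    keep_inter <- inter &
      e$score >= best[keyA] - 1e-9 &
      e$score >= best[keyB] - 1e-9
    keep_intra <- !inter &
      e$score >= bi(e$a) - 1e-9 &
      e$score >= bi(e$b) - 1e-9
    e <- e[keep_inter | keep_intra, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (nrow(e) > 0) {
    w <- e$score / max(e$score)
    g <- igraph::add_edges(g, rbind(e$a, e$b), weight = w)
  }
  g
}

#' Markov clustering of the orthology graph
#'
#' Canonical MCL on the weighted adjacency matrix: add a self loop per
#' node (weight = the node's maximum incident edge weight, 1 for isolated
#' nodes), column-normalize, then iterate expansion (matrix squaring) and
#' inflation (entry-wise power `inflation`, re-normalize) with pruning of
#' entries below `prune`, until the largest entry change falls below `tol`
#' or `max_iter` iterations.  Clusters are the connected components of the
#' converged matrix's support.  Connected components of the input graph
#' are processed independently, so MCL always refines them.
#'
#' @param graph weighted undirected [igraph] graph.
#' @param inflation inflation exponent (OrthoMCL's default 1.5).
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max entry change.
#' @param max_iter iteration cap; non-convergence yields a warning and a
#'   partial result flagged via `attr(, "converged")`.
#' @return named integer vector: node -> cluster id (1..K, numbered by
#'   each cluster's lexicographically smallest member).
#' @export
mcl_cluster <- function(graph, inflation = 1.5, prune = 1e-6,
                        tol = 1e-8, max_iter = 200) {
  comp <- igraph::components(graph)
  nodes <- igraph::V(graph)$name
  converged <- TRUE
  membership <- integer(0)
  next_id <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- nodes[comp$membership == ci]
    if (length(vs) == 1) {
      next_id <- next_id + 1L
      membership[vs] <- next_id
      next
    }
    sg <- igraph::induced_subgraph(graph, vs)
    A <- as.matrix(igraph::as_adjacency_matrix(sg, attr = "weight",
                                               sparse = TRUE))
    A <- A[vs, vs, drop = FALSE]
    diag(A) <- apply(A, 1, max)
    M <- sweep(A, 2, colSums(A), "/")
    it <- 0L
    repeat {
      it <- it + 1L
      M2 <- M %*% M                       # expansion
      M2 <- M2^inflation                  # inflation
      M2[M2 < prune] <- 0
      cs <- colSums(M2)
      cs[cs == 0] <- 1
      M2 <- sweep(M2, 2, cs, "/")
      delta <- max(abs(M2 - M))
      M <- M2
      if (delta < tol) break
      if (it >= max_iter) {
        warning(sprintf("MCL did not converge on a %d-node component",
                        length(vs)))
        converged <- FALSE
        break
      }
    }
    supp <- (M > prune) | (t(M) > prune)
    cg <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected")
    sub <- igraph::components(cg)$membership
    for (k in sort(unique(sub))) {
      next_id <- next_id + 1L
      membership[vs[sub == k]] <- next_id
    }
  }
  # renumber clusters by smallest member for stable ids
  cl <- split(names(membership), membership)
  ord <- order(vapply(cl, function(x) min(x), ""))
  out <- integer(length(membership))
  names(out) <- names(membership)
  for (r in seq_along(ord)) out[cl[[ord[r]]]] <- r
  out <- out[sort(names(out))]
  attr(out, "converged") <- converged
  out
}

#' Assemble ortholog groups from a partition
#'
#' @param partition named vector gene id -> cluster id ([mcl_cluster()]).
#' @param strain_of named character vector gene id -> strain.
#' @param annotations optional named vector gene id -> description; the
#'   OG's consensus annotation is the most frequent member annotation.
#' @return object of class `og_set`: `og` (data.frame with `og_id`,
#'   `n_genes`, `n_strains`, `single_copy`, `singleton`, `annotation`),
#'   `members` (named list og -> gene ids), `counts` (OG x strain matrix).
#' @export
make_ogs <- function(partition, strain_of, annotations = NULL) {
  strains <- sort(unique(unname(strain_of)))
  if (length(partition) == 0) {
    return(structure(list(
      og = data.frame(og_id = character(), n_genes = integer(),
                      n_strains = integer(), single_copy = logical(),
                      singleton = logical(), annotation = character(),
                      stringsAsFactors = FALSE),
      members = list(),
      counts = matrix(0L, 0, length(strains),
                      dimnames = list(NULL, strains))),
      class = "og_set"))
  }
  cl <- split(names(partition), partition)
  cl <- lapply(cl, sort)
  cl <- cl[order(vapply(cl, `[`, "", 1))]
  og_ids <- sprintf("OG%05d", seq_along(cl))
  names(cl) <- og_ids
  counts <- matrix(0L, length(cl), length(strains),
                   dimnames = list(og_ids, strains))
  for (i in seq_along(cl)) {
    tab <- table(strain_of[cl[[i]]])
    counts[i, names(tab)] <- as.integer(tab)
  }
  ann <- rep(NA_character_, length(cl))
  if (!is.null(annotations)) {
    ann <- vapply(cl, function(g) {
      a <- annotations[g]
      a <- a[!is.na(a)]
      if (length(a) == 0) return(NA_character_)
      tb <- sort(table(a), decreasing = TRUE)
      names(tb)[1]
    }, "")
  }
  og <- data.frame(og_id = og_ids,
                   n_genes = lengths(cl),
                   n_strains = as.integer(rowSums(counts > 0)),
                   single_copy = apply(counts, 1, function(x) all(x == 1L)),
                   singleton = lengths(cl) == 1L,
                   annotation = ann,
                   stringsAsFactors = FALSE)
  rownames(og) <- NULL
  structure(list(og = og, members = cl, counts = counts), class = "og_set")
}

#' One-call ortholog inference
#'
#' Convenience wrapper: [score_pairs()] -> [build_graph()] ->
#' [mcl_cluster()] -> [make_ogs()].
#'
#' @param proteins named character vector or AAStringSet.
#' @param strain_of named vector gene -> strain; by default parsed from
#'   gene ids of the form `"STRAIN|gene"`.
#' @param annotations optional gene-level annotations.
#' @param inflation MCL inflation.
#' @param ... passed to [score_pairs()].
#' @return an `og_set`.
#' @export
infer_orthologs <- function(proteins, strain_of = NULL, annotations = NULL,
                            inflation = 1.5, ...) {
  nm <- names(proteins)
  if (is.null(strain_of)) {
    strain_of <- setNames(sub("\\|.*$", "", nm), nm)
  }
  edges <- score_pairs(proteins, ...)
  g <- build_graph(edges, strain_of)
  part <- mcl_cluster(g, inflation = inflation)
  make_ogs(part, strain_of, annotations)
}
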