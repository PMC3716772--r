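#' Reference-anchored contig ordering ("pseudo-assembly")
#'
#' Draft contigs are ordered along a finished circular reference
#' chromosome: each query gene is matched to its reciprocal-best reference
#' gene, every matched gene contributes the midpoint of its reference hit
#' as an anchor, and contigs are sorted by the mean of their anchor
#' coordinates.  Contigs without anchors go to an unplaced bin.  The same
#' anchoring projects ortholog groups onto reference gene order (their
#' "rank"), which downstream island detection and GC tracks use.
#'
#' Anchors of a contig spanning the circular origin are unwrapped by
#' adding the reference length to the smaller coordinates whenever the
#' anchor spread exceeds half the reference.
#'
#' @name pseudoasm
NULL

# reciprocal-best hits between one strain's proteins and the reference
reference_rbh <- function(prot_strain, prot_ref, ...) {
  all_prot <- c(prot_strain, prot_ref)
  strain_of <- setNames(c(rep("Q", length(prot_strain)),
                          rep("REF", length(prot_ref))),
                        names(all_prot))
  edges <- score_pairs(all_prot, ...)
  if (nrow(edges) == 0) {
    return(data.frame(gene_id = character(), ref_gene = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  g <- build_graph(edges, strain_of)
  e <- igraph::as_data_frame(g, what = "edges")
  sa <- strain_of[e$from]
  sb <- strain_of[e$to]
  cross <- sa != sb
  e <- e[cross, , drop = FALSE]
  q <- ifelse(strain_of[e$from] == "Q", e$from, e$to)
  r <- ifelse(strain_of[e$from] == "Q", e$to, e$from)
  out <- data.frame(gene_id = q, ref_gene = r, score = e$weight,
                    stringsAsFactors = FALSE)
  # a gene may tie to several reference genes; keep the best-scoring one
  # (ties broken by reference gene id for determinism)
  out <- out[order(out$gene_id, -out$score, out$ref_gene), , drop = FALSE]
  out[!duplicated(out$gene_id), , drop = FALSE]
}

unwrap_mean <- function(mids, ref_len) {
  if (length(mids) == 0) return(NA_real_)
  if (max(mids) - min(mids) > ref_len / 2) {
    mids[mids < ref_len / 2] <- mids[mids < ref_len / 2] + ref_len
  }
  mean(mids)
}

#' Order a strain's contigs against a circular reference
#'
#' @param genes gene table of one or more strains (columns `gene_id`,
#'   `strain`, `contig`, `start`, `end`).
#' @param proteins [Biostrings::AAStringSet] covering those genes.
#' @param reference list with `seq` (single-sequence DNAStringSet),
#'   `genes` (reference gene table, `gene_id`, `start`, `end`) and
#'   `proteins`; the reference is treated as circular.
#' @param genomes named list of per-strain [Biostrings::DNAStringSet]
#'   (used for contig lengths and the contig universe).
#' @param ogs optional `og_set`; when given, OG ranks are projected from
#'   reference gene order (majority reference hit per OG).
#' @param ... passed to [score_pairs()] (alignment parameters).
#' @return object of class `pseudo_assembly`: `orders` (data.frame
#'   `strain`, `rank`, `contig`, `mean_coord`, `n_anchors`, `placed`),
#'   `anchors`, `og_ranks` (named vector or NULL).
#' @export
pseudo_assemble <- function(genes, proteins, reference, genomes,
                            ogs = NULL, ...) {
  if (is.null(reference$genes) || nrow(reference$genes) == 0) {
    stop("reference annotation is required")
  }
  ref_len <- Biostrings::width(reference$seq)[1]
  rg <- reference$genes[order(reference$genes$start), , drop = FALSE]
  ref_mid <- setNames((rg$start + rg$end) / 2, rg$gene_id)
  ref_rank <- setNames(seq_len(nrow(rg)), rg$gene_id)

  orders <- list()
  anchors <- list()
  for (s in sort(unique(genes$strain))) {
    gs <- genes[genes$strain == s, , drop = FALSE]
    rbh <- reference_rbh(proteins[gs$gene_id], reference$proteins, ...)
    rbh$contig <- gs$contig[match(rbh$gene_id, gs$gene_id)]
    rbh$ref_mid <- unname(ref_mid[rbh$ref_gene])
    rbh$strain <- s
    anchors[[s]] <- rbh
    contigs <- names(genomes[[s]])
    clen <- setNames(Biostrings::width(genomes[[s]]), contigs)
    mean_coord <- vapply(contigs, function(ctg) {
      unwrap_mean(rbh$ref_mid[rbh$contig == ctg], ref_len)
    }, 0)
    n_anchors <- vapply(contigs, function(ctg)
      sum(rbh$contig == ctg), 0L)
    placed <- contigs[n_anchors > 0]
    # ascending mean coordinate; ties: longer contig first, then id
    placed <- placed[order(mean_coord[placed], -clen[placed], placed)]
    unplaced <- contigs[n_anchors == 0]  # input order
    ord <- c(placed, unplaced)
    orders[[s]] <- data.frame(
      strain = s, rank = seq_along(ord), contig = ord,
      mean_coord = unname(mean_coord[ord]),
      n_anchors = unname(n_anchors[ord]),
      placed = ord %in% placed, stringsAsFactors = FALSE)
  }
  og_ranks <- NULL
  if (!is.null(ogs)) {
    anc <- do.call(rbind, anchors)
    hit_rank <- setNames(unname(ref_rank[anc$ref_gene]), anc$gene_id)
    og_ranks <- vapply(ogs$members, function(g) {
      r <- hit_rank[intersect(g, names(hit_rank))]
      if (length(r) == 0) return(NA_real_)
      tb <- sort(table(r), decreasing = TRUE)
      as.numeric(names(tb)[1])
    }, 0)
    og_ranks <- og_ranks[!is.na(og_ranks)]
  }
  structure(list(orders = do.call(rbind, orders),
                 anchors = do.call(rbind, anchors),
                 og_ranks = og_ranks),
            class = "pseudo_assembly")
}

#' Sliding-window GC track
#'
#' GC fraction in sliding windows along contigs, in the given
#' (pseudo-assembly) contig order.  Ambiguous bases are excluded from both
#' numerator and denominator.  Contigs shorter than the window yield a
#' single whole-contig window.
#'
#' @param contigs [Biostrings::DNAStringSet], already in display order.
#' @param window window size (bp).
#' @param step step size (bp); `window >= step > 0` required.
#' @return data.frame: `contig`, `start`, `end`, `gc`.
#' @export
gc_profile <- function(contigs, window = 5000, step = 1000) {
  if (!(window >= step && step > 0)) stop("require window >= step > 0")
  out <- list()
  for (i in seq_along(contigs)) {
    sq <- contigs[[i]]
    w <- length(sq)
    starts <- if (w <= window) 1L else seq(1L, w - window + 1L, by = step)
    ends <- pmin(starts + window - 1L, w)
    v <- Biostrings::Views(sq, start = starts, end = ends)
    gc <- Biostrings::letterFrequency(v, "GC")[, 1]
    acgt <- Biostrings::letterFrequency(v, "ACGT")[, 1]
    out[[i]] <- data.frame(contig = names(contigs)[i], start = starts,
                           end = ends,
                           gc = ifelse(acgt > 0, gc / acgt, NA_real_),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
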