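#' Consensus gene calling from multiple predictor tracks
#'
#' Draft-genome annotation pipelines run several ab initio ORF callers and
#' keep only calls supported by a majority of them.  Predictors typically
#' agree on the stop codon of a gene but disagree on the start, so the
#' identity notion used for voting is (contig, strand, stop coordinate);
#' the accepted interval is taken from the longest supporting call.
#' Accepted genes are then screened for excessive overlap: whenever two
#' genes on a contig overlap by more than 100 bp, the shorter one is
#' discarded (an overlap of exactly 100 bp is allowed).
#'
#' Coordinates are 1-based inclusive throughout; the stop coordinate of a
#' "+" gene is its `end`, of a "-" gene its `start`.
#'
#' @name genecall
NULL

orf_stop <- function(orfs) {
  ifelse(orfs$strand == "+", orfs$end, orfs$start)
}

#' Group predicted ORFs into stop-anchored candidates
#'
#' ORFs from different predictors that share contig, strand and stop
#' coordinate are one candidate gene; the candidate interval is the longest
#' member's interval, and its support is the number of distinct predictors
#' backing it.
#'
#' @param orfs data.frame of predicted ORFs for ONE strain: columns
#'   `contig`, `start`, `end`, `strand`, `predictor` (and optionally
#'   `strain`, which must be constant).
#' @return data.frame of candidates: `contig`, `start`, `end`, `strand`,
#'   `stop`, `support`, `predictors` (comma-joined).
#' @export
group_by_stop <- function(orfs) {
  if ("strain" %in% names(orfs) && length(unique(orfs$strain)) > 1) {
    stop("group_by_stop expects ORFs from a single strain")
  }
  if (nrow(orfs) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      stop = integer(), support = integer(),
                      predictors = character(), stringsAsFactors = FALSE))
  }
  key <- paste(orfs$contig, orfs$strand, orf_stop(orfs), sep = "\r")
  len <- orfs$end - orfs$start + 1L
  o <- order(key, -len)                      # longest member first per key
  first <- o[!duplicated(key[o])]
  support <- tapply(orfs$predictor, key, function(p) length(unique(p)))
  preds <- tapply(orfs$predictor, key,
                  function(p) paste(sort(unique(p)), collapse = ","))
  k <- key[first]
  out <- data.frame(contig = orfs$contig[first], start = orfs$start[first],
                    end = orfs$end[first], strand = orfs$strand[first],
                    stop = orf_stop(orfs[first, , drop = FALSE]),
                    support = as.integer(support[k]),
                    predictors = unname(preds[k]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$contig, out$start, out$end, out$strand), , drop = FALSE]
}

#' Apply the majority vote to stop-anchored candidates
#'
#' A candidate is accepted iff it is supported by a strict majority of the
#' predictors, i.e. `support > n_predictors * min_support_fraction`
#' (default fraction 0.5: 3 of 4 passes, 2 of 4 does not).
#'
#' @param candidates output of [group_by_stop()].
#' @param n_predictors number of predictor tracks that were run.
#' @param min_support_fraction vote threshold as a fraction of
#'   `n_predictors`; acceptance requires support strictly above it.
#' @return accepted candidates (same layout).
#' @export
majority_vote <- function(candidates, n_predictors,
                          min_support_fraction = 0.5) {
  if (n_predictors < 1) stop("n_predictors must be >= 1")
  if (any(candidates$support > n_predictors)) {
    stop("candidate support exceeds n_predictors: corrupt input")
  }
  candidates[candidates$support >
               n_predictors * min_support_fraction, , drop = FALSE]
}

pairwise_overlaps <- function(genes) {
  # all overlapping pairs on a contig, nucleotide overlap irrespective of
  # strand; O(n^2) per contig is fine at panel scale
  out <- list()
  for (ctg in unique(genes$contig)) {
    g <- which(genes$contig == ctg)
    if (length(g) < 2) next
    cmb <- combn(g, 2)
    ov <- pmin(genes$end[cmb[1, ]], genes$end[cmb[2, ]]) -
      pmax(genes$start[cmb[1, ]], genes$start[cmb[2, ]]) + 1L
    keep <- ov > 0
    if (any(keep)) {
      out[[ctg]] <- data.frame(i = cmb[1, keep], j = cmb[2, keep],
                               overlap = ov[keep])
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), overlap = integer()))
  }
  do.call(rbind, out)
}

#' Resolve excessive overlaps among accepted genes
#'
#' While any pair of accepted genes on a contig overlaps by more than
#' `max_overlap` bp, the pair with the largest overlap is processed first
#' and its shorter member discarded (equal lengths: the one with the later
#' start).  Overlaps of exactly `max_overlap` bp are kept.  Every discard
#' is logged with the overlap and the retained partner.
#'
#' @param accepted data.frame of accepted candidates ([majority_vote()]).
#' @param max_overlap maximum tolerated pairwise overlap in bp.
#' @return list of class `consensus_genes`: `genes` (surviving rows,
#'   with `gene_id` assigned by contig/start order), `discards` (log
#'   data.frame with `reason`).
#' @export
resolve_overlaps <- function(accepted, max_overlap = 100L) {
  g <- accepted
  g$.len <- g$end - g$start + 1L
  discards <- list()
  repeat {
    ov <- pairwise_overlaps(g)
    ov <- ov[ov$overlap > max_overlap, , drop = FALSE]
    if (nrow(ov) == 0) break
    # deterministic processing: largest overlap first, then position
    ov <- ov[order(-ov$overlap, g$contig[ov$i], pmin(g$start[ov$i],
                                                     g$start[ov$j])), ,
             drop = FALSE]
    i <- ov$i[1]; j <- ov$j[1]
    drop <- if (g$.len[i] < g$.len[j]) i
            else if (g$.len[j] < g$.len[i]) j
            else if (g$start[i] > g$start[j]) i else j
    keep <- if (drop == i) j else i
    discards[[length(discards) + 1L]] <- data.frame(
      contig = g$contig[drop], start = g$start[drop], end = g$end[drop],
      strand = g$strand[drop],
      reason = sprintf("overlap %d bp with %s:%d-%d", ov$overlap[1],
                       g$contig[keep], g$start[keep], g$end[keep]),
      stringsAsFactors = FALSE)
    g <- g[-drop, , drop = FALSE]
  }
  g$.len <- NULL
  g <- g[order(g$contig, g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  dl <- if (length(discards)) do.call(rbind, discards) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(genes = g, discards = dl), class = "consensus_genes")
}

#' Run the full consensus caller for one strain
#'
#' Chains [group_by_stop()], [majority_vote()] and [resolve_overlaps()],
#' then extracts protein translations (bacterial genetic code) from the
#' genome sequence.
#'
#' @param tracks list of per-predictor ORF data.frames (columns `contig`,
#'   `start`, `end`, `strand`, `predictor`).
#' @param genome [Biostrings::DNAStringSet] of the strain's contigs.
#' @param strain strain name used for gene ids.
#' @param n_predictors defaults to `length(tracks)`.
#' @param min_support_fraction see [majority_vote()].
#' @param max_overlap see [resolve_overlaps()].
#' @return `consensus_genes` with `genes` (incl. `gene_id`), `proteins`
#'   ([Biostrings::AAStringSet]) and `discards`.
#' @export
call_genes <- function(tracks, genome, strain = "strain",
                       n_predictors = length(tracks),
                       min_support_fraction = 0.5, max_overlap = 100L) {
  orfs <- do.call(rbind, lapply(tracks, function(t)
    t[, c("contig", "start", "end", "strand", "predictor")]))
  cand <- group_by_stop(orfs)
  acc <- majority_vote(cand, n_predictors, min_support_fraction)
  res <- resolve_overlaps(acc, max_overlap)
  g <- res$genes
  if (nrow(g) > 0) {
    g$gene_id <- sprintf("%s|c%04d", strain, seq_len(nrow(g)))
    g$strain <- strain
    cds <- Biostrings::DNAStringSet(lapply(seq_len(nrow(g)), function(i)
      Biostrings::subseq(genome[[g$contig[i]]], g$start[i], g$end[i])))
    minus <- g$strand == "-"
    if (any(minus)) {
      cds[minus] <- Biostrings::reverseComplement(cds[minus])
    }
    prot <- sub("\\*$", "", as.character(Biostrings::translate(
      cds, genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "solve")))
    res$proteins <- Biostrings::AAStringSet(setNames(prot, g$gene_id))
  } else {
    g$gene_id <- character(0)
    g$strain <- character(0)
    res$proteins <- Biostrings::AAStringSet()
  }
  res$genes <- g
  res
}
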