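#' Plasmid-contig classification
#'
#' A contig is evaluated against four criteria commonly used to flag
#' plasmids in draft assemblies: (1) its genes do not map to the reference
#' chromosome, (2) it encodes typical plasmid functions (replication
#' initiator, rep/mob/tra genes, relaxase, parA/parB partitioning,
#' toxin-antitoxin), (3) a large part of it matches a known plasmid at
#' high identity, (4) it appears circular, i.e. carries an exact terminal
#' repeat (the assembly artifact of a circular molecule).  One satisfied
#' criterion yields a putative plasmid call, two or more a plasmid call.
#'
#' @name plasmids
NULL

PLASMID_KEYWORDS <- paste0(
  "replication initiator|\\brep[A-Z]?\\b|\\bmob[A-Z]?\\b|\\btra[A-Z]\\b|",
  "relaxase|\\bpar[AB]\\b|toxin[- ]antitoxin")

#' Detect circularity via an exact terminal repeat
#'
#' A sequence "appears circular" when a prefix of at least `min_overlap`
#' bp recurs exactly as its suffix; the longest such overlap not exceeding
#' half the sequence length is reported.  Exact matching (the default
#' `max_mismatch = 0`) uses the classic border (failure-function) scan;
#' for `max_mismatch > 0` overlaps up to `max_scan` bp are compared
#' allowing that many mismatches.
#'
#' @param sequence character or [Biostrings::DNAString].
#' @param min_overlap minimum terminal repeat length (bp).
#' @param max_mismatch mismatches tolerated in the repeat.
#' @param max_scan overlap-length cap for the mismatch-tolerant scan.
#' @return list `circular` (flag), `overlap` (bp, 0 if none).
#' @export
detect_circularity <- function(sequence, min_overlap = 50,
                               max_mismatch = 0, max_scan = 5000) {
  s <- as.character(sequence)
  n <- nchar(s)
  if (n <= 2 * min_overlap) {
    stop("sequence must be longer than twice min_overlap")
  }
  if (max_mismatch == 0) {
    x <- utf8ToInt(s)
    # KMP failure function: longest proper border of the whole sequence
    f <- integer(n)
    k <- 0L
    for (i in 2:n) {
      while (k > 0L && x[k + 1L] != x[i]) k <- f[k]
      if (x[k + 1L] == x[i]) k <- k + 1L
      f[i] <- k
    }
    b <- f[n]
    while (b > n / 2) b <- f[b]
    if (b >= min_overlap) {
      return(list(circular = TRUE, overlap = as.integer(b)))
    }
    return(list(circular = FALSE, overlap = 0L))
  }
  x <- utf8ToInt(s)
  top <- min(floor(n / 2), max_scan)
  for (k in seq(top, min_overlap)) {
    mm <- sum(x[seq_len(k)] != x[(n - k + 1):n])
    if (mm <= max_mismatch) {
      return(list(circular = TRUE, overlap = as.integer(k)))
    }
  }
  list(circular = FALSE, overlap = 0L)
}

# seeded local alignment of a contig against known plasmids: pairs are
# aligned only when they share exact seed k-mers, mirroring BLAST's
# seed-and-extend economy at desk scale
known_plasmid_match <- function(seq, known, seed_k = 15, min_seeds = 3) {
  s <- as.character(seq)
  n <- nchar(s)
  if (length(known) == 0 || n < seed_k) {
    return(list(coverage = 0, identity = 0))
  }
  qk <- unique(substring(s, 1:(n - seed_k + 1), seed_k:n))
  best_cov <- 0
  best_id <- 0
  for (i in seq_along(known)) {
    t <- as.character(known[[i]])
    m <- nchar(t)
    if (m < seed_k) next
    tk <- unique(substring(t, 1:(m - seed_k + 1), seed_k:m))
    if (length(intersect(qk, tk)) < min_seeds) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(t), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    cov <- (nm + nmm) / n
    idf <- if (nm + nmm > 0) nm / (nm + nmm) else 0
    if (cov > best_cov) {
      best_cov <- cov
      best_id <- idf
    }
  }
  list(coverage = best_cov, identity = best_id)
}

#' Evaluate the four plasmid criteria for one contig
#'
#' @param contig_id contig name.
#' @param seq contig sequence ([Biostrings::DNAString] or character).
#' @param genes gene table rows on this contig (may be empty).
#' @param ref_mapped character vector of gene ids that have a reference
#'   chromosome ortholog.
#' @param annotations named vector gene id -> functional annotation.
#' @param known_plasmids [Biostrings::DNAStringSet] of published plasmids.
#' @param chrom_map_cutoff criterion 1 fires when the fraction of contig
#'   genes with a reference ortholog is below this.
#' @param known_cov_cutoff,known_id_cutoff criterion 3 thresholds
#'   (coverage of the contig, alignment identity).
#' @param min_overlap criterion 4 minimum terminal repeat.
#' @return one-row data.frame of class `plasmid_evidence`.
#' @export
evaluate_criteria <- function(contig_id, seq, genes, ref_mapped,
                              annotations, known_plasmids,
                              chrom_map_cutoff = 0.2,
                              known_cov_cutoff = 0.5,
                              known_id_cutoff = 0.8,
                              min_overlap = 50) {
  n_genes <- nrow(genes)
  map_frac <- if (n_genes == 0) 0 else
    mean(genes$gene_id %in% ref_mapped)
  c1 <- map_frac < chrom_map_cutoff
  ann <- annotations[genes$gene_id]
  ann <- ann[!is.na(ann)]
  hits <- ann[grepl(PLASMID_KEYWORDS, ann, ignore.case = TRUE)]
  c2 <- length(hits) > 0
  km <- known_plasmid_match(seq, known_plasmids)
  c3 <- km$coverage >= known_cov_cutoff && km$identity >= known_id_cutoff
  circ <- detect_circularity(seq, min_overlap = min_overlap)
  c4 <- circ$circular
  n_crit <- sum(c1, c2, c3, c4)
  call <- if (n_crit >= 2) "plasmid" else
    if (n_crit == 1) "putative_plasmid" else "chromosomal"
  structure(data.frame(
    contig = contig_id, n_genes = n_genes,
    c1_chrom_map_fraction = map_frac, c1 = c1,
    c2_keyword_hits = paste(unique(hits), collapse = ";"), c2 = c2,
    c3_known_plasmid_coverage = km$coverage,
    c3_known_plasmid_identity = km$identity, c3 = c3,
    c4_circular = c4, c4_overlap = circ$overlap,
    n_criteria = n_crit, call = call, stringsAsFactors = FALSE),
    class = c("plasmid_evidence", "data.frame"))
}

#' Classify all contigs of a panel and extract the plasmid pan-genome
#'
#' Applies [evaluate_criteria()] to every contig of every strain; a
#' contig with >= 2 satisfied criteria is called `plasmid`, exactly 1
#' `putative_plasmid`, 0 `chromosomal`.  OGs whose member genes lie
#' exclusively on plasmid-called contigs form the plasmid pan-genome.
#'
#' @param genomes named list of per-strain [Biostrings::DNAStringSet].
#' @param genes combined gene table (all strains).
#' @param ref_mapped gene ids with a reference-chromosome ortholog.
#' @param annotations named vector gene id -> annotation.
#' @param known_plasmids DNAStringSet of published plasmids.
#' @param ogs optional `og_set` for the plasmid pan-genome report.
#' @param ... thresholds passed to [evaluate_criteria()].
#' @return list of class `plasmid_calls`: `evidence` (data.frame, one row
#'   per contig with `strain`), `plasmid_ogs` (character vector).
#' @export
classify_plasmids <- function(genomes, genes, ref_mapped, annotations,
                              known_plasmids, ogs = NULL, ...) {
  rows <- list()
  for (s in names(genomes)) {
    gnm <- genomes[[s]]
    for (ctg in names(gnm)) {
      ev <- evaluate_criteria(ctg, gnm[[ctg]],
                              genes[genes$contig == ctg, , drop = FALSE],
                              ref_mapped, annotations, known_plasmids,
                              ...)
      ev <- cbind(strain = s, ev)
      rows[[length(rows) + 1L]] <- ev
    }
  }
  evidence <- do.call(rbind, rows)
  rownames(evidence) <- NULL
  plasmid_ogs <- character(0)
  if (!is.null(ogs)) {
    plasmid_contigs <- evidence$contig[evidence$call == "plasmid"]
    gene_on_plasmid <- setNames(genes$contig %in% plasmid_contigs,
                                genes$gene_id)
    plasmid_ogs <- names(ogs$members)[vapply(ogs$members, function(g) {
      known <- intersect(g, names(gene_on_plasmid))
      length(known) > 0 && all(gene_on_plasmid[known])
    }, TRUE)]
  }
  structure(list(evidence = evidence, plasmid_ogs = plasmid_ogs),
            class = "plasmid_calls")
}
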