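#' CRISPR array detection, spacer cataloguing and strain typing
#'
#' CRISPR loci consist of near-identical direct repeats (typically ~36 nt
#' in lactobacilli) separated by unique spacers acquired from invading
#' DNA.  Detection proceeds by seeding: 12-mers recurring at regular
#' offsets compatible with a repeat+spacer period nucleate candidate
#' arrays, repeats are extended to their maximal agreement with the
#' consensus, and spacers are read off between consecutive repeats.
#' Spacer content identifies a strain's "CRISPR type": strains with
#' identical ordered spacer sets share a type, strains without an array
#' are type 0.
#'
#' @name crispr
NULL

seq_kmer_starts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  km <- substring(s, 1:(n - k + 1), k:n)
  split(seq_along(km), km)
}

consensus_of <- function(strs) {
  mat <- do.call(rbind, strsplit(strs, ""))
  paste0(apply(mat, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  }), collapse = "")
}

mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Find CRISPR arrays in one sequence
#'
#' @param sequence contig sequence (character or DNAString).
#' @param repeat_len_range allowed direct-repeat length (bp).
#' @param spacer_len_range allowed spacer length (bp).
#' @param min_repeats minimum repeats per reported array.
#' @param max_repeat_mismatch tolerated mismatches of any repeat instance
#'   against the array's repeat consensus.
#' @param seed_k seed k-mer length used to nucleate candidates.
#' @return data.frame: `start`, `end`, `repeat_consensus`, `repeat_len`,
#'   `n_repeats`, `spacers` (comma-joined, in array order),
#'   `truncated` (array abuts a contig end within one repeat length).
#' @export
find_arrays <- function(sequence, repeat_len_range = c(23, 47),
                        spacer_len_range = c(20, 50), min_repeats = 3,
                        max_repeat_mismatch = 1, seed_k = 12) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n < 3 * repeat_len_range[1]) {
    return(empty_array_df())
  }
  period_min <- repeat_len_range[1] + spacer_len_range[1]
  period_max <- repeat_len_range[2] + spacer_len_range[2]
  tab <- seq_kmer_starts(s, seed_k)
  tab <- tab[lengths(tab) >= min_repeats]
  cands <- list()
  for (pos in tab) {
    pos <- sort(pos)
    gaps <- diff(pos)
    ok <- gaps >= period_min & gaps <= period_max
    # maximal runs of in-band gaps
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i] || r$lengths[i] < min_repeats - 1) next
      anchors <- pos[starts[i]:(ends[i] + 1L)]
      cands[[length(cands) + 1L]] <- anchors
    }
  }
  if (length(cands) == 0) return(empty_array_df())

  arrays <- list()
  for (anchors in cands) {
    m <- length(anchors)
    gaps <- diff(anchors)
    # extend the repeat column-by-column around the seed; a column is
    # conserved iff at most max_repeat_mismatch instances deviate from
    # its majority base (unique-spacer columns fail this immediately)
    col_ok <- function(offsets) {
      pos <- anchors + offsets
      if (any(pos < 1L | pos > n)) return(FALSE)
      b <- substring(s, pos, pos)
      m - max(table(b)) <= max_repeat_mismatch
    }
    left <- 0L
    right <- 0L
    max_span <- min(gaps) - 1L   # never reach the next anchor's seed copy
    repeat {
      grown <- FALSE
      if (seed_k + left + right < repeat_len_range[2] &&
          seed_k + right + left < max_span &&
          col_ok(rep(seed_k + right, m))) {
        right <- right + 1L
        grown <- TRUE
      }
      if (seed_k + left + right < repeat_len_range[2] &&
          seed_k + left + right < max_span &&
          col_ok(rep(-left - 1L, m))) {
        left <- left + 1L
        grown <- TRUE
      }
      if (!grown) break
    }
    # trim: boundary columns must be perfectly conserved, otherwise a
    # chance near-agreement in the flanks/spacer ends would shift the
    # repeat boundary by a column
    col_dev <- function(offsets) {
      b <- substring(s, anchors + offsets, anchors + offsets)
      m - max(table(b))
    }
    while (left > 0L && col_dev(rep(-left, m)) > 0L) left <- left - 1L
    while (right > 0L &&
             col_dev(rep(seed_k + right - 1L, m)) > 0L) right <- right - 1L
    w <- seed_k + left + right
    if (w < repeat_len_range[1]) next
    st <- anchors - left
    inst <- substring(s, st, st + w - 1L)
    cons <- consensus_of(inst)
    mm <- vapply(inst, mismatches, 0L, b = cons)
    if (any(mm > max_repeat_mismatch)) next
    best <- list(cons = cons)
    sp_st <- st[-length(st)] + w
    sp_en <- st[-1] - 1L
    sp_len <- sp_en - sp_st + 1L
    if (any(sp_len < spacer_len_range[1] | sp_len > spacer_len_range[2])) {
      next
    }
    spacers <- substring(s, sp_st, sp_en)
    arrays[[length(arrays) + 1L]] <- data.frame(
      start = st[1], end = st[length(st)] + w - 1L,
      repeat_consensus = best$cons, repeat_len = w,
      n_repeats = length(st),
      spacers = paste(spacers, collapse = ","),
      truncated = st[1] <= w | (st[length(st)] + 2L * w - 1L) > n,
      stringsAsFactors = FALSE)
  }
  if (length(arrays) == 0) return(empty_array_df())
  arr <- do.call(rbind, arrays)
  arr <- arr[!duplicated(arr[, c("start", "end")]), , drop = FALSE]
  # overlapping candidates: keep the array with the most repeats
  # (ties: longer span, then leftmost), drop the rest
  arr <- arr[order(-arr$n_repeats, -(arr$end - arr$start), arr$start), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(arr))
  for (i in seq_len(nrow(arr))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(arr))) {
      if (j == i || !keep[j]) next
      if (arr$start[j] <= arr$end[i] && arr$end[j] >= arr$start[i]) {
        keep[j] <- FALSE
      }
    }
  }
  arr <- arr[keep, , drop = FALSE]
  arr <- arr[order(arr$start), , drop = FALSE]
  rownames(arr) <- NULL
  arr
}

empty_array_df <- function() {
  data.frame(start = integer(), end = integer(),
             repeat_consensus = character(), repeat_len = integer(),
             n_repeats = integer(), spacers = character(),
             truncated = logical(), stringsAsFactors = FALSE)
}

#' Scan a panel of genomes for CRISPR arrays
#'
#' @param genomes named list of per-strain [Biostrings::DNAStringSet].
#' @param ... passed to [find_arrays()].
#' @return data.frame with `strain`, `contig` and the [find_arrays()]
#'   columns.
#' @export
scan_crispr <- function(genomes, ...) {
  rows <- list()
  for (s in names(genomes)) {
    for (ctg in names(genomes[[s]])) {
      a <- find_arrays(genomes[[s]][[ctg]], ...)
      if (nrow(a) > 0) {
        rows[[length(rows) + 1L]] <- cbind(strain = s, contig = ctg, a)
      }
    }
  }
  if (length(rows) == 0) {
    return(cbind(data.frame(strain = character(), contig = character()),
                 empty_array_df()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

canonical_spacer <- function(sp) {
  rc <- vapply(sp, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    "")
  ifelse(sp <= rc, sp, rc)
}

#' Catalogue distinct spacers across strains
#'
#' Spacers are deduplicated exactly but reverse-complement aware (a spacer
#' read on the opposite strand is the same spacer).
#'
#' @param arrays output of [scan_crispr()] (needs `strain`, `spacers`).
#' @param strains strain universe for the incidence matrix columns
#'   (defaults to strains present in `arrays`).
#' @return list of class `spacer_catalogue`: `spacers` (data.frame
#'   `spacer_id`, `sequence` (canonical form), `n_strains`), `incidence`
#'   (spacer x strain binary matrix).
#' @export
catalog_spacers <- function(arrays, strains = unique(arrays$strain)) {
  per <- list()
  for (i in seq_len(nrow(arrays))) {
    sp <- strsplit(arrays$spacers[i], ",", fixed = TRUE)[[1]]
    per[[i]] <- data.frame(strain = arrays$strain[i],
                           spacer = canonical_spacer(sp),
                           stringsAsFactors = FALSE)
  }
  all_sp <- if (length(per)) do.call(rbind, per) else
    data.frame(strain = character(), spacer = character())
  uniq <- sort(unique(all_sp$spacer))
  inc <- matrix(0L, length(uniq), length(strains),
                dimnames = list(uniq, strains))
  if (nrow(all_sp) > 0) {
    idx <- unique(all_sp)
    inc[cbind(match(idx$spacer, uniq), match(idx$strain, strains))] <- 1L
  }
  ids <- sprintf("SP%04d", seq_along(uniq))
  rownames(inc) <- ids
  structure(list(
    spacers = data.frame(spacer_id = ids, sequence = uniq,
                         n_strains = as.integer(rowSums(inc)),
                         stringsAsFactors = FALSE),
    incidence = inc), class = "spacer_catalogue")
}

#' Assign CRISPR types to strains
#'
#' Strains with identical ordered spacer sets (orientation-insensitive:
#' an array read on the opposite strand matches) share a type id; ids are
#' assigned in order of first appearance over the given strain order.
#' Strains with no array are type 0.  Subset relations between types
#' (candidate ancestral arrays) are reported as metadata, not merged.
#'
#' @param arrays output of [scan_crispr()].
#' @param strains strain universe, in the order that fixes type-id
#'   assignment.
#' @return list of class `crispr_types`: `types` (named integer vector
#'   strain -> type id), `keys` (type id -> spacer key), `subset_pairs`
#'   (data.frame of type pairs where one spacer set contains the other).
#' @export
assign_types <- function(arrays, strains = unique(arrays$strain)) {
  key_of <- setNames(rep("", length(strains)), strains)
  spset <- setNames(vector("list", length(strains)), strains)
  for (s in strains) {
    a <- arrays[arrays$strain == s, , drop = FALSE]
    if (nrow(a) == 0) next
    a <- a[order(a$contig, a$start), , drop = FALSE]
    sp <- unlist(strsplit(a$spacers, ",", fixed = TRUE))
    # canonical orientation of the whole ordered set
    fwd <- paste(sp, collapse = "|")
    rev <- paste(rev(vapply(sp, function(x)
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x))), "")), collapse = "|")
    key_of[s] <- min(fwd, rev)
    spset[[s]] <- canonical_spacer(sp)
  }
  types <- setNames(integer(length(strains)), strains)
  seen <- character(0)
  for (s in strains) {
    if (key_of[s] == "") {
      types[s] <- 0L
      next
    }
    hit <- match(key_of[s], seen)
    if (is.na(hit)) {
      seen <- c(seen, key_of[s])
      hit <- length(seen)
    }
    types[s] <- hit
  }
  keys <- setNames(seen, seq_along(seen))
  # subset metadata between distinct types
  reps <- strains[!duplicated(types) & types > 0]
  pairs <- list()
  if (length(reps) > 1) {
    cmb <- combn(reps, 2)
    for (i in seq_len(ncol(cmb))) {
      s1 <- cmb[1, i]; s2 <- cmb[2, i]
      a <- spset[[s1]]; b <- spset[[s2]]
      if (all(a %in% b) || all(b %in% a)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          type_a = types[s1], type_b = types[s2],
          relation = if (all(a %in% b)) "a_subset_of_b" else
            "b_subset_of_a", stringsAsFactors = FALSE)
      }
    }
  }
  subset_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(type_a = integer(), type_b = integer(),
               relation = character(), stringsAsFactors = FALSE)
  structure(list(types = types, keys = keys,
                 subset_pairs = subset_pairs), class = "crispr_types")
}
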