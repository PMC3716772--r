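# independent oracles used by the tests; deliberately naive
# implementations that share no code with the package's own paths

# Smith-Waterman with affine gaps (gap of length L costs open + ext * L),
# BLOSUM62; plain dynamic programming over dense matrices
sw_oracle <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- get("BLOSUM62", envir = e)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + S[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# overlap resolution replayed naively: repeatedly find the largest
# excessive overlap and discard the shorter (later-start on ties) member
overlap_oracle <- function(g, max_overlap = 100) {
  repeat {
    n <- nrow(g)
    best <- NULL
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (g$contig[i] != g$contig[j]) next
          ov <- min(g$end[i], g$end[j]) - max(g$start[i], g$start[j]) + 1
          if (ov > max_overlap && (is.null(best) || ov > best$ov)) {
            best <- list(i = i, j = j, ov = ov)
          }
        }
      }
    }
    if (is.null(best)) return(g)
    li <- g$end[best$i] - g$start[best$i] + 1
    lj <- g$end[best$j] - g$start[best$j] + 1
    drop <- if (li < lj) best$i else if (lj < li) best$j else
      if (g$start[best$i] > g$start[best$j]) best$i else best$j
    g <- g[-drop, , drop = FALSE]
  }
}

# plain whole-matrix MCL iteration (no component decomposition, no
# igraph): same conventions (self loop = max incident weight)
mcl_oracle <- function(A, inflation = 1.5, prune = 1e-6, tol = 1e-8) {
  diag(A) <- apply(A, 1, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:200) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    done <- max(abs(M2 - M)) < tol
    M <- M2
    if (done) break
  }
  supp <- (M > prune) | (t(M) > prune)
  # connected components by breadth-first search
  n <- nrow(supp)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(supp[v, ] & is.na(comp)))
    }
  }
  stats::setNames(comp, rownames(A))
}

# average-linkage agglomeration replayed naively on a distance matrix;
# returns the merged member sets with their heights
avg_linkage_oracle <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
      }
    }
    members <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(members = members, h = best$h)
    clusters[[best$i]] <- members
    clusters[[best$j]] <- NULL
  }
  merges
}

# member sets + heights of every internal node of an hclust tree
hclust_merges <- function(hc) {
  sets <- list()
  out <- list()
  for (i in seq_len(nrow(hc$merge))) {
    get_members <- function(k) {
      if (k < 0) hc$labels[-k] else sets[[k]]
    }
    members <- sort(c(get_members(hc$merge[i, 1]),
                      get_members(hc$merge[i, 2])))
    sets[[i]] <- members
    out[[i]] <- list(members = members, h = hc$height[i])
  }
  out
}

# adjusted Rand index between two labelings (contingency-table formula)
ari_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(as.vector(tab))
  b1 <- sum_comb(rowSums(tab))
  b2 <- sum_comb(colSums(tab))
  expected <- b1 * b2 / choose(n, 2)
  maxi <- (b1 + b2) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# longest exact terminal overlap by direct substring comparison
circularity_oracle <- function(s, min_overlap = 50) {
  s <- as.character(s)
  n <- nchar(s)
  best <- 0L
  for (k in seq(min_overlap, floor(n / 2))) {
    if (substr(s, 1, k) == substr(s, n - k + 1, n)) best <- k
  }
  list(circular = best >= min_overlap && best > 0, overlap = best)
}
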