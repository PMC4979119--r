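# independent brute-force oracles and small fixture builders used across
# test files; these deliberately re-derive results by direct enumeration,
# not by calling the package's optimized code paths

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# mature + loop + reverse complement of mature: a perfect stem-loop
makeHairpin <- function(mature, loopLen = 12) {
  paste0(mature, randSeq(loopLen), rc(mature))
}

# minimal ungapped mismatch count over all offsets, counting overhangs as
# mismatches: plain double loop, the reference for matchKnown
oracleMinMismatch <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  best <- la + lb
  for (o in (-(lb - 1)):(la - 1)) {
    mm <- 0; ov <- 0
    for (k in seq_len(lb)) {
      ai <- o + k
      if (ai >= 1 && ai <= la) {
        ov <- ov + 1
        if (a[ai] != b[k]) mm <- mm + 1
      }
    }
    tot <- mm + (la - ov) + (lb - ov)
    if (tot < best) best <- tot
  }
  best
}

# per-position target-site scoring by direct rule application
oracleSiteScore <- function(mirna, window) {
  m <- strsplit(mirna, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])
  s <- 0
  for (p in seq_along(m)) {
    pair <- paste0(m[p], w[p])
    pen <- if (pair %in% c("AT", "TA", "CG", "GC")) 0
           else if (pair %in% c("GT", "TG")) 0.5
           else 1
    if (p >= 2 && p <= 13) pen <- pen * 2
    s <- s + pen
  }
  s
}

# BH step-up from the definition: q_i = min_{j: p_j >= p_i} (m * p_j / rank_j)
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  cummin_rev <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q[ord] <- pmin(1, cummin_rev)
  q
}

# UPGMA by direct agglomeration on a distance matrix; returns merge heights
# and the leaf partition at each step for comparison with hclust
oracleUPGMA <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  merges <- list()
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      dd <- d[a, b]
      if (dd < bestd) { bestd <- dd; best <- c(b, a) }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, bestd)
    merges[[length(merges) + 1]] <- sort(c(clusters[[a]], clusters[[b]]))
    # average-linkage update into slot a
    for (k in active) {
      if (k == a || k == b) next
      d[a, k] <- d[k, a] <- (sizes[a] * d[a, k] + sizes[b] * d[b, k]) /
        (sizes[a] + sizes[b])
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  list(heights = heights, merges = merges)
}

# partitions formed by an hclust merge matrix, step by step
hclustMerges <- function(hc) {
  groups <- list()
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    members <- c()
    for (x in hc$merge[s, ]) {
      members <- c(members, if (x < 0) -x else groups[[x]])
    }
    groups[[s]] <- members
    out[[s]] <- sort(members)
  }
  out
}

# write a small FASTQ file from sequences with uniform quality
writeTestFastq <- function(seqs, path, qchar = "I") {
  lines <- as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                           vapply(nchar(seqs), function(n)
                             strrep(qchar, n), character(1))))
  writeLines(lines, path)
  path
}
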