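#' Map degradome tags onto the transcriptome
#'
#' Exact sense-strand matching only; a tag hitting several transcripts (or
#' several positions of one transcript) is counted at every locus. Profiles
#' are keyed by the 0-based transcript coordinate of the tag's 5' end, which
#' marks an uncapped mRNA 5' end (a candidate cleavage site).
#'
#' @param tags a \linkS4class{UniqueTagSet} or named integer vector
#'   (sequence -> count); unnamed character vectors get count 1 per read.
#' @param transcriptome named \code{DNAStringSet} or character vector.
#' @return named list, one \code{DegradomeProfile}-style element per
#'   transcript with any hit: a list with \code{counts} (named numeric,
#'   position -> count) and \code{total}.
#' @export
mapDegradome <- function(tags, transcriptome) {
  if (is(tags, "UniqueTagSet")) {
    counts <- setNames(tagTotals(tags), tagSequences(tags))
  } else if (is.null(names(tags))) {
    tab <- table(canonDNA(tags))
    counts <- setNames(as.numeric(tab), names(tab))
  } else {
    counts <- setNames(as.numeric(tags), canonDNA(names(tags)))
  }
  tx <- setNames(canonDNA(as.character(transcriptome)), names(transcriptome))
  profiles <- list()
  for (tg in names(counts)) {
    for (txid in names(tx)) {
      m <- gregexpr(tg, tx[[txid]], fixed = TRUE)[[1]]
      if (m[1] < 0L) next
      for (pos in as.integer(m)) {
        key <- as.character(pos - 1L)  # 0-based 5' end
        if (is.null(profiles[[txid]])) profiles[[txid]] <- numeric(0)
        profiles[[txid]][key] <- sum(profiles[[txid]][key], counts[[tg]],
                                     na.rm = TRUE)
      }
    }
  }
  lapply(profiles, function(p) list(counts = p, total = sum(p)))
}

#' Position-weighted miRNA/target complementarity score
#'
#' The miRNA is aligned antiparallel to a transcript window of its own
#' length. Penalties: mismatch 1.0, G:U wobble 0.5, doubled at miRNA
#' positions 2-13 (counted from the miRNA 5' end). A perfect
#' reverse-complement window scores 0.
#'
#' @param mirna miRNA sequence (5' to 3').
#' @param window transcript window (5' to 3'), same length as the miRNA.
#' @return list with \code{score} and \code{states} (character vector per
#'   miRNA position: "match", "GU" or "mismatch").
#' @export
complementarityScore <- function(mirna, window) {
  m <- strsplit(canonDNA(mirna), "")[[1]]
  w <- strsplit(canonDNA(window), "")[[1]]
  if (length(m) != length(w))
    stop("window length must equal miRNA length")
  L <- length(m)
  # miRNA position p pairs the window base at index L - p + 1 (antiparallel)
  t <- w[L:1]
  states <- ifelse(.isWC(m, t), "match", ifelse(.isGU(m, t), "GU", "mismatch"))
  pen <- c(match = 0, GU = 0.5, mismatch = 1)[states]
  weight <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  list(score = sum(pen * weight), states = unname(states))
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Scores every ungapped antiparallel alignment of the miRNA along the
#' transcript and keeps those with score at most \code{maxScore}. Each site
#' is annotated with its expected cleavage coordinate: the transcript
#' position pairing miRNA position 10 (cleavage falls between positions
#' opposite miRNA 10 and 11, and the degradome tag marking the 3' fragment
#' starts at the position opposite miRNA 10).
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence (at least miRNA length).
#' @param maxScore score cutoff, default 4.5.
#' @return data.frame with columns start (0-based alignment start on the
#'   transcript), score, cleavage_pos (0-based).
#' @export
predictSites <- function(mirna, transcript, maxScore = 4.5) {
  mirna <- canonDNA(mirna); transcript <- canonDNA(transcript)
  L <- nchar(mirna)
  n <- nchar(transcript)
  if (n < L) stop("transcript shorter than miRNA")
  m <- strsplit(mirna, "")[[1]]
  tchars <- strsplit(transcript, "")[[1]]
  weight <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  starts <- 0:(n - L)
  scores <- vapply(starts, function(s) {
    t <- tchars[(s + L):(s + 1)]
    pen <- ifelse(.isWC(m, t), 0, ifelse(.isGU(m, t), 0.5, 1))
    sum(pen * weight)
  }, numeric(1))
  keep <- scores <= maxScore
  data.frame(start = starts[keep], score = scores[keep],
             cleavage_pos = starts[keep] + L - 10L)
}

#' Categorize a supported cleavage site by tag abundance
#'
#' Class 1 when the cleavage signal is the most abundant on the transcript;
#' class 2 when it is at least the median of the non-zero positions but
#' below the maximum; class 3 otherwise. Scale-invariant by construction.
#'
#' @param profile a profile element from \code{\link{mapDegradome}} (or a
#'   named numeric position -> count vector).
#' @param siteCount the summed tag count attributed to the cleavage site.
#' @return integer class, 1, 2 or 3.
#' @export
categorizeTarget <- function(profile, siteCount) {
  counts <- if (is.list(profile)) profile$counts else profile
  if (length(counts) == 0L) stop("empty degradome profile")
  mx <- max(counts)
  med <- median(counts[counts > 0])
  if (siteCount >= mx) return(1L)
  if (siteCount >= med) return(2L)
  3L
}

#' Call miRNA cleavage targets from degradome profiles
#'
#' A candidate site is supported when the degradome profile carries at least
#' \code{minReads} tag 5' ends within \code{shift} nt of the expected
#' cleavage coordinate; the site count is that sum, and the target class is
#' assigned by \code{\link{categorizeTarget}}.
#'
#' @param profiles output of \code{\link{mapDegradome}}.
#' @param mirnas named character vector of miRNA sequences.
#' @param transcriptome named \code{DNAStringSet} or character vector.
#' @param maxScore complementarity cutoff, default 4.5.
#' @param shift cleavage coordinate slack in nt, default 1.
#' @param minReads minimum supporting tag count, default 2.
#' @return data.frame with columns mirna, transcript, start, score,
#'   cleavage_pos, site_count, category.
#' @export
callTargets <- function(profiles, mirnas, transcriptome, maxScore = 4.5,
                        shift = 1L, minReads = 2L) {
  tx <- setNames(canonDNA(as.character(transcriptome)), names(transcriptome))
  out <- list()
  for (mir in names(mirnas)) {
    for (txid in names(tx)) {
      sites <- predictSites(mirnas[[mir]], tx[[txid]], maxScore)
      if (nrow(sites) == 0L) next
      prof <- profiles[[txid]]
      if (is.null(prof)) next
      pos <- as.integer(names(prof$counts))
      for (r in seq_len(nrow(sites))) {
        cp <- sites$cleavage_pos[r]
        nearby <- abs(pos - cp) <= shift
        siteCount <- sum(prof$counts[nearby])
        if (siteCount >= minReads) {
          out[[length(out) + 1L]] <- data.frame(
            mirna = mir, transcript = txid, start = sites$start[r],
            score = sites$score[r], cleavage_pos = cp,
            site_count = siteCount,
            category = categorizeTarget(prof, siteCount))
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), score = numeric(0),
                      cleavage_pos = integer(0), site_count = numeric(0),
                      category = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Degradome annotation summary
#'
#' Partitions degradome tags into cDNA_sense, cDNA_antisense, ncRNA classes
#' and unannotated, with read-level and unique-level counts and percentages
#' (two decimals), plus the count of unique tags with a perfect genome match.
#'
#' @param tags a \linkS4class{UniqueTagSet} of clean degradome tags.
#' @param transcriptome named \code{DNAStringSet} or character vector.
#' @param ncrnaRefs named list of ncRNA reference sets (see
#'   \code{\link{classifyTags}}).
#' @param genome optional named \code{DNAStringSet} for the genome-mapped
#'   count.
#' @return data.frame with columns category, read_count, unique_count,
#'   read_pct, unique_pct; genome-mapped unique count as attribute
#'   \code{"genome_mapped"}.
#' @export
degradomeSummary <- function(tags, transcriptome, ncrnaRefs = list(),
                             genome = NULL) {
  seqs <- tagSequences(tags)
  tot <- tagTotals(tags)
  tx <- canonDNA(as.character(transcriptome))
  ncCat <- classifyTags(seqs, ncrnaRefs)
  categories <- vapply(seq_along(seqs), function(i) {
    if (ncCat[i] != "unann") return(ncCat[i])
    if (any(grepl(seqs[i], tx, fixed = TRUE))) return("cDNA_sense")
    if (any(grepl(revComp(seqs[i]), tx, fixed = TRUE))) return("cDNA_antisense")
    "unann"
  }, character(1))
  cats <- c("cDNA_antisense", "cDNA_sense", "rRNA", "snRNA", "snoRNA",
            "tRNA", "unann")
  res <- data.frame(
    category = cats,
    read_count = vapply(cats, function(cc) sum(tot[categories == cc]),
                        numeric(1)),
    unique_count = vapply(cats, function(cc) sum(categories == cc),
                          integer(1)),
    row.names = NULL)
  res$read_pct <- percentOf(res$read_count, max(1, sum(tot)), 2)
  res$unique_pct <- percentOf(res$unique_count, max(1, length(seqs)), 2)
  if (!is.null(genome)) {
    mapped <- vapply(seqs, function(s) length(mapExact(s, genome)) > 0L,
                     logical(1))
    attr(res, "genome_mapped") <- sum(mapped)
  }
  res
}
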