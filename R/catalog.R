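# known-miRNA identification, families, precursors and isomiRs

# minimal ungapped mismatch count between two sequences over all relative
# offsets; overhanging bases on either side count as mismatches
minMismatchUngapped <- function(a, b) {
  a <- strsplit(canonDNA(a), "")[[1]]
  b <- strsplit(canonDNA(b), "")[[1]]
  la <- length(a); lb <- length(b)
  best <- la + lb
  for (o in (-(lb - 1L)):(la - 1L)) {
    loA <- max(1L, o + 1L); hiA <- min(la, o + lb)
    if (hiA < loA) next
    idxA <- loA:hiA
    idxB <- idxA - o
    ov <- length(idxA)
    mm <- sum(a[idxA] != b[idxB]) + (la - ov) + (lb - ov)
    if (mm < best) best <- mm
  }
  best
}

#' Match a tag against a mature-miRNA reference with tolerance for mismatches
#'
#' Ungapped comparison of each tag against each mature sequence whose length
#' is within 2 nt of the tag's, over all relative offsets; overhanging bases
#' count as mismatches. Hits with minimal mismatch count at most
#' \code{maxMismatch} are reported.
#'
#' @param tags a \linkS4class{UniqueTagSet} or character vector (18-30 nt).
#' @param matureDb named character vector of mature miRNA sequences.
#' @param maxMismatch maximum mismatches, default 2.
#' @return data.frame with columns tag, mirna, family, mismatches.
#' @export
matchKnown <- function(tags, matureDb, maxMismatch = 2L) {
  if (length(matureDb) == 0L) stop("empty mature miRNA database")
  seqs <- if (is(tags, "UniqueTagSet")) tagSequences(tags) else canonDNA(tags)
  mseq <- canonDNA(matureDb)
  mlen <- nchar(mseq)
  out <- list()
  # vectorized over all tags of one length at a time; offsets whose overhang
  # alone exceeds the mismatch budget cannot yield a hit and are skipped
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    tagMat <- do.call(rbind, strsplit(seqs[idx], ""))
    best <- NULL
    for (j in which(abs(mlen - L) <= 2L)) {
      m <- strsplit(mseq[j], "")[[1]]
      Lm <- length(m)
      bestMM <- rep(Inf, length(idx))
      for (o in (-(Lm - 1L)):(L - 1L)) {
        loT <- max(1L, o + 1L); hiT <- min(L, o + Lm)
        if (hiT < loT) next
        ov <- hiT - loT + 1L
        overhang <- (L - ov) + (Lm - ov)
        if (overhang > maxMismatch) next
        idxT <- loT:hiT
        idxM <- idxT - o
        ham <- rowSums(tagMat[, idxT, drop = FALSE] !=
                         matrix(m[idxM], length(idx), ov, byrow = TRUE))
        bestMM <- pmin(bestMM, ham + overhang)
      }
      hit <- which(bestMM <= maxMismatch)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          tag = seqs[idx][hit], mirna = names(matureDb)[j],
          mismatches = as.integer(bestMM[hit]))
    }
  }
  if (!length(out))
    return(data.frame(tag = character(0), mirna = character(0),
                      family = character(0), mismatches = integer(0)))
  res <- do.call(rbind, out)
  res$family <- vapply(res$mirna, function(nm)
    tryCatch(assignFamily(nm), error = function(e) NA_character_),
    character(1))
  rownames(res) <- NULL
  res[, c("tag", "mirna", "family", "mismatches")]
}

#' Derive the family name from a miRNA name
#'
#' Strips the species prefix and variant suffixes: \code{cga-miR167a.1}
#' belongs to family \code{miR167}. Novel-style names (\code{can-miRn-12})
#' map to family \code{miRn}.
#'
#' @param name miRNA name.
#' @return family string, e.g. \code{"miR167"}.
#' @export
assignFamily <- function(name) {
  if (grepl("^[A-Za-z]{2,5}-miRn-[0-9]+$", name)) return("miRn")
  m <- regmatches(name, regexec("^[A-Za-z]{2,5}-miR([0-9]+)[A-Za-z]*([.-][0-9A-Za-z]+)*$",
                                name))[[1]]
  if (length(m) < 2L || !nzchar(m[2]))
    stop("cannot parse miRNA name: ", name)
  paste0("miR", m[2])
}

#' Locate genomic precursors for a set of mature miRNAs
#'
#' Maps each mature sequence to the genome with perfect match, extracts
#' flanked windows, folds and evaluates them; loci passing the hairpin
#' criteria become precursors. Overlapping passing windows are merged into
#' one precursor, so a precursor can carry several matures and one mature
#' can own several precursors.
#'
#' @param matures named character vector of mature sequences.
#' @param genome named \code{DNAStringSet}.
#' @param flank,mfeMax,minPaired,maxBulge,backend see \code{\link{callNovel}}.
#' @return list with \code{precursors} (data.frame: id, chrom, start, end),
#'   \code{hits} (data.frame: mature, precursor_id, chrom, start,
#'   end, strand, mfe) and \code{candidates} (HairpinCandidate list for the
#'   passing loci).
#' @export
locatePrecursors <- function(matures, genome, flank = 200L, mfeMax = -20,
                             minPaired = 14L, maxBulge = 4L, backend = NULL) {
  hits <- list(); cands <- list(); wins <- list()
  for (nm in names(matures)) {
    loci <- mapExact(matures[[nm]], genome)
    for (k in seq_along(loci)) {
      w <- extractWindow(loci[k], genome, flank)
      fr <- foldRNA(w$window, backend = backend)
      cand <- evaluateHairpin(w$window, fr$structure, fr$mfe, w$matureSpan,
                              mfeMax = mfeMax, minPaired = minPaired,
                              maxBulge = maxBulge, locus = loci[k])
      if (hairpinPasses(cand)) {
        hits[[length(hits) + 1L]] <- data.frame(
          mature = nm,
          chrom = as.character(GenomicRanges::seqnames(loci[k])),
          start = GenomicRanges::start(loci[k]),
          end = GenomicRanges::end(loci[k]),
          strand = as.character(GenomicRanges::strand(loci[k])),
          mfe = fr$mfe)
        wins[[length(wins) + 1L]] <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(loci[k])),
          start = w$wstart, end = w$wend)
        cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  if (!length(hits)) {
    return(list(precursors = data.frame(id = character(0), chrom = character(0),
                                        start = integer(0), end = integer(0),
                                        strand = character(0)),
                hits = data.frame(mature = character(0),
                                  precursor_id = character(0)),
                candidates = list()))
  }
  hits <- do.call(rbind, hits)
  windf <- do.call(rbind, wins)
  # both arms of one stem give overlapping windows on opposite strands;
  # a precursor is the merged genomic region regardless of arm strand
  wingr <- GenomicRanges::GRanges(windf$chrom,
                                  IRanges::IRanges(windf$start, windf$end))
  red <- GenomicRanges::reduce(wingr)
  # each window lies inside exactly one reduced region, in query order
  ov <- GenomicRanges::findOverlaps(wingr, red, select = "first")
  hits$precursor_id <- paste0("prec-", ov)
  precursors <- data.frame(
    id = paste0("prec-", seq_along(red)),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red))
  rownames(hits) <- NULL
  list(precursors = precursors, hits = hits, candidates = cands)
}

#' Detect isomiRs on a precursor
#'
#' Tags mapping exactly into the precursor whose start and end coordinates
#' are each within \code{maxShift} nt of a mature's span are grouped with
#' that mature as its isomiRs.
#'
#' @param precursorSeq precursor (or window) sequence.
#' @param tags character vector of tag sequences.
#' @param matureSpans named list of integer(2) 0-based half-open mature spans
#'   on the precursor.
#' @param maxShift maximum coordinate shift, default 2.
#' @return named list (one element per mature) of data.frames with columns
#'   tag, start, end, shift_start, shift_end.
#' @export
detectIsomirs <- function(precursorSeq, tags, matureSpans, maxShift = 2L) {
  precursorSeq <- canonDNA(precursorSeq)
  tags <- canonDNA(tags)
  groups <- lapply(matureSpans, function(sp)
    data.frame(tag = character(0), start = integer(0), end = integer(0),
               shift_start = integer(0), shift_end = integer(0)))
  for (tg in unique(tags)) {
    m <- gregexpr(tg, precursorSeq, fixed = TRUE)[[1]]
    if (m[1] < 0L) next
    for (pos in as.integer(m)) {
      st <- pos - 1L; en <- st + nchar(tg)  # 0-based half-open
      for (nm in names(matureSpans)) {
        sp <- matureSpans[[nm]]
        ds <- st - sp[1]; de <- en - sp[2]
        if (abs(ds) <= maxShift && abs(de) <= maxShift) {
          groups[[nm]] <- rbind(groups[[nm]], data.frame(
            tag = tg, start = st, end = en,
            shift_start = ds, shift_end = de))
        }
      }
    }
  }
  groups
}
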