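#' Exact genome mapping of a tag
#'
#' Finds every perfect-match locus of a tag on both strands of the genome.
#' A minus-strand locus means the tag equals the reverse complement of the
#' plus-strand slice.
#'
#' @param tag a single tag sequence (T/U accepted).
#' @param genome named \code{DNAStringSet}.
#' @return \link[GenomicRanges]{GRanges} of loci, sorted by (chrom, start,
#'   strand) with "+" before "-".
#' @export
mapExact <- function(tag, genome) {
  stopifnot(length(tag) == 1L)
  tag <- canonDNA(tag)
  si <- GenomeInfoDb::Seqinfo(seqnames = names(genome))
  hits <- list()
  for (pat in list(c(tag, "+"), c(revComp(tag), "-"))) {
    m <- Biostrings::vmatchPattern(pat[1], genome)
    for (chr in names(genome)) {
      ir <- m[[chr]]
      if (length(ir))
        hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
          chr, ir, strand = pat[2], seqinfo = si)
    }
  }
  if (length(hits) == 0L)
    return(GenomicRanges::GRanges(seqinfo = si))
  gr <- do.call(c, hits)
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr),
           as.character(GenomicRanges::strand(gr)))]
}

#' Extract a genome window around a mapped tag
#'
#' Extends the locus by \code{flank} nucleotides on both sides, clamped at
#' chromosome ends. Minus-strand windows are reverse-complemented so the
#' mature always reads 5' to 3' on the returned window; the mature span is
#' given in 0-based half-open window coordinates.
#'
#' @param locus \code{GRanges} of length 1.
#' @param genome named \code{DNAStringSet}.
#' @param flank flank length in nt, default 200.
#' @return list with \code{window} (character), \code{matureSpan}
#'   (integer(2), 0-based half-open) and the genomic window bounds
#'   \code{wstart}, \code{wend} (1-based closed).
#' @export
extractWindow <- function(locus, genome, flank = 200L) {
  stopifnot(length(locus) == 1L)
  chr <- as.character(GenomicRanges::seqnames(locus))
  if (!chr %in% names(genome)) stop("locus chromosome not in genome: ", chr)
  chromLen <- Biostrings::width(genome[chr])
  s <- GenomicRanges::start(locus); e <- GenomicRanges::end(locus)
  if (s < 1L || e > chromLen) stop("locus outside chromosome bounds")
  wstart <- max(1L, s - flank)
  wend <- min(chromLen, e + flank)
  win <- as.character(Biostrings::subseq(genome[[chr]], wstart, wend))
  if (as.character(GenomicRanges::strand(locus)) == "-") {
    win <- revComp(win)
    span <- c(wend - e, wend - s + 1L)
  } else {
    span <- c(s - wstart, e - wstart + 1L)
  }
  list(window = win, matureSpan = as.integer(span),
       wstart = wstart, wend = wend)
}

#' Predict the minimum-free-energy secondary structure of a window
#'
#' The default backend is the package's dynamic program over nearest-neighbor
#' stacking energies (see the methods vignette); any backend must return a
#' balanced pseudoknot-free dot-bracket string of the window length with only
#' AU/UA/CG/GC/GU/UG pairs and an MFE of at most 0 whenever an admissible
#' pair exists.
#'
#' @param window window sequence, length at least 40 nt.
#' @param backend NULL for the built-in engine, or a function
#'   \code{function(seq)} returning \code{list(structure=, mfe=)}.
#' @return list with \code{structure} (dot-bracket) and \code{mfe} (kcal/mol).
#' @export
foldRNA <- function(window, backend = getOption("plantSmallRNA.foldBackend")) {
  if (nchar(window) < 40L)
    stop("window too short to fold (< 40 nt)")
  res <- if (is.null(backend)) .fold_stack_cpp(canonDNA(window))
         else backend(window)
  if (nchar(res$structure) != nchar(window))
    stop("fold backend returned a structure of the wrong length")
  res
}

#' RNAfold backend for foldRNA
#'
#' Builds a \code{\link{foldRNA}} backend that shells out to the ViennaRNA
#' \code{RNAfold} executable, for cross-checking or replacing the built-in
#' engine where ViennaRNA is installed.
#'
#' @param exe path to the RNAfold executable.
#' @return a backend function suitable for \code{foldRNA(backend=)}.
#' @export
viennaFoldBackend <- function(exe = "RNAfold") {
  function(window) {
    rna <- gsub("T", "U", canonDNA(window), fixed = TRUE)
    out <- system2(exe, args = c("--noPS"), input = rna, stdout = TRUE)
    line <- out[2]
    structure <- sub("\\s.*$", "", line)
    mfe <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
    list(structure = structure, mfe = mfe)
  }
}

#' Derive the miRNA* span from a structure and mature span
#'
#' The star is the block pairing with the mature across the stem, positioned
#' so that each duplex strand carries a 2-nt 3' overhang: it runs from the
#' partner of the 3'-most paired mature base (excluding the mature's last
#' two bases) to two nucleotides past the partner of the mature's 5'-most
#' paired base. With internal bulges the star length can differ from the
#' mature's by the bulge size.
#'
#' @param structure dot-bracket string.
#' @param matureSpan integer(2), 0-based half-open span on the structure.
#' @param minPaired minimum paired mature bases required to define a star,
#'   default 10.
#' @param maxSpace maximal spacing between the mature and its star (the
#'   loop side), default 35 nt; pairs beyond it belong to flanking helices,
#'   not to the miRNA duplex.
#' @return integer(2), 0-based half-open star span.
#' @export
deriveStar <- function(structure, matureSpan, minPaired = 10L,
                       maxSpace = 35L, maxBulge = 4L) {
  pt <- pairTable(structure)
  a <- matureSpan[1] + 1L; b <- matureSpan[2]  # 1-based inclusive
  if (a < 1L || b > length(pt)) stop("mature span outside structure")
  geo <- .duplexGeometry(pt, a, b, maxSpace, maxBulge)
  paired <- geo$block[geo$block <= max(a, b - 2L)]
  if (length(paired) < minPaired)
    stop("star undefined: fewer than ", minPaired, " paired mature bases")
  partners <- pt[paired]
  lo <- min(partners); hi <- max(partners) + 2L
  if (hi > length(pt)) hi <- length(pt)  # clamp at window edge
  c(lo - 1L, hi)
}

# duplex geometry for a mature [a, b] (1-based) on a pair table:
# - pairs whose partner lies beyond maxSpace + mature length of the mature's
#   edges belong to flanking structure, not to the miRNA/miRNA* duplex;
# - remaining paired positions are segmented into blocks, broken where the
#   mature-side or partner-side jump exceeds the bulge tolerance, and the
#   largest block is taken as the duplex
.duplexGeometry <- function(pt, a, b, maxSpace, maxBulge) {
  L <- b - a + 1L
  reach <- maxSpace + L + 4L
  mat <- a:b
  p <- pt[mat]
  near <- p > 0L & ((p > b & p <= b + reach) | (p < a & p >= a - reach))
  paired <- mat[near]
  partners <- p[near]
  bothSides <- any(partners > b) && any(partners < a)
  block <- integer(0)
  if (length(paired)) {
    brk <- c(FALSE, abs(diff(paired)) - 1L > maxBulge |
               abs(abs(diff(partners)) - 1L) > maxBulge |
               diff(sign(partners - b)) != 0)
    grp <- cumsum(brk)
    sizes <- table(grp)
    block <- paired[grp == names(sizes)[which.max(sizes)]]
  }
  list(paired = paired, partners = partners, bothSides = bothSides,
       block = block)
}

#' Evaluate a folded window against miRNA precursor criteria
#'
#' Sets four flags: \code{mfe_ok} (MFE at or below the threshold),
#' \code{arm_ok} (all duplex-paired mature bases pair to the same side, i.e.
#' the mature sits on one arm and does not straddle the loop),
#' \code{pairing_ok} (at least \code{minPaired} mature bases paired within
#' the duplex and no internal bulge larger than \code{maxBulge}), and
#' \code{overhang_ok} (the derived miRNA/miRNA* duplex leaves exactly 2
#' unpaired nt at each strand's 3' end). Only pairs whose partner lies
#' within \code{maxSpace} + mature length of the mature count towards the
#' duplex; more distant pairs belong to flanking structure.
#'
#' @param window window sequence.
#' @param structure dot-bracket structure of the window.
#' @param mfe minimum free energy of the structure, kcal/mol.
#' @param matureSpan integer(2), 0-based half-open mature span on the window.
#' @param mfeMax MFE threshold, default -20 kcal/mol.
#' @param minPaired minimum paired mature bases, default 14.
#' @param maxBulge largest tolerated internal bulge (nt), default 4.
#' @param maxSpace maximal mature/star spacing, default 35 nt.
#' @param locus optional \code{GRanges} recording the genomic locus.
#' @return a \linkS4class{HairpinCandidate}.
#' @export
evaluateHairpin <- function(window, structure, mfe, matureSpan,
                            mfeMax = -20, minPaired = 14L, maxBulge = 4L,
                            maxSpace = 35L,
                            locus = GenomicRanges::GRanges("unk",
                              IRanges::IRanges(1, 1))) {
  n <- nchar(window)
  if (matureSpan[1] < 0L || matureSpan[2] > n || matureSpan[1] >= matureSpan[2])
    stop("mature span outside window")
  pt <- pairTable(structure)
  a <- matureSpan[1] + 1L; b <- matureSpan[2]
  geo <- .duplexGeometry(pt, a, b, maxSpace, maxBulge)

  mfe_ok <- mfe <= mfeMax

  # the mature must sit on one arm: self-pairing inside the mature means it
  # contains the loop, and more than a couple of duplex pairs on the
  # minority side mean it straddles the loop (one or two stray pairs into
  # flanking helices are tolerated)
  selfPaired <- any(pt[a:b] >= a & pt[a:b] <= b)
  nRight <- sum(geo$partners > b)
  nLeft <- sum(geo$partners < a)
  arm_ok <- length(geo$paired) > 0L && !selfPaired &&
    min(nRight, nLeft) <= 2L

  # the dominant block already satisfies the bulge tolerance internally,
  # so pairing quality reduces to its size
  pairing_ok <- length(geo$block) >= minPaired

  starSpan <- c(NA_integer_, NA_integer_)
  overhang_ok <- FALSE
  if (arm_ok) {
    star <- tryCatch(deriveStar(structure, matureSpan, maxSpace = maxSpace,
                                maxBulge = maxBulge),
                     error = function(e) NULL)
    if (!is.null(star)) {
      starSpan <- star
      sIdx <- (star[1] + 1L):star[2]
      disjoint <- star[2] <= matureSpan[1] || star[1] >= matureSpan[2]
      # mature's two 3'-terminal bases must not pair into the star block
      mat3 <- pt[max(a, b - 1L):b]
      matFree <- !any(mat3 >= star[1] + 1L & mat3 <= star[2])
      # star's two 3'-terminal bases must not pair into the mature block
      star3 <- pt[max(star[1] + 1L, star[2] - 1L):star[2]]
      starFree <- !any(star3 >= a & star3 <= b)
      overhang_ok <- disjoint && matFree && starFree
    }
  }

  new("HairpinCandidate", locus = locus, window = window,
      structure = structure, mfe = as.numeric(mfe),
      matureSpan = as.integer(matureSpan), starSpan = as.integer(starSpan),
      flags = c(mfe_ok = mfe_ok, arm_ok = arm_ok, pairing_ok = pairing_ok,
                overhang_ok = overhang_ok))
}

#' Call novel miRNAs from unannotated tags
#'
#' Maps each sufficiently abundant unannotated tag to the genome, extracts
#' flanked windows around every exact locus, folds them, and emits the tag
#' as a novel mature miRNA when at least one locus passes all hairpin
#' criteria. Novel names are assigned in order of descending tag abundance
#' (\code{can-miRn-1}, \code{can-miRn-2}, ...).
#'
#' @param tags a \linkS4class{UniqueTagSet} of unannotated tags.
#' @param genome named \code{DNAStringSet}.
#' @param flank window flank, default 200 nt.
#' @param mfeMax MFE threshold, default -20 kcal/mol.
#' @param minCount minimum total read count across libraries, default 5.
#' @param minPaired,maxBulge duplex criteria, see
#'   \code{\link{evaluateHairpin}}.
#' @param backend optional fold backend for \code{\link{foldRNA}}.
#' @return list with \code{calls} (data.frame: name, sequence, chrom, start,
#'   end, strand, total, mfe) and \code{candidates} (every evaluated
#'   \linkS4class{HairpinCandidate}, passing or not).
#' @export
callNovel <- function(tags, genome, flank = 200L, mfeMax = -20,
                      minCount = 5L, minPaired = 14L, maxBulge = 4L,
                      backend = NULL) {
  seqs <- tagSequences(tags)
  tot <- tagTotals(tags)
  keep <- tot >= minCount
  logStage("call_novel", length(seqs), sum(keep), list(min_count = minCount))
  seqs <- seqs[keep]; tot <- tot[keep]
  calls <- list(); cands <- list()
  for (i in seq_along(seqs)) {
    loci <- mapExact(seqs[i], genome)
    for (k in seq_along(loci)) {
      w <- extractWindow(loci[k], genome, flank)
      fr <- foldRNA(w$window, backend = backend)
      cand <- evaluateHairpin(w$window, fr$structure, fr$mfe, w$matureSpan,
                              mfeMax = mfeMax, minPaired = minPaired,
                              maxBulge = maxBulge, locus = loci[k])
      cands[[length(cands) + 1L]] <- cand
      if (hairpinPasses(cand)) {
        calls[[length(calls) + 1L]] <- data.frame(
          sequence = seqs[i],
          chrom = as.character(GenomicRanges::seqnames(loci[k])),
          start = GenomicRanges::start(loci[k]),
          end = GenomicRanges::end(loci[k]),
          strand = as.character(GenomicRanges::strand(loci[k])),
          total = tot[i], mfe = fr$mfe)
      }
    }
  }
  if (length(calls)) {
    calls <- do.call(rbind, calls)
    seqOrder <- unique(calls$sequence[order(-calls$total, calls$sequence)])
    calls$name <- paste0("can-miRn-", match(calls$sequence, seqOrder))
    calls <- calls[order(-calls$total, calls$sequence, calls$chrom, calls$start),
                   c("name", "sequence", "chrom", "start", "end", "strand",
                     "total", "mfe")]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(name = character(0), sequence = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        total = numeric(0), mfe = numeric(0))
  }
  list(calls = calls, candidates = cands)
}
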