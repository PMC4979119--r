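#' Classify unique tags into annotation categories
#'
#' Assigns each tag to exactly one category in the fixed priority order
#' rRNA > tRNA > snRNA > snoRNA > exon_sense > exon_antisense >
#' intron_sense > intron_antisense > unann. An ncRNA match is an exact
#' substring hit against a reference sequence in either orientation.
#' Genomic sense/antisense is decided from the tag's exact mapping strand
#' versus the feature strand; a tag hitting several features takes the
#' highest-priority category.
#'
#' @param tags a \linkS4class{UniqueTagSet} or character vector of sequences.
#' @param ncrnaRefs named list of reference sequence sets (character vectors
#'   or \code{DNAStringSet}s), with names among rRNA, tRNA, snRNA, snoRNA.
#' @param geneModels a \linkS4class{GeneModelSet} (may be NULL).
#' @param genome named \code{DNAStringSet} (may be NULL; genomic categories
#'   then unavailable).
#' @return character vector of categories, one per tag.
#' @export
classifyTags <- function(tags, ncrnaRefs = list(), geneModels = NULL,
                         genome = NULL) {
  seqs <- if (is(tags, "UniqueTagSet")) tagSequences(tags) else canonDNA(tags)
  allowed <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  if (length(ncrnaRefs) && !all(names(ncrnaRefs) %in% allowed))
    stop("unknown ncRNA class: ",
         paste(setdiff(names(ncrnaRefs), allowed), collapse = ", "))
  refs <- lapply(ncrnaRefs, function(r) canonDNA(as.character(r)))
  cat_out <- rep("unann", length(seqs))
  undecided <- rep(TRUE, length(seqs))

  # ncRNA classes in priority order; a tag (or its reverse complement) that
  # is a substring of any reference in the class belongs to that class
  rcs <- revComp(seqs)
  for (cls in allowed) {
    rr <- refs[[cls]]
    if (is.null(rr) || !length(rr)) next
    hay <- paste(rr, collapse = "#")
    idx <- which(undecided)
    hit <- vapply(idx, function(i)
      grepl(seqs[i], hay, fixed = TRUE) || grepl(rcs[i], hay, fixed = TRUE),
      logical(1))
    cat_out[idx[hit]] <- cls
    undecided[idx[hit]] <- FALSE
  }

  if (!is.null(genome) && !is.null(geneModels) && any(undecided)) {
    idx <- which(undecided)
    loci <- .mapTagsBulk(seqs[idx], genome)
    if (length(loci)) {
      exGr <- unlist(exonRanges(geneModels), use.names = FALSE)
      inGr <- unlist(intronRanges(geneModels), use.names = FALSE)
      best <- rep(5L, length(idx))  # 1..4 feature priority, 5 = unann
      featCat <- c("exon_sense", "exon_antisense", "intron_sense",
                   "intron_antisense")
      for (f in 1:4) {
        gr <- if (f <= 2) exGr else inGr
        if (length(gr) == 0L) next
        hits <- GenomicRanges::findOverlaps(loci, gr, ignore.strand = TRUE)
        if (length(hits) == 0L) next
        same <- as.character(GenomicRanges::strand(loci))[
          S4Vectors::queryHits(hits)] ==
          as.character(GenomicRanges::strand(gr))[S4Vectors::subjectHits(hits)]
        want <- if (f %% 2L == 1L) same else !same
        tagIdx <- loci$tag[S4Vectors::queryHits(hits)[want]]
        best[unique(tagIdx)] <- pmin(best[unique(tagIdx)], f)
      }
      cat_out[idx[best < 5L]] <- featCat[best[best < 5L]]
    }
  }
  cat_out
}

# exact-match loci for many tags at once: tags grouped by width into PDicts,
# matched against both strands; returns GRanges with a tag index column
.mapTagsBulk <- function(seqs, genome) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(genome))
  out <- list()
  lens <- nchar(seqs)
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    fwd <- Biostrings::DNAStringSet(seqs[idx])
    rev <- Biostrings::reverseComplement(fwd)
    for (strand in c("+", "-")) {
      pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
      for (chr in names(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[chr]])
        n <- lengths(m)
        if (sum(n) == 0L) next
        ir <- unlist(m)
        gr <- GenomicRanges::GRanges(chr, ir, strand = strand, seqinfo = si)
        gr$tag <- rep(idx, n)
        out[[length(out) + 1L]] <- gr
      }
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    gr$tag <- integer(0)
    return(gr)
  }
  do.call(c, out)
}

#' Annotation categories in reporting order
#' @export
annotationCategories <- function() {
  c("exon_antisense", "exon_sense", "intron_antisense", "intron_sense",
    "rRNA", "snRNA", "snoRNA", "tRNA", "unann")
}

#' Per-library annotation summary table
#'
#' Partitions tags across the annotation categories and reports read-level
#' and unique-tag-level counts with percentages of the library's clean reads
#' and unique tags (two decimals, half-up).
#'
#' @param tags a \linkS4class{UniqueTagSet}.
#' @param ncrnaRefs,geneModels,genome see \code{\link{classifyTags}}.
#' @param categories optional precomputed category per tag (skips
#'   classification).
#' @return data.frame with columns library, category, read_count,
#'   unique_count, read_pct, unique_pct; one block of rows per library, plus
#'   the tag categories as an attribute \code{"categories"}.
#' @export
buildAnnotationTable <- function(tags, ncrnaRefs = list(), geneModels = NULL,
                                 genome = NULL, categories = NULL) {
  if (is.null(categories))
    categories <- classifyTags(tags, ncrnaRefs, geneModels, genome)
  stopifnot(length(categories) == length(tags))
  cats <- annotationCategories()
  counts <- tagCounts(tags)
  out <- list()
  for (lib in libraryNames(tags)) {
    libCounts <- counts[, lib]
    present <- libCounts > 0L
    readTot <- sum(libCounts)
    uniqTot <- sum(present)
    rows <- data.frame(
      library = lib, category = cats,
      read_count = vapply(cats, function(cc)
        sum(libCounts[categories == cc]), numeric(1)),
      unique_count = vapply(cats, function(cc)
        sum(present & categories == cc), integer(1)),
      row.names = NULL)
    rows$read_pct <- percentOf(rows$read_count, max(1, readTot), 2)
    rows$unique_pct <- percentOf(rows$unique_count, max(1, uniqTot), 2)
    out[[lib]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "categories") <- categories
  res
}
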