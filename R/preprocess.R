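#' Quality filter for raw small-RNA reads
#'
#' A read survives when its mean Phred quality is at least \code{minMeanQ}
#' (inclusive) and it contains at most \code{maxN} ambiguous (N) bases.
#'
#' @param reads data.frame from \code{\link{readFastqRecords}} (columns
#'   \code{sequence} and list column \code{quality}).
#' @param minMeanQ minimum mean Phred score, default 20.
#' @param maxN maximum number of N bases, default 0.
#' @return logical vector, TRUE for reads that pass.
#' @export
qualityFilter <- function(reads, minMeanQ = 20, maxN = 0L) {
  if (is.null(reads$quality) || any(lengths(reads$quality) == 0L))
    stop("quality filter requires per-base quality scores")
  meanq <- vapply(reads$quality, mean, numeric(1))
  nN <- vapply(gregexpr("N", reads$sequence, fixed = TRUE),
               function(m) sum(m > 0L), integer(1))
  keep <- meanq >= minMeanQ & nN <= maxN
  logStage("quality_filter", nrow(reads), sum(keep),
           list(min_mean_q = minMeanQ, max_n = maxN))
  keep
}

#' Trim the 3' adapter from read sequences
#'
#' Finds the leftmost position at which a prefix of the adapter (length at
#' least \code{minOverlap}) matches with at most \code{maxMismatch}
#' mismatches and returns the insert before it. Reads with no adapter hit,
#' and adapter-adapter ligation products (empty insert), return NA.
#'
#' @param sequences character vector of read sequences.
#' @param adapter 3' adapter sequence; default is the standard Illumina
#'   small-RNA 3' adapter.
#' @param minOverlap minimum matched adapter prefix length, default 6.
#' @param maxMismatch maximum mismatches in the matched prefix, default 1.
#' @return character vector of trimmed inserts, NA where no valid insert.
#' @export
trimAdapter <- function(sequences, adapter = "TGGAATTCTCGGGTGCCAAGG",
                        minOverlap = 6L, maxMismatch = 1L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  pos <- .trim_adapter_cpp(as.character(sequences), adapter,
                           as.integer(minOverlap), as.integer(maxMismatch))
  out <- rep(NA_character_, length(sequences))
  keep <- pos > 0L
  out[keep] <- substr(sequences[keep], 1L, pos[keep])
  logStage("trim_adapter", length(sequences), sum(keep),
           list(adapter = adapter, min_overlap = minOverlap,
                max_mismatch = maxMismatch))
  out
}

#' Length filter for clean tags
#'
#' @param sequences character vector of sequences (NAs dropped).
#' @param lo,hi inclusive length bounds, defaults 18 and 30.
#' @return the sequences with lo <= length <= hi.
#' @export
lengthFilter <- function(sequences, lo = 18L, hi = 30L) {
  if (lo > hi) stop("length filter bounds inverted: lo > hi")
  sequences <- sequences[!is.na(sequences)]
  keep <- nchar(sequences) >= lo & nchar(sequences) <= hi
  logStage("length_filter", length(sequences), sum(keep),
           list(lo = lo, hi = hi))
  sequences[keep]
}

#' Collapse cleaned reads into unique tags with per-library counts
#'
#' @param readsByLibrary named list: library id -> character vector of clean
#'   read sequences.
#' @return a \linkS4class{UniqueTagSet} ordered by descending total count,
#'   ties broken lexicographically.
#' @export
collapseUnique <- function(readsByLibrary) {
  stopifnot(is.list(readsByLibrary), !is.null(names(readsByLibrary)))
  readsByLibrary <- lapply(readsByLibrary, canonDNA)
  seqs <- sort(unique(unlist(readsByLibrary, use.names = FALSE)))
  counts <- vapply(readsByLibrary, function(r) {
    tab <- table(r)
    as.integer(tab[match(seqs, names(tab))]) -> v
    v[is.na(v)] <- 0L
    v
  }, integer(length(seqs)))
  counts <- matrix(counts, nrow = length(seqs),
                   dimnames = list(NULL, names(readsByLibrary)))
  UniqueTagSet(seqs, counts)
}

#' Tag- or read-level length distribution
#'
#' @param tags a \linkS4class{UniqueTagSet}.
#' @param weighted if TRUE, weight each tag by its total read count
#'   (read-level distribution); otherwise count distinct tags per length.
#' @return named integer vector, length -> count, over the observed range.
#' @export
lengthDistribution <- function(tags, weighted = FALSE) {
  len <- nchar(tagSequences(tags))
  w <- if (weighted) tagTotals(tags) else rep(1, length(len))
  if (length(len) == 0L) return(setNames(integer(0), character(0)))
  out <- tapply(w, len, sum)
  setNames(as.integer(out), names(out))
}

#' Per-library cleaning summary
#'
#' Builds the per-library read-accounting table (total, high-quality, clean,
#' unique reads, and percent clean) with percentages rounded half-up to one
#' decimal, as conventional in published summary tables.
#'
#' @param counts data.frame with columns \code{library}, \code{total},
#'   \code{high_quality}, \code{clean}, \code{unique}.
#' @return the same data.frame with a \code{clean_pct} column appended.
#' @export
summarizeCleaning <- function(counts) {
  need <- c("library", "total", "high_quality", "clean", "unique")
  if (!all(need %in% names(counts)))
    stop("missing columns: ", paste(setdiff(need, names(counts)), collapse = ", "))
  if (any(counts$clean > counts$high_quality) ||
      any(counts$high_quality > counts$total))
    stop("inconsistent counts: need clean <= high_quality <= total")
  counts$clean_pct <- percentOf(counts$clean, counts$total, 1)
  counts
}

#' One-call cleaning of raw FASTQ libraries
#'
#' Applies quality filtering, 3' adapter trimming and 18-30-nt length
#' selection to each library, then collapses to unique tags.
#'
#' @param fastqByLibrary named list: library id -> FASTQ path or a records
#'   data.frame from \code{\link{readFastqRecords}}.
#' @param adapter,minOverlap,maxMismatch see \code{\link{trimAdapter}}.
#' @param minMeanQ,maxN see \code{\link{qualityFilter}}.
#' @param lo,hi see \code{\link{lengthFilter}}.
#' @return list with \code{tags} (a \linkS4class{UniqueTagSet}),
#'   \code{summary} (a \code{\link{summarizeCleaning}} table) and
#'   \code{cleanReads} (named list of clean sequences per library).
#' @export
cleanLibraries <- function(fastqByLibrary, adapter = "TGGAATTCTCGGGTGCCAAGG",
                           minOverlap = 6L, maxMismatch = 1L,
                           minMeanQ = 20, maxN = 0L, lo = 18L, hi = 30L) {
  cleanReads <- list()
  tab <- data.frame(library = character(0), total = integer(0),
                    high_quality = integer(0), clean = integer(0),
                    unique = integer(0))
  for (lib in names(fastqByLibrary)) {
    rec <- fastqByLibrary[[lib]]
    if (is.character(rec)) rec <- readFastqRecords(rec)
    total <- nrow(rec)
    hq <- rec[qualityFilter(rec, minMeanQ, maxN), , drop = FALSE]
    trimmed <- trimAdapter(hq$sequence, adapter, minOverlap, maxMismatch)
    clean <- lengthFilter(trimmed, lo, hi)
    cleanReads[[lib]] <- canonDNA(clean)
    tab <- rbind(tab, data.frame(library = lib, total = total,
                                 high_quality = nrow(hq),
                                 clean = length(clean),
                                 unique = length(unique(cleanReads[[lib]]))))
  }
  list(tags = collapseUnique(cleanReads), summary = summarizeCleaning(tab),
       cleanReads = cleanReads)
}
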