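#' UniqueTagSet: collapsed unique small-RNA tags with per-library counts
#'
#' The unit flowing through annotation, miRNA identification and expression:
#' one row per distinct tag sequence, one count column per library. Rows are
#' ordered by descending total count, ties broken lexicographically by
#' sequence, so output is deterministic.
#'
#' @slot sequences character vector of distinct tag sequences (uppercase DNA).
#' @slot counts integer matrix, tags x libraries, non-negative.
#' @exportClass UniqueTagSet
setClass("UniqueTagSet",
  representation(sequences = "character", counts = "matrix"))

setValidity("UniqueTagSet", function(object) {
  msgs <- character(0)
  if (nrow(object@counts) != length(object@sequences))
    msgs <- c(msgs, "counts must have one row per tag sequence")
  if (anyDuplicated(object@sequences))
    msgs <- c(msgs, "tag sequences must be unique")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (is.null(colnames(object@counts)))
    msgs <- c(msgs, "count columns must be named by library")
  if (length(msgs)) msgs else TRUE
})

#' Construct a UniqueTagSet
#'
#' @param sequences character vector of tag sequences (T/U accepted).
#' @param counts matrix of non-negative counts (tags x libraries) with
#'   library column names.
#' @return a \linkS4class{UniqueTagSet}, rows sorted by descending total
#'   count then sequence.
#' @export
UniqueTagSet <- function(sequences, counts) {
  sequences <- canonDNA(sequences)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  tot <- rowSums(counts)
  ord <- order(-tot, sequences)
  new("UniqueTagSet", sequences = sequences[ord],
      counts = counts[ord, , drop = FALSE])
}

#' @describeIn UniqueTagSet tag sequences, in set order
#' @param x a UniqueTagSet.
#' @export
tagSequences <- function(x) x@sequences

#' @describeIn UniqueTagSet tags x libraries count matrix
#' @export
tagCounts <- function(x) x@counts

#' @describeIn UniqueTagSet per-tag total counts over libraries
#' @export
tagTotals <- function(x) rowSums(x@counts)

#' @describeIn UniqueTagSet library (column) names
#' @export
libraryNames <- function(x) colnames(x@counts)

setMethod("length", "UniqueTagSet", function(x) length(x@sequences))

setMethod("show", "UniqueTagSet", function(object) {
  cat("UniqueTagSet with", length(object@sequences), "tags across",
      ncol(object@counts), "libraries\n")
  if (length(object@sequences)) {
    n <- min(3L, length(object@sequences))
    for (i in seq_len(n))
      cat("  ", object@sequences[i], " total=", sum(object@counts[i, ]), "\n",
          sep = "")
    if (length(object@sequences) > n) cat("  ...\n")
  }
})

setMethod("[", "UniqueTagSet", function(x, i, j, ..., drop = FALSE) {
  new("UniqueTagSet", sequences = x@sequences[i],
      counts = x@counts[i, , drop = FALSE])
})

#' GeneModelSet: transcript models with exon/intron structure
#'
#' @slot transcripts \link[GenomicRanges]{GRanges} of transcript spans, named
#'   by transcript id.
#' @slot exons \link[GenomicRanges]{GRangesList} of exons per transcript,
#'   sorted and disjoint.
#' @slot introns \link[GenomicRanges]{GRangesList}: the gaps between
#'   consecutive exons within each transcript span.
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(transcripts = "GRanges", exons = "GRangesList",
                 introns = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  msgs <- character(0)
  ids <- names(object@transcripts)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "transcripts must have unique names")
  if (!identical(names(object@exons), ids) ||
      !identical(names(object@introns), ids))
    msgs <- c(msgs, "exons/introns must be named like transcripts")
  for (id in ids) {
    ex <- object@exons[[id]]
    if (length(ex) > 1L) {
      st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
      if (is.unsorted(st) || any(st[-1] <= en[-length(en)])) {
        msgs <- c(msgs, paste0("exons of ", id, " must be sorted and disjoint"))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@transcripts), "transcripts\n")
})

#' @describeIn GeneModelSet transcript spans (named GRanges)
#' @param x a GeneModelSet.
#' @export
transcriptRanges <- function(x) x@transcripts

#' @describeIn GeneModelSet exon ranges per transcript
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GeneModelSet intron ranges per transcript
#' @export
intronRanges <- function(x) x@introns

#' HairpinCandidate: one genome window evaluated against miRNA precursor
#' criteria
#'
#' Window coordinates are 0-based half-open on the (strand-oriented) window
#' sequence. A candidate passes when all four flags (\code{mfe_ok},
#' \code{arm_ok}, \code{pairing_ok}, \code{overhang_ok}) are TRUE.
#'
#' @slot locus GRanges of length 1: the mature tag's genomic locus.
#' @slot window character: window sequence (plus-strand oriented to the tag).
#' @slot structure character: dot-bracket secondary structure of the window.
#' @slot mfe numeric: minimum free energy, kcal/mol.
#' @slot matureSpan integer(2): mature [start, end) on the window.
#' @slot starSpan integer(2): derived star [start, end) on the window, or NA.
#' @slot flags named logical(4).
#' @exportClass HairpinCandidate
setClass("HairpinCandidate",
  representation(locus = "GRanges", window = "character",
                 structure = "character", mfe = "numeric",
                 matureSpan = "integer", starSpan = "integer",
                 flags = "logical"))

setValidity("HairpinCandidate", function(object) {
  msgs <- character(0)
  if (nchar(object@structure) != nchar(object@window))
    msgs <- c(msgs, "structure length must equal window length")
  ok <- tryCatch({ pairTable(object@structure); TRUE },
                 error = function(e) FALSE)
  if (!ok) msgs <- c(msgs, "structure brackets must balance")
  need <- c("mfe_ok", "arm_ok", "pairing_ok", "overhang_ok")
  if (!all(need %in% names(object@flags)))
    msgs <- c(msgs, "flags must contain mfe_ok, arm_ok, pairing_ok, overhang_ok")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HairpinCandidate TRUE when all precursor criteria hold
#' @param object a HairpinCandidate.
#' @export
hairpinPasses <- function(object) all(object@flags)

#' @describeIn HairpinCandidate the named criterion flags
#' @export
hairpinFlags <- function(object) object@flags

setMethod("show", "HairpinCandidate", function(object) {
  cat("HairpinCandidate", as.character(GenomicRanges::seqnames(object@locus)),
      paste0("[", GenomicRanges::start(object@locus) - 1L, ",",
             GenomicRanges::end(object@locus), ")"),
      as.character(GenomicRanges::strand(object@locus)), "\n")
  cat("  window", nchar(object@window), "nt; MFE",
      sprintf("%.2f", object@mfe), "kcal/mol;",
      if (hairpinPasses(object)) "PASS" else "fail", "\n")
  cat("  flags:", paste(names(object@flags), object@flags, sep = "=",
                        collapse = " "), "\n")
})

#' SimulationTruth: planted ground truth for a synthetic dataset
#'
#' @slot mirnas data.frame: name, sequence, family, status (known/novel),
#'   chrom, start, end (1-based closed mature locus, GRanges convention),
#'   strand, baseline (relative abundance).
#' @slot decoys data.frame: sequence, chrom, start, end — tags planted in
#'   non-hairpin context.
#' @slot foldChanges numeric matrix, miRNA x stage: expected
#'   numerator-line/denominator-line fold change.
#' @slot dispersion numeric: negative-binomial dispersion of replicate counts.
#' @slot targets data.frame: mirna, transcript, cleavage_pos (0-based
#'   coordinate of the planted cleavage tag 5' end).
#' @slot categoryProps named numeric: generating proportions for background
#'   read categories.
#' @slot seed integer seed the dataset was generated from.
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(mirnas = "data.frame", decoys = "data.frame",
                 foldChanges = "matrix", dispersion = "numeric",
                 targets = "data.frame", categoryProps = "numeric",
                 seed = "integer"))

setValidity("SimulationTruth", function(object) {
  msgs <- character(0)
  if (any(object@foldChanges <= 0)) msgs <- c(msgs, "fold changes must be > 0")
  if (nrow(object@mirnas) &&
      !all(rownames(object@foldChanges) %in% object@mirnas$name))
    msgs <- c(msgs, "foldChanges rows must name planted miRNAs")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", sum(object@mirnas$status == "known"), "known +",
      sum(object@mirnas$status == "novel"), "novel miRNAs,",
      nrow(object@decoys), "decoys,", nrow(object@targets),
      "target pairs (seed", object@seed, ")\n")
})

#' @describeIn SimulationTruth planted miRNA table
#' @param x a SimulationTruth.
#' @export
truthMirnas <- function(x) x@mirnas

#' @describeIn SimulationTruth planted decoy table
#' @export
truthDecoys <- function(x) x@decoys

#' @describeIn SimulationTruth planted miRNA-target pairs
#' @export
truthTargets <- function(x) x@targets

#' @describeIn SimulationTruth fold-change matrix (miRNA x stage)
#' @export
truthFoldChanges <- function(x) x@foldChanges
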