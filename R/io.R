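#' Read a FASTA file into sequence records
#'
#' Thin validating wrapper around \code{\link[Biostrings]{readBStringSet}}:
#' the file is first scanned so that structural problems are reported with
#' their line number, then parsed. Sequences are uppercased; U and T are both
#' accepted and preserved as written.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns \code{id} and \code{sequence}, one row per
#'   record, in file order.
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(id = character(0), sequence = character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("FASTA parse error at line 1: expected '>' header")
  for (i in which(hdr)) {
    if (nchar(trimws(sub("^>", "", lines[i]))) == 0L)
      stop("FASTA parse error at line ", i, ": empty header")
    if (i == length(lines) || hdr[i + 1L])
      stop("FASTA parse error at line ", i, ": record has empty sequence")
  }
  bad <- which(!hdr & grepl("[^ACGTUNacgtun]", lines))
  if (length(bad))
    stop("FASTA parse error at line ", bad[1], ": non-nucleotide characters")
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  data.frame(id = sub("\\s.*$", "", names(ss)),
             sequence = toupper(as.character(ss)),
             row.names = NULL)
}

#' Write sequence records as FASTA
#'
#' @param records data.frame with \code{id} and \code{sequence} columns, or a
#'   named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFastaRecords <- function(records, path) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records))
  ss <- Biostrings::BStringSet(records$sequence)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into sequence records
#'
#' Validates the 4-line record structure (reporting the offending line on
#' failure, including sequence/quality length mismatches) and decodes
#' qualities to integer Phred scores.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns \code{id}, \code{sequence} and a list
#'   column \code{quality} of integer Phred scores.
#' @export
readFastqRecords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = I(list())))
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error at line ", length(lines),
         ": incomplete 4-line record")
  idl <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  ql <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(idl, "@"))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 1L,
         ": expected '@' header")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 3L,
         ": expected '+' separator")
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 4L,
         ": quality length differs from sequence length")
  qual <- lapply(ql, function(q) as.integer(charToRaw(q)) - 33L)
  data.frame(id = sub("\\s.*$", "", sub("^@", "", idl)),
             sequence = toupper(sq), quality = I(qual), row.names = NULL)
}

#' Write sequence records as FASTQ (Phred+33)
#'
#' @param records data.frame with \code{id}, \code{sequence} and list column
#'   \code{quality} (integer Phred scores per base).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFastqRecords <- function(records, path) {
  stopifnot(all(nchar(records$sequence) == lengths(records$quality)))
  qs <- vapply(records$quality,
               function(q) rawToChar(as.raw(q + 33L)), character(1))
  out <- as.vector(rbind(paste0("@", records$id), records$sequence, "+", qs))
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon features via
#' \code{\link[rtracklayer]{import.gff3}} and assembles one model per
#' mRNA/transcript with exons sorted along the genome and introns derived as
#' the gaps between consecutive exons. Coordinates are held in the usual
#' \link[GenomicRanges]{GRanges} 1-based closed convention.
#'
#' @param path path to a GFF3 file.
#' @return a \linkS4class{GeneModelSet}.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  buildGeneModels(gr)
}

# assemble a GeneModelSet from an annotation GRanges (type/ID/Parent columns)
buildGeneModels <- function(gr) {
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  txid <- as.character(tx$ID)
  if (anyDuplicated(txid)) stop("duplicate transcript IDs in GFF3")
  names(tx) <- txid
  ex <- gr[type == "exon"]
  parents <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
  exl <- list(); inl <- list()
  for (id in txid) {
    exi <- ex[parents == id]
    exi <- GenomicRanges::sort(exi)
    span <- tx[id]
    if (length(exi) == 0L)
      stop("transcript ", id, " has no exons")
    if (any(GenomicRanges::start(exi) < GenomicRanges::start(span)) ||
        any(GenomicRanges::end(exi) > GenomicRanges::end(span)))
      stop("exon outside bounds of transcript ", id)
    gaps <- IRanges::gaps(IRanges::ranges(exi),
                          start = GenomicRanges::start(span),
                          end = GenomicRanges::end(span))
    exl[[id]] <- GenomicRanges::granges(exi)
    inl[[id]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(span)[rep(1L, length(gaps))], gaps,
      strand = GenomicRanges::strand(span)[rep(1L, length(gaps))])
  }
  new("GeneModelSet", transcripts = GenomicRanges::granges(tx),
      exons = GenomicRanges::GRangesList(exl),
      introns = GenomicRanges::GRangesList(inl))
}

#' Write a gene model set as GFF3
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGeneModels <- function(models, path) {
  tx <- transcriptRanges(models)
  exs <- exonRanges(models)
  rows <- character(0)
  for (id in names(tx)) {
    t1 <- tx[id]
    rows <- c(rows, paste(as.character(GenomicRanges::seqnames(t1)), "plantSmallRNA",
                          "mRNA", GenomicRanges::start(t1), GenomicRanges::end(t1), ".",
                          as.character(GenomicRanges::strand(t1)), ".",
                          paste0("ID=", id), sep = "\t"))
    ex <- exs[[id]]
    for (k in seq_along(ex)) {
      rows <- c(rows, paste(as.character(GenomicRanges::seqnames(ex))[k], "plantSmallRNA",
                            "exon", GenomicRanges::start(ex)[k], GenomicRanges::end(ex)[k],
                            ".", as.character(GenomicRanges::strand(ex))[k], ".",
                            paste0("ID=", id, ".exon", k, ";Parent=", id), sep = "\t"))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Write a data frame as a fixed-format TSV table
#'
#' Header line first, tab-separated, with numeric columns formatted to a
#' fixed number of decimals per the column spec.
#'
#' @param rows data.frame to write.
#' @param colSpec named character vector mapping column names to formats;
#'   currently \code{"<n>dp"} for n fixed decimals (e.g. \code{"2dp"}).
#'   Unspecified columns are written as-is.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTsvTable <- function(rows, colSpec = character(0), path) {
  for (cn in names(colSpec)) {
    if (!cn %in% names(rows))
      stop("column spec names missing column: ", cn)
    dp <- as.integer(sub("dp$", "", colSpec[[cn]]))
    rows[[cn]] <- formatC(roundHalfUp(rows[[cn]], dp), format = "f",
                          digits = dp)
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
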