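# seeded synthetic genomes, libraries and degradome tags with ground truth

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate a synthetic genome with planted miRNA hairpins and gene models
#'
#' Background sequence is uniform random. Each planted miRNA hairpin is
#' mature + loop + reverse complement of the mature, so the folding engine
#' recovers a perfect stem and the locus passes all precursor criteria.
#' Decoys are lone tags planted without a complementary arm, so their
#' windows fail the duplex criteria. Every planted locus is self-verified
#' with the same fold-and-evaluate path the discovery stage uses, and the
#' rare ambiguous draw (a decoy whose random context happens to mimic a
#' duplex, or a hairpin whose terminal base is co-opted by flanking
#' structure) is redrawn, so the ground truth is unambiguous by
#' construction. Gene models (multi-exon, plus strand)
#' provide exon/intron annotation categories and a spliced transcriptome;
#' perfect reverse-complement target sites for the first planted known
#' miRNAs are written into exons, defining degradome ground truth. ncRNA
#' reference sets are generated independently of the genome.
#'
#' @param seed integer RNG seed; all outputs are byte-identical for a seed.
#' @param nChrom,chromLen genome shape, defaults 2 x 15000 nt.
#' @param nKnown,nNovel,nDecoys planted counts, defaults 10, 5, 10.
#' @param nTargets planted miRNA-target pairs (among known miRNAs),
#'   default 5.
#' @param matureLen mature miRNA length, default 21.
#' @param loopLen hairpin loop length, default 12.
#' @param nGenes gene models to plant, default 6.
#' @return list with \code{genome} (DNAStringSet), \code{geneModels}
#'   (\linkS4class{GeneModelSet}), \code{transcriptome} (named character),
#'   \code{ncrnaRefs} (named list), \code{matureDb} (named character of
#'   planted known matures) and \code{truth}
#'   (\linkS4class{SimulationTruth}).
#' @export
makeGenome <- function(seed, nChrom = 2L, chromLen = 15000L, nKnown = 10L,
                       nNovel = 5L, nDecoys = 10L, nTargets = 5L,
                       matureLen = 21L, loopLen = 12L, nGenes = 6L) {
  set.seed(seed)
  footprint <- 2L * matureLen + loopLen
  spacing <- 520L  # window flank + slack, keeps planted loci non-overlapping
  slotsPerChrom <- (chromLen - 600L) %/% spacing
  nPlant <- nKnown + nNovel + nDecoys
  geneLen <- 900L
  geneSlots <- ceiling(geneLen / spacing) + 1L
  if (nPlant + nGenes * geneSlots > nChrom * slotsPerChrom)
    stop("overcrowded genome: cannot place planted loci without overlap")

  chroms <- paste0("chr", seq_len(nChrom))
  genome <- lapply(chroms, function(x) .randSeq(chromLen))
  names(genome) <- chroms

  # slot allocation round-robin over chromosomes
  slots <- expand.grid(slot = seq_len(slotsPerChrom), chrom = chroms,
                       stringsAsFactors = FALSE)
  slots$pos <- 300L + (slots$slot - 1L) * spacing

  plantSeq <- function(chrom, pos, s) {
    substr(genome[[chrom]], pos, pos + nchar(s) - 1L) <<- s
    invisible(NULL)
  }

  # self-check helper: does the planted locus pass (or fail) the same
  # hairpin evaluation the discovery stage applies? Planted miRNAs and
  # decoys are redrawn until the ground truth is unambiguous.
  checkLocus <- function(chrom, pos) {
    g1 <- Biostrings::DNAStringSet(setNames(genome[[chrom]], chrom))
    loc <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(pos, pos + matureLen - 1L))
    w <- extractWindow(loc, g1, flank = 200L)
    f <- foldRNA(w$window)
    hairpinPasses(evaluateHairpin(w$window, f$structure, f$mfe,
                                  w$matureSpan))
  }

  si <- 1L
  mirnas <- list()
  for (i in seq_len(nKnown + nNovel)) {
    known <- i <= nKnown
    chrom <- slots$chrom[si]; pos <- slots$pos[si]; si <- si + 1L
    for (try in 1:25) {
      mature <- .randSeq(matureLen)
      hairpin <- paste0(mature, .randSeq(loopLen), revComp(mature))
      plantSeq(chrom, pos, hairpin)
      if (checkLocus(chrom, pos)) break
      if (try == 25L) stop("could not plant a passing hairpin")
    }
    mirnas[[i]] <- data.frame(
      name = if (known) paste0("syn-miR", 100L + i, "a")
             else paste0("can-miRn-", i - nKnown),
      sequence = mature, status = if (known) "known" else "novel",
      chrom = chrom, start = pos, end = pos + matureLen - 1L,
      strand = "+")
  }
  mirnas <- do.call(rbind, mirnas)
  mirnas$family <- vapply(mirnas$name, function(nm)
    tryCatch(assignFamily(nm), error = function(e) NA_character_),
    character(1))
  mirnas$baseline <- exp(rnorm(nrow(mirnas), log(200), 1.5))
  # the differentially expressed matures are planted as highly abundant,
  # like the dominant guide strands they emulate
  if (nKnown >= 2L)
    mirnas$baseline[1:2] <- pmax(mirnas$baseline[1:2], exp(log(200) + 1.5))

  decoys <- list()
  for (i in seq_len(nDecoys)) {
    chrom <- slots$chrom[si]; pos <- slots$pos[si]; si <- si + 1L
    for (try in 1:25) {
      tag <- .randSeq(matureLen)
      plantSeq(chrom, pos, tag)
      if (!checkLocus(chrom, pos)) break
      if (try == 25L) stop("could not plant a failing decoy")
    }
    decoys[[i]] <- data.frame(sequence = tag, chrom = chrom, start = pos,
                              end = pos + matureLen - 1L)
  }
  decoys <- if (nDecoys) do.call(rbind, decoys) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), end = integer(0))

  # gene models: 3 exons of 250 nt separated by 100-nt introns, plus strand
  gsi <- GenomeInfoDb::Seqinfo(seqnames = chroms)
  txl <- list(); exl <- list(); inl <- list()
  geneStarts <- list()
  for (g in seq_len(nGenes)) {
    chrom <- slots$chrom[si]; pos <- slots$pos[si]; si <- si + geneSlots
    id <- paste0("tx", g)
    exs <- IRanges::IRanges(start = pos + c(0L, 350L, 700L), width = 250L)
    txl[[id]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(pos, pos + 949L), strand = "+", seqinfo = gsi)
    exl[[id]] <- GenomicRanges::GRanges(chrom, exs, strand = "+",
                                        seqinfo = gsi)
    inl[[id]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = pos + c(250L, 600L), width = 100L),
      strand = "+", seqinfo = gsi)
    geneStarts[[id]] <- c(chrom = chrom, pos = pos)
  }
  tx <- do.call(c, unname(txl)); names(tx) <- names(txl)
  geneModels <- new("GeneModelSet", transcripts = tx,
                    exons = GenomicRanges::GRangesList(exl),
                    introns = GenomicRanges::GRangesList(inl))

  # plant perfect reverse-complement target sites inside first exons
  nTargets <- min(nTargets, nKnown, nGenes)
  targets <- list()
  for (k in seq_len(nTargets)) {
    id <- paste0("tx", k)
    info <- geneStarts[[id]]
    mat <- mirnas$sequence[k]
    offset <- 60L  # within exon 1, away from transcript ends
    plantSeq(info["chrom"], as.integer(info["pos"]) + offset, revComp(mat))
    # transcript coordinate of the site equals the exon-1 offset here
    targets[[k]] <- data.frame(
      mirna = mirnas$name[k], transcript = id,
      site_start = offset, cleavage_pos = offset + matureLen - 10L)
  }
  targets <- if (nTargets) do.call(rbind, targets) else
    data.frame(mirna = character(0), transcript = character(0),
               site_start = integer(0), cleavage_pos = integer(0))

  genome <- Biostrings::DNAStringSet(unlist(genome))

  transcriptome <- vapply(names(txl), function(id) {
    ex <- exl[[id]]
    paste(vapply(seq_along(ex), function(k)
      as.character(Biostrings::subseq(
        genome[[as.character(GenomicRanges::seqnames(ex))[k]]],
        GenomicRanges::start(ex)[k], GenomicRanges::end(ex)[k])),
      character(1)), collapse = "")
  }, character(1))

  ncrnaRefs <- list(
    rRNA = setNames(vapply(1:2, function(i) .randSeq(1200L), character(1)),
                    paste0("rRNA", 1:2)),
    tRNA = setNames(vapply(1:4, function(i) .randSeq(75L), character(1)),
                    paste0("tRNA", 1:4)),
    snRNA = setNames(vapply(1:3, function(i) .randSeq(150L), character(1)),
                     paste0("snRNA", 1:3)),
    snoRNA = setNames(vapply(1:3, function(i) .randSeq(110L), character(1)),
                      paste0("snoRNA", 1:3)))

  # default expression design: one miR167-like mature down 3-fold at stages
  # 2-3 in the sterile line, one miR399-like mature down 3-fold throughout
  fc <- matrix(1, nrow(mirnas), 3,
               dimnames = list(mirnas$name, paste0("stage", 1:3)))
  if (nKnown >= 1L) fc[1, 2:3] <- 1 / 3
  if (nKnown >= 2L) fc[2, ] <- 1 / 3
  props <- c(exon_sense = 0.040, exon_antisense = 0.025,
             intron_sense = 0.012, intron_antisense = 0.010,
             rRNA = 0.010, tRNA = 0.0012, snRNA = 0.0004, snoRNA = 0.0002)
  props <- c(props, unann = 1 - sum(props))

  truth <- new("SimulationTruth", mirnas = mirnas, decoys = decoys,
               foldChanges = fc, dispersion = 0.05, targets = targets,
               categoryProps = props, seed = as.integer(seed))
  list(genome = genome, geneModels = geneModels,
       transcriptome = transcriptome, ncrnaRefs = ncrnaRefs,
       matureDb = setNames(mirnas$sequence[mirnas$status == "known"],
                           mirnas$name[mirnas$status == "known"]),
       truth = truth)
}

#' Simulate a negative-binomial miRNA count matrix
#'
#' Counts are drawn per library as NB(mean = baseline share x fold change x
#' depth, size = 1/dispersion); dispersion 0 gives Poisson draws. Fold
#' changes apply to the numerator line only.
#'
#' @param baseline named numeric vector of relative miRNA abundances.
#' @param foldChanges matrix miRNA x stage of numerator-line fold changes.
#' @param dispersion NB dispersion, default 0.05.
#' @param depth expected miRNA-derived reads per library, default 20000.
#' @param replicates,stages design shape, defaults 2 and 3.
#' @param lines character(2): denominator then numerator line labels.
#' @return list with \code{counts} (matrix, miRNA x library) and
#'   \code{design} (data.frame library, line, stage, replicate).
#' @export
simulateCounts <- function(baseline, foldChanges, dispersion = 0.05,
                           depth = 20000, replicates = 2L, stages = 3L,
                           lines = c("fertile", "sterile")) {
  stopifnot(length(lines) == 2L)
  share <- baseline / sum(baseline)
  design <- expand.grid(replicate = seq_len(replicates),
                        stage = seq_len(stages), line = lines,
                        stringsAsFactors = FALSE)
  design$library <- sprintf("%s_s%d_r%d", design$line, design$stage,
                            design$replicate)
  counts <- matrix(0L, length(baseline), nrow(design),
                   dimnames = list(names(baseline), design$library))
  for (j in seq_len(nrow(design))) {
    mu <- share * depth
    if (design$line[j] == lines[2])
      mu <- mu * foldChanges[names(baseline), design$stage[j]]
    counts[, j] <- if (dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else rpois(length(mu), mu)
  }
  list(counts = counts, design = design[, c("library", "line", "stage",
                                            "replicate")])
}

# vectorized background reads for one category: substrings of the category's
# source sequences at uniform positions (antisense = reverse complement)
.bgReadsBulk <- function(category, lens, bundle) {
  n <- length(lens)
  if (n == 0L) return(character(0))
  if (category == "unann") {
    return(vapply(lens, .randSeq, character(1)))
  }
  sliceSeqs <- function(gr) vapply(seq_along(gr), function(k)
    as.character(Biostrings::subseq(
      bundle$genome[[as.character(GenomicRanges::seqnames(gr))[k]]],
      GenomicRanges::start(gr)[k], GenomicRanges::end(gr)[k])),
    character(1))
  if (category %in% c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    src <- unname(bundle$ncrnaRefs[[category]])
  } else if (startsWith(category, "exon")) {
    src <- sliceSeqs(unlist(exonRanges(bundle$geneModels), use.names = FALSE))
  } else {
    src <- sliceSeqs(unlist(intronRanges(bundle$geneModels),
                            use.names = FALSE))
  }
  pick <- sample.int(length(src), n, replace = TRUE)
  avail <- nchar(src)[pick] - lens + 1L
  ok <- avail >= 1L
  starts <- integer(n)
  starts[ok] <- 1L + floor(runif(sum(ok)) * avail[ok])
  reads <- rep(NA_character_, n)
  reads[ok] <- substr(src[pick[ok]], starts[ok], starts[ok] + lens[ok] - 1L)
  if (endsWith(category, "antisense")) reads[ok] <- revComp(reads[ok])
  reads[!is.na(reads)]
}

#' Simulate replicated small-RNA sequencing libraries
#'
#' Emits raw reads (insert + 3' adapter) for a 2-line x 3-stage x
#' 2-replicate design: planted miRNA reads with negative-binomial counts
#' and planted fold changes, decoy-tag reads, and background reads in the
#' annotation categories with a 24-nt-dominant length distribution
#' (secondary 21-nt mode). A small fraction of reads is emitted with low
#' base qualities and a small fraction as adapter-adapter ligation
#' products, so the cleaning stages have work to do; all other reads carry
#' uniform Q40 qualities.
#'
#' @param bundle output of \code{\link{makeGenome}}.
#' @param depth total expected reads per library, default 20000.
#' @param mirnaFrac fraction of depth carried by planted miRNAs,
#'   default 0.18.
#' @param decoyDepth expected reads per decoy tag per library, default 15.
#' @param lowQualRate fraction of reads given mean Phred below 20,
#'   default 0.006.
#' @param dimerRate fraction of adapter-adapter product reads,
#'   default 0.002.
#' @param replicates,stages,lines see \code{\link{simulateCounts}}.
#' @param adapter 3' adapter appended to every read.
#' @return list with \code{reads} (named list of FASTQ-style data.frames),
#'   \code{design}, \code{mirnaCounts} (true planted counts) and
#'   \code{adapter}.
#' @export
simulateSmallRNA <- function(bundle, depth = 20000, mirnaFrac = 0.18,
                             decoyDepth = 15, lowQualRate = 0.006,
                             dimerRate = 0.002, replicates = 2L, stages = 3L,
                             lines = c("fertile", "sterile"),
                             adapter = "TGGAATTCTCGGGTGCCAAGG") {
  truth <- bundle$truth
  mir <- truthMirnas(truth)
  baseline <- setNames(mir$baseline, mir$name)
  sim <- simulateCounts(baseline, truthFoldChanges(truth),
                        dispersion = truth@dispersion,
                        depth = depth * mirnaFrac,
                        replicates = replicates, stages = stages,
                        lines = lines)
  lens <- 18:30
  lenProb <- c(0.02, 0.03, 0.04, 0.08, 0.08, 0.12, 0.45, 0.08,
               0.04, 0.02, 0.02, 0.01, 0.01)  # mode 24, secondary 21
  props <- truth@categoryProps
  nBg <- max(0L, round(depth * (1 - mirnaFrac) -
                         nrow(truthDecoys(truth)) * decoyDepth))
  reads <- list()
  for (j in seq_len(nrow(sim$design))) {
    lib <- sim$design$library[j]
    seqs <- rep(mir$sequence, sim$counts[, j])
    if (nrow(truthDecoys(truth)))
      seqs <- c(seqs, rep(truthDecoys(truth)$sequence,
                          rpois(nrow(truthDecoys(truth)), decoyDepth)))
    cats <- sample(names(props), nBg, replace = TRUE, prob = props)
    ls <- sample(lens, nBg, replace = TRUE, prob = lenProb)
    bg <- unlist(lapply(unique(cats), function(cc)
      .bgReadsBulk(cc, ls[cats == cc], bundle)), use.names = FALSE)
    seqs <- c(seqs, bg)
    raw <- paste0(seqs, adapter)
    nDimer <- rpois(1L, dimerRate * length(raw))
    raw <- c(raw, rep(paste0(adapter, adapter), nDimer))
    raw <- sample(raw)
    qual <- lapply(nchar(raw), function(n) rep(40L, n))
    lowq <- runif(length(raw)) < lowQualRate
    qual[lowq] <- lapply(nchar(raw)[lowq], function(n) rep(8L, n))
    reads[[lib]] <- data.frame(
      id = sprintf("%s_read%d", lib, seq_along(raw)),
      sequence = raw, quality = I(qual))
  }
  list(reads = reads, design = sim$design, mirnaCounts = sim$counts,
       adapter = adapter)
}

#' Simulate a pooled degradome library
#'
#' Signal tags are transcript substrings whose 5' ends sit exactly at the
#' planted cleavage coordinates (counts Poisson around
#' \code{signalDepth}); background tags start uniformly along each
#' transcript at \code{backgroundRate} expected tags per nt.
#'
#' @param bundle output of \code{\link{makeGenome}}.
#' @param signalDepth expected tag count per planted cleavage site,
#'   default 20.
#' @param backgroundRate expected background tags per transcript nt,
#'   default 0.02.
#' @param tagLen degradome tag length, default 20.
#' @return named numeric vector: tag sequence -> count.
#' @export
simulateDegradome <- function(bundle, signalDepth = 20, backgroundRate = 0.02,
                              tagLen = 20L) {
  tx <- bundle$transcriptome
  tgt <- truthTargets(bundle$truth)
  tags <- numeric(0)
  addTag <- function(s, n) {
    if (is.na(s) || nchar(s) < tagLen || n <= 0) return(invisible(NULL))
    tags[s] <<- sum(tags[s], n, na.rm = TRUE)
    invisible(NULL)
  }
  for (r in seq_len(nrow(tgt))) {
    s <- tx[[tgt$transcript[r]]]
    cp <- tgt$cleavage_pos[r]
    addTag(substr(s, cp + 1L, cp + tagLen), rpois(1L, signalDepth))
  }
  for (id in names(tx)) {
    s <- tx[[id]]
    span <- nchar(s) - tagLen
    nbg <- rpois(1L, backgroundRate * span)
    if (nbg > 0L) {
      starts <- sample.int(span, nbg, replace = TRUE)
      for (st in starts) addTag(substr(s, st, st + tagLen - 1L), 1)
    }
  }
  tags
}

#' Score pipeline outputs against planted truth
#'
#' Exact set comparisons of identified known miRNAs, novel hairpin calls,
#' DE calls (with sign) and degradome targets against the
#' \linkS4class{SimulationTruth}. Empty outputs give recall 0 and NULL
#' precision.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param known optional \code{\link{matchKnown}} result.
#' @param novel optional \code{\link{callNovel}} result.
#' @param de optional \code{\link{callDE}} result (pooled mode).
#' @param targets optional \code{\link{callTargets}} result.
#' @return nested list of recall/precision (and for DE, sensitivity and
#'   empirical FDR; for targets, the class of each recovered pair).
#' @export
scoreRecovery <- function(truth, known = NULL, novel = NULL, de = NULL,
                          targets = NULL) {
  mir <- truthMirnas(truth)
  out <- list()
  prec <- function(tp, called) if (called == 0) NULL else tp / called
  if (!is.null(known)) {
    planted <- mir[mir$status == "known", ]
    found <- vapply(seq_len(nrow(planted)), function(i)
      any(known$tag == planted$sequence[i] &
            known$mirna == planted$name[i]), logical(1))
    tp <- sum(known$tag %in% planted$sequence)
    out$known <- list(recall = if (nrow(planted)) mean(found) else NA,
                      precision = prec(tp, nrow(known)))
  }
  if (!is.null(novel)) {
    planted <- mir$sequence[mir$status == "novel"]
    calledSeq <- unique(novel$calls$sequence)
    out$novel <- list(
      recall = if (length(planted)) mean(planted %in% calledSeq) else NA,
      precision = prec(sum(calledSeq %in% planted), length(calledSeq)),
      decoy_false_positives =
        sum(truthDecoys(truth)$sequence %in% calledSeq))
  }
  if (!is.null(de)) {
    fc <- truthFoldChanges(truth)
    expected <- exp(rowMeans(log(fc)))  # geometric mean over stages
    trueDE <- rownames(fc)[abs(log(expected)) > 1e-9]
    called <- de$mirna[de$is_de]
    signOK <- de$mirna[de$is_de &
                         sign(de$log2_ratio) ==
                           sign(log(expected[de$mirna]))]
    out$de <- list(
      sensitivity = if (length(trueDE))
        mean(trueDE %in% signOK) else NA,
      empirical_fdr = if (length(called))
        sum(!(called %in% trueDE)) / length(called) else 0)
  }
  if (!is.null(targets)) {
    tgt <- truthTargets(truth)
    hit <- vapply(seq_len(nrow(tgt)), function(r) {
      rows <- targets$transcript == tgt$transcript[r] &
        abs(targets$cleavage_pos - tgt$cleavage_pos[r]) <= 1
      any(rows)
    }, logical(1))
    cls <- vapply(seq_len(nrow(tgt)), function(r) {
      rows <- which(targets$transcript == tgt$transcript[r] &
                      abs(targets$cleavage_pos - tgt$cleavage_pos[r]) <= 1)
      if (length(rows)) min(targets$category[rows]) else NA_integer_
    }, integer(1))
    out$targets <- list(recall = if (nrow(tgt)) mean(hit) else NA,
                        classes = cls)
  }
  out
}

#' Serialize simulation truth to JSON
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTruth <- function(truth, path) {
  obj <- list(mirnas = truthMirnas(truth), decoys = truthDecoys(truth),
              foldChanges = list(values = truthFoldChanges(truth),
                                 rows = rownames(truthFoldChanges(truth)),
                                 cols = colnames(truthFoldChanges(truth))),
              dispersion = truth@dispersion, targets = truthTargets(truth),
              categoryProps = as.list(truth@categoryProps),
              seed = truth@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Reload simulation truth from JSON
#'
#' @param path path written by \code{\link{writeTruth}}.
#' @return a \linkS4class{SimulationTruth}.
#' @export
readTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fc <- matrix(unlist(obj$foldChanges$values),
               nrow = length(obj$foldChanges$rows),
               dimnames = list(obj$foldChanges$rows, obj$foldChanges$cols))
  new("SimulationTruth",
      mirnas = as.data.frame(obj$mirnas),
      decoys = as.data.frame(obj$decoys),
      foldChanges = fc, dispersion = obj$dispersion,
      targets = as.data.frame(obj$targets),
      categoryProps = unlist(obj$categoryProps),
      seed = as.integer(obj$seed))
}
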