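#' TPM-normalize a miRNA count matrix
#'
#' TPM (transcripts per million) scales each count by the library's clean
#' read total: \code{tpm = count / clean_total * 1e6}. The clean totals are
#' whole-library totals, so each TPM column sums to at most one million.
#'
#' @param counts integer matrix, miRNAs x libraries, with dimnames.
#' @param cleanTotals named numeric vector of clean read totals per library.
#' @param design optional data.frame with columns \code{library},
#'   \code{line}, \code{stage}, \code{replicate}; stored as colData.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assays
#'   \code{counts} and \code{tpm}.
#' @export
tpmNormalize <- function(counts, cleanTotals, design = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("count columns must be named")
  cleanTotals <- cleanTotals[colnames(counts)]
  if (any(is.na(cleanTotals)) || any(cleanTotals <= 0))
    stop("clean totals must be positive for every library")
  tpm <- sweep(counts, 2, cleanTotals, "/") * 1e6
  cd <- S4Vectors::DataFrame(library = colnames(counts),
                             clean_total = as.numeric(cleanTotals))
  if (!is.null(design)) {
    m <- match(colnames(counts), design$library)
    if (any(is.na(m))) stop("library missing from design: ",
                            paste(colnames(counts)[is.na(m)], collapse = ", "))
    cd$line <- design$line[m]
    cd$stage <- design$stage[m]
    cd$replicate <- design$replicate[m]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm), colData = cd)
}

#' Pearson correlation of log-transformed TPM between two replicates
#'
#' @param tpm1,tpm2 TPM vectors over the same miRNAs.
#' @param pseudocount added before the natural log, default 1.
#' @return Pearson r.
#' @export
replicateCorrelation <- function(tpm1, tpm2, pseudocount = 1) {
  stopifnot(length(tpm1) == length(tpm2))
  both <- tpm1 > 0 & tpm2 > 0
  if (sum(both) < 3L)
    stop("need at least 3 miRNAs expressed in both replicates")
  x <- log(tpm1 + pseudocount); y <- log(tpm2 + pseudocount)
  if (var(x) == 0 || var(y) == 0)
    stop("degenerate replicate: zero variance on log scale")
  cor(x, y)
}

#' Two-sided pooled-variance Student's t-test
#'
#' Wraps \code{stats::t.test(var.equal = TRUE)} with explicit handling of
#' the zero-variance degenerate case: equal means give t = 0, p = 1; unequal
#' means with zero pooled variance are flagged degenerate (p = 0).
#'
#' @param a,b numeric vectors, each of length at least 2.
#' @return list with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
tTestPooled <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  df <- length(a) + length(b) - 2L
  if (var(a) == 0 && var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment via \code{stats::p.adjust(method = "BH")}, with
#' input validation; output order matches input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed miRNAs between two lines
#'
#' Compares TPM between the numerator and denominator line with a pooled
#' two-sided Student's t-test and BH-FDR, and filters on fold change
#' computed from pseudocounted mean TPM. The default mode pools the three
#' developmental stages, so each line contributes stages x replicates
#' libraries to its group (one test per miRNA); \code{mode = "per-stage"}
#' instead tests each stage's replicates separately (n = replicates per
#' group) with BH pooled over all miRNA x stage tests, and calls a miRNA
#' differential when any stage is significant. Per-stage fold changes and
#' log2 ratios are reported in both modes.
#'
#' @param se SummarizedExperiment from \code{\link{tpmNormalize}} with
#'   \code{line}, \code{stage}, \code{replicate} in colData.
#' @param numerator,denominator line labels; fold change is
#'   numerator over denominator.
#' @param fcThreshold fold-change threshold (strict), default 1.5; a miRNA
#'   qualifies with fold change > threshold or < 1/threshold.
#' @param qThreshold BH-FDR threshold, default 0.05.
#' @param pseudocount TPM pseudocount for fold changes and ratios, default 1.
#' @param mode "pooled" (default) or "per-stage".
#' @return data.frame with one row per miRNA (pooled) or per miRNA x stage
#'   (per-stage): means, fold change, log2 ratio, t, p, q, is_de, and for
#'   pooled mode the per-stage log2 ratios as attribute \code{"ratios"}
#'   (see \code{\link{log2RatioMatrix}}).
#' @export
callDE <- function(se, numerator = "sterile", denominator = "fertile",
                   fcThreshold = 1.5, qThreshold = 0.05, pseudocount = 1,
                   mode = c("pooled", "per-stage")) {
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(se)
  if (is.null(cd$line) || is.null(cd$stage))
    stop("colData must provide line and stage for every library")
  if (!all(c(numerator, denominator) %in% cd$line))
    stop("line labels not found in design")
  tpm <- SummarizedExperiment::assay(se, "tpm")
  mirnas <- rownames(tpm)
  stages <- sort(unique(cd$stage))

  testBlock <- function(colsA, colsB) {
    res <- lapply(seq_len(nrow(tpm)), function(i)
      tTestPooled(tpm[i, colsA], tpm[i, colsB]))
    data.frame(
      mean_num = rowMeans(tpm[, colsA, drop = FALSE]),
      mean_den = rowMeans(tpm[, colsB, drop = FALSE]),
      t = vapply(res, `[[`, numeric(1), "t"),
      p = vapply(res, `[[`, numeric(1), "p"),
      degenerate = vapply(res, `[[`, logical(1), "degenerate"))
  }

  finish <- function(tab) {
    tab$fold_change <- (tab$mean_num + pseudocount) /
      (tab$mean_den + pseudocount)
    tab$log2_ratio <- log2(tab$fold_change)
    tab$q <- bhFdr(tab$p)
    tab$is_de <- (tab$fold_change > fcThreshold |
                  tab$fold_change < 1 / fcThreshold) & tab$q < qThreshold
    tab
  }

  if (mode == "pooled") {
    tab <- testBlock(which(cd$line == numerator),
                     which(cd$line == denominator))
    tab <- cbind(data.frame(mirna = mirnas), tab)
    tab <- finish(tab)
    attr(tab, "ratios") <- log2RatioMatrix(se, numerator, denominator,
                                           pseudocount)
    rownames(tab) <- NULL
    return(tab)
  }

  out <- list()
  for (st in stages) {
    tab <- testBlock(which(cd$line == numerator & cd$stage == st),
                     which(cd$line == denominator & cd$stage == st))
    out[[as.character(st)]] <- cbind(
      data.frame(mirna = mirnas, stage = st), tab)
  }
  tab <- do.call(rbind, out)
  tab <- finish(tab)
  rownames(tab) <- NULL
  tab
}

#' Per-stage log2 expression ratio matrix
#'
#' log2 of pseudocounted mean TPM of the numerator line over the denominator
#' line at each stage; negative values indicate down-regulation in the
#' numerator line.
#'
#' @inheritParams callDE
#' @return numeric matrix, miRNAs x stages.
#' @export
log2RatioMatrix <- function(se, numerator = "sterile",
                            denominator = "fertile", pseudocount = 1) {
  cd <- SummarizedExperiment::colData(se)
  tpm <- SummarizedExperiment::assay(se, "tpm")
  stages <- sort(unique(cd$stage))
  out <- sapply(stages, function(st) {
    a <- rowMeans(tpm[, cd$line == numerator & cd$stage == st, drop = FALSE])
    b <- rowMeans(tpm[, cd$line == denominator & cd$stage == st, drop = FALSE])
    log2((a + pseudocount) / (b + pseudocount))
  })
  out <- matrix(out, nrow = nrow(tpm),
                dimnames = list(rownames(tpm), paste0("stage", stages)))
  out
}

#' Average-linkage (UPGMA) clustering of expression rows
#'
#' Hierarchical clustering with distance 1 - Pearson correlation between
#' rows and average linkage, as used for expression heat maps.
#'
#' @param x numeric matrix with at least 2 rows (e.g. a log2-ratio matrix).
#' @return an \code{\link[stats]{hclust}} object.
#' @export
averageLinkageCluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to cluster")
  d <- as.dist(1 - cor(t(x)))
  if (any(is.na(d)))
    stop("constant rows give undefined correlation distance")
  hclust(d, method = "average")
}

#' Pearson correlation between two expression series
#'
#' @param x,y numeric vectors over the same samples, length at least 3.
#' @return list with \code{r} and \code{degenerate} (TRUE when either
#'   series is constant, in which case r is NA).
#' @export
exprCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 samples")
  if (var(x) == 0 || var(y) == 0)
    return(list(r = NA_real_, degenerate = TRUE))
  list(r = cor(x, y), degenerate = FALSE)
}
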