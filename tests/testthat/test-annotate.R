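# a tiny hand-built annotation world: one chromosome, one 2-exon gene,
# small ncRNA references
annWorld <- function() {
  set.seed(404)
  chrom <- randSeq(2000)
  exon1 <- c(201, 400); intron <- c(401, 500); exon2 <- c(501, 700)
  gm <- local({
    tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 700),
                                 strand = "+")
    names(tx) <- "t1"
    new("GeneModelSet", transcripts = tx,
        exons = GenomicRanges::GRangesList(t1 = GenomicRanges::GRanges(
          "chr1", IRanges::IRanges(c(201, 501), c(400, 700)), strand = "+")),
        introns = GenomicRanges::GRangesList(t1 = GenomicRanges::GRanges(
          "chr1", IRanges::IRanges(401, 500), strand = "+")))
  })
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  refs <- list(rRNA = randSeq(300), tRNA = randSeq(80),
               snRNA = randSeq(120), snoRNA = randSeq(100))
  list(genome = genome, gm = gm, refs = refs, chrom = chrom,
       exon1 = exon1, intron = intron)
}

test_that("tags are classified by fixed priority", {
  w <- annWorld()
  rTag <- substr(w$refs$rRNA, 10, 30)
  exTag <- substr(w$chrom, 220, 240)     # inside exon 1, sense
  inTag <- substr(w$chrom, 430, 450)     # inside the intron
  noTag <- randSeq(21)
  cats <- classifyTags(c(rTag, exTag, inTag, noTag), w$refs, w$gm, w$genome)
  expect_equal(cats, c("rRNA", "exon_sense", "intron_sense", "unann"))
  # antisense: reverse complement of a feature slice
  cats2 <- classifyTags(c(rc(exTag), rc(inTag)), w$refs, w$gm, w$genome)
  expect_equal(cats2, c("exon_antisense", "intron_antisense"))
  # ncRNA reverse-complement orientation also matches
  expect_equal(classifyTags(rc(rTag), w$refs), "rRNA")
  # a tag in both an rRNA reference and an exon takes the rRNA priority
  w2 <- w
  w2$refs$rRNA <- paste0(w$refs$rRNA, exTag)
  expect_equal(classifyTags(exTag, w2$refs, w$gm, w$genome), "rRNA")
  expect_error(classifyTags("ACGT", list(bogus = "ACGT")), "unknown ncRNA")
})

test_that("classification is stable under reference permutation", {
  w <- annWorld()
  tags <- c(substr(w$refs$tRNA, 5, 25), substr(w$refs$snRNA, 5, 26),
            substr(w$chrom, 300, 320), randSeq(22))
  base <- classifyTags(tags, w$refs, w$gm, w$genome)
  perm <- lapply(w$refs, function(r) rev(r))
  expect_equal(classifyTags(tags, perm, w$gm, w$genome), base)
})

test_that("classifyTags agrees with a brute-force scan on small tag sets", {
  w <- annWorld()
  set.seed(7)
  pool <- c(
    vapply(1:20, function(i) randSeq(sample(18:24, 1)), character(1)),
    vapply(1:10, function(i) {
      cls <- sample(names(w$refs), 1)
      s <- w$refs[[cls]]
      st <- sample(nchar(s) - 22, 1)
      substr(s, st, st + 20)
    }, character(1)),
    vapply(1:10, function(i) {
      st <- sample(1800, 1)
      s <- substr(w$chrom, st, st + 20)
      if (runif(1) < 0.5) rc(s) else s
    }, character(1)))
  got <- classifyTags(pool, w$refs, w$gm, w$genome)

  bruteOne <- function(tag) {
    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      if (grepl(tag, w$refs[[cls]], fixed = TRUE) ||
          grepl(rc(tag), w$refs[[cls]], fixed = TRUE)) return(cls)
    }
    feats <- list(exon_sense = c(201, 400, 1), exon_sense2 = c(501, 700, 1),
                  intron_sense = c(401, 500, 1))
    hitCat <- character(0)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else rc(tag)
      m <- gregexpr(pat, w$chrom, fixed = TRUE)[[1]]
      if (m[1] < 0) next
      for (pos in as.integer(m)) {
        span <- c(pos, pos + nchar(tag) - 1)
        for (nm in names(feats)) {
          f <- feats[[nm]]
          if (span[2] >= f[1] && span[1] <= f[2]) {
            base <- if (startsWith(nm, "exon")) "exon" else "intron"
            ori <- if (strand == "+") "sense" else "antisense"
            hitCat <- c(hitCat, paste0(base, "_", ori))
          }
        }
      }
    }
    prio <- c("exon_sense", "exon_antisense", "intron_sense",
              "intron_antisense")
    for (p in prio) if (p %in% hitCat) return(p)
    "unann"
  }
  expect_equal(got, vapply(pool, bruteOne, character(1), USE.NAMES = FALSE))
})

test_that("annotation table partitions reads and unique tags exactly", {
  w <- annWorld()
  reads <- list(
    lib1 = c(rep(substr(w$refs$rRNA, 10, 30), 3),
             rep(substr(w$chrom, 220, 240), 2), randSeq(21)),
    lib2 = c(substr(w$refs$tRNA, 5, 25), randSeq(22)))
  tags <- collapseUnique(reads)
  tab <- buildAnnotationTable(tags, w$refs, w$gm, w$genome)
  for (lib in names(reads)) {
    sub <- tab[tab$library == lib, ]
    expect_equal(sum(sub$read_count), length(reads[[lib]]))
    expect_equal(sum(sub$unique_count), length(unique(reads[[lib]])))
  }
  # worked percentage arithmetic at printed precision
  expect_equal(percentOf(1820 + 1792 + 1311 + 291, 1971912, 2), 0.26)
  # single-category library reaches 100.00 at unique level
  tagsT <- collapseUnique(list(l = substr(w$refs$tRNA, 5, 25)))
  tabT <- buildAnnotationTable(tagsT, w$refs, w$gm, w$genome)
  expect_equal(tabT$unique_pct[tabT$category == "tRNA"], 100)
})

test_that("generated libraries recover planted category proportions", {
  set.seed(88)
  b <- makeGenome(88, nTargets = 0L)
  sim <- simulateSmallRNA(b, depth = 12000, replicates = 1L, stages = 1L,
                          lowQualRate = 0, dimerRate = 0)
  cl <- cleanLibraries(sim$reads)
  tab <- buildAnnotationTable(cl$tags, b$ncrnaRefs, b$geneModels, b$genome)
  # with no planted targets, non-unann categories come only from background
  # sampling; compare their relative shares with the generating proportions
  props <- b$truth@categoryProps
  feat <- setdiff(names(props), "unann")
  gen <- props[feat] / sum(props[feat])
  obs <- setNames(tab$read_count[match(feat, tab$category)], feat)
  obs <- obs / sum(obs)
  expect_true(all(abs(obs - gen) < 0.06))
  # the planted categories with sizeable mass are all observed
  expect_true(all(obs[c("exon_sense", "exon_antisense", "rRNA")] > 0))
})
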