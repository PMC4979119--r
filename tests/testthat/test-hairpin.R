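test_that("exact mapping reports both strands deterministically", {
  set.seed(61)
  tag <- randSeq(21)
  chrom <- paste0(randSeq(100), tag, randSeq(100), rc(tag), randSeq(50))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  loci <- mapExact(tag, genome)
  expect_equal(length(loci), 2L)
  expect_equal(as.character(GenomicRanges::strand(loci)), c("+", "-"))
  expect_equal(GenomicRanges::start(loci)[1], 101L)
  # palindromic tag at a palindromic site: one locus per strand
  pal <- "ACGTACGTACGTACGTACGT"  # 20-nt, reverse complement of itself
  expect_equal(pal, rc(pal))
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(randSeq(60), pal,
                                                 randSeq(60))))
  loci2 <- mapExact(pal, g2)
  expect_equal(length(loci2), 2L)
  expect_setequal(as.character(GenomicRanges::strand(loci2)), c("+", "-"))
})

test_that("window extraction clamps, flips strand and tracks the mature", {
  set.seed(62)
  chrom <- randSeq(2000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  # interior locus: 21-nt at [1001, 1021] with 200-nt flanks
  loc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1021))
  w <- extractWindow(loc, genome, flank = 200)
  expect_equal(nchar(w$window), 421L)
  expect_equal(w$matureSpan, c(200L, 221L))
  expect_equal(substr(w$window, 201, 221), substr(chrom, 1001, 1021))
  # locus near the chromosome start clamps at 1
  locEdge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 70))
  wE <- extractWindow(locEdge, genome, flank = 200)
  expect_equal(wE$wstart, 1L)
  expect_equal(nchar(wE$window), 70 + 200)
  # window length identity: span + min(flank, upstream) + min(flank, downstream)
  for (st in c(30, 500, 1950)) {
    l <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 20))
    ww <- extractWindow(l, genome, flank = 200)
    expect_equal(nchar(ww$window),
                 21 + min(200, st - 1) + min(200, 2000 - (st + 20)))
  }
  # minus-strand window is the reverse complement of the plus slice
  locM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1021),
                                 strand = "-")
  wM <- extractWindow(locM, genome, flank = 200)
  expect_equal(wM$window, rc(w$window))
  expect_equal(substr(wM$window, wM$matureSpan[1] + 1, wM$matureSpan[2]),
               rc(substr(chrom, 1001, 1021)))
})

test_that("hairpin evaluation flags each criterion independently", {
  set.seed(63)
  mature <- randSeq(21)
  win <- paste0(randSeq(80), makeHairpin(mature), randSeq(80))
  f <- foldRNA(win)
  span <- c(80L, 101L)
  cand <- evaluateHairpin(win, f$structure, f$mfe, span)
  expect_true(hairpinPasses(cand))
  # forcing a shallow MFE fails only the mfe flag
  cand2 <- evaluateHairpin(win, f$structure, -10, span)
  expect_false(hairpinFlags(cand2)[["mfe_ok"]])
  expect_true(hairpinFlags(cand2)[["arm_ok"]])
  expect_false(hairpinPasses(cand2))
  # a mature centered on the loop pairs into both arms
  loopSpan <- c(96L, 117L)  # 5' stem end + loop + 3' stem start
  cand3 <- evaluateHairpin(win, f$structure, f$mfe, loopSpan)
  expect_false(hairpinFlags(cand3)[["arm_ok"]])
  expect_error(evaluateHairpin(win, f$structure, f$mfe, c(400L, 421L)),
               "outside window")
})

test_that("star derivation leaves 2-nt 3' overhangs on a perfect stem", {
  set.seed(64)
  mature <- randSeq(21)
  loop <- 12
  win <- paste0(makeHairpin(mature, loop), strrep("A", 6))
  f <- foldRNA(win)
  star <- deriveStar(f$structure, c(0L, 21L))
  # the star block is the 3' arm shifted by the 2-nt overhang
  expect_equal(star, c(21L + loop + 2L, 21L + loop + 21L + 2L))
  starSeq <- substr(win, star[1] + 1, star[2])
  expect_equal(substr(starSeq, 1, 19), substr(rc(mature), 3, 21))
  # unpaired mature has no defined star
  expect_error(deriveStar(strrep(".", 60), c(0L, 21L)), "star undefined")
})

test_that("novel calling recovers planted hairpins and rejects decoys", {
  set.seed(65)
  b <- makeGenome(65, nKnown = 2L, nNovel = 5L, nDecoys = 6L, nGenes = 2L,
                  nTargets = 0L)
  tr <- truthMirnas(b$truth)
  unann <- c(tr$sequence[tr$status == "novel"], truthDecoys(b$truth)$sequence)
  tags <- UniqueTagSet(unann, matrix(10L, length(unann), 1,
                                     dimnames = list(NULL, "lib")))
  res <- callNovel(tags, b$genome)
  rec <- scoreRecovery(b$truth, novel = res)
  expect_equal(rec$novel$recall, 1.0)
  expect_equal(rec$novel$decoy_false_positives, 0L)
  # called loci include the planted ones
  planted <- tr[tr$status == "novel", ]
  for (i in seq_len(nrow(planted))) {
    expect_true(any(res$calls$sequence == planted$sequence[i] &
                      res$calls$chrom == planted$chrom[i] &
                      res$calls$start == planted$start[i]))
  }
  # abundance floor excludes rare tags
  tags2 <- UniqueTagSet(unann, matrix(2L, length(unann), 1,
                                      dimnames = list(NULL, "lib")))
  expect_equal(nrow(callNovel(tags2, b$genome, minCount = 5)$calls), 0L)
})

test_that("relaxing the MFE threshold never loses candidates", {
  set.seed(66)
  b <- makeGenome(66, nKnown = 2L, nNovel = 3L, nDecoys = 2L, nGenes = 2L,
                  nTargets = 0L)
  tr <- truthMirnas(b$truth)
  unann <- c(tr$sequence[tr$status == "novel"], truthDecoys(b$truth)$sequence)
  tags <- UniqueTagSet(unann, matrix(10L, length(unann), 1,
                                     dimnames = list(NULL, "lib")))
  nPass <- vapply(c(-300, -100, -20, -5), function(th)
    nrow(callNovel(tags, b$genome, mfeMax = th)$calls), numeric(1))
  expect_true(all(diff(nPass) >= 0))
})

test_that("mirrored genomes give mirrored candidate loci", {
  set.seed(67)
  mature <- randSeq(21)
  chrom <- paste0(randSeq(300), makeHairpin(mature), randSeq(300))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  genomeRC <- Biostrings::reverseComplement(genome)
  names(genomeRC) <- names(genome)
  tags <- UniqueTagSet(mature, matrix(10L, 1, 1,
                                      dimnames = list(NULL, "lib")))
  a <- callNovel(tags, genome)
  bb <- callNovel(tags, genomeRC)
  expect_equal(nrow(a$calls), nrow(bb$calls))
  n <- nchar(chrom)
  # loci mirror: start' = n - end + 1
  expect_setequal(n - bb$calls$end + 1L, a$calls$start)
  expect_setequal(n - bb$calls$start + 1L, a$calls$end)
})
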