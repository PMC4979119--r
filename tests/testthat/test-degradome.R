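test_that("degradome tags map sense-only with multi-mapping", {
  set.seed(91)
  t1 <- randSeq(300); t2 <- randSeq(300)
  tag <- substr(t1, 101, 120)
  t2 <- paste0(substr(t2, 1, 50), tag, substr(t2, 71, 300))
  tx <- c(tx1 = t1, tx2 = t2)
  prof <- mapDegradome(setNames(7, tag), tx)
  expect_equal(unname(prof$tx1$counts["100"]), 7)   # 0-based 5' end
  expect_equal(unname(prof$tx2$counts["50"]), 7)    # multi-mapping counted
  # antisense-only matches are not counted
  profA <- mapDegradome(setNames(5, rc(tag)), c(tx1 = t1))
  expect_null(profA$tx1)
})

test_that("complementarity scoring applies position weighting", {
  set.seed(92)
  mir <- randSeq(21)
  perfect <- rc(mir)
  expect_equal(complementarityScore(mir, perfect)$score, 0)
  # G:U wobble opposite miRNA position 5 scores 0.5 x 2
  m5 <- mir; substr(m5, 5, 5) <- "G"
  w5 <- rc(m5)
  # transcript base pairing position 5 is at window index L - 5 + 1
  substr(w5, 21 - 5 + 1, 21 - 5 + 1) <- "T"
  sc <- complementarityScore(m5, w5)
  expect_equal(sc$score, 1.0)
  expect_equal(sc$states[5], "GU")
  # mismatch at position 15 is outside the doubled core: penalty 1.0
  m15 <- mir; w15 <- rc(m15)
  # a base never pairs with itself, so copying the miRNA base forces a
  # mismatch at the window index pairing miRNA position 15
  substr(w15, 21 - 15 + 1, 21 - 15 + 1) <- substr(m15, 15, 15)
  s15 <- complementarityScore(m15, w15)
  expect_equal(s15$states[15], "mismatch")
  expect_equal(s15$score, 1.0)
  expect_error(complementarityScore(mir, randSeq(20)), "length")
})

test_that("hand-applied scoring rules match on random pairs", {
  set.seed(93)
  for (i in 1:50) {
    mir <- randSeq(21); win <- randSeq(21)
    expect_equal(complementarityScore(mir, win)$score,
                 oracleSiteScore(mir, win))
  }
})

test_that("site prediction equals the exhaustive scan", {
  set.seed(94)
  mir <- randSeq(21)
  tx <- paste0(randSeq(400), rc(mir), randSeq(400))
  sites <- predictSites(mir, tx, maxScore = 0)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 400L)
  expect_equal(sites$score, 0)
  expect_equal(sites$cleavage_pos, 400L + 21L - 10L)
  # brute force over every offset at the default cutoff
  tx2 <- randSeq(1000)
  got <- predictSites(mir, tx2, maxScore = 4.5)
  exp_rows <- Filter(Negate(is.null), lapply(0:(1000 - 21), function(s) {
    sc <- oracleSiteScore(mir, substr(tx2, s + 1, s + 21))
    if (sc <= 4.5) data.frame(start = s, score = sc) else NULL
  }))
  if (length(exp_rows)) {
    exp_df <- do.call(rbind, exp_rows)
    expect_equal(got$start, exp_df$start)
    expect_equal(got$score, exp_df$score)
  } else {
    expect_equal(nrow(got), 0L)
  }
  # lowering the cutoff never adds sites
  n45 <- nrow(predictSites(mir, tx2, maxScore = 4.5))
  n30 <- nrow(predictSites(mir, tx2, maxScore = 3.0))
  n0 <- nrow(predictSites(mir, tx2, maxScore = 0))
  expect_true(n0 <= n30 && n30 <= n45)
})

test_that("target classes follow the abundance rule and scale invariance", {
  prof <- list(counts = c("100" = 50, "200" = 10, "300" = 2), total = 62)
  expect_equal(categorizeTarget(prof, 50), 1L)
  expect_equal(categorizeTarget(prof, 10), 2L)   # equals the median
  expect_equal(categorizeTarget(prof, 2), 3L)
  for (k in c(2, 10, 1000)) {
    scaled <- list(counts = prof$counts * k, total = prof$total * k)
    expect_equal(categorizeTarget(scaled, 50 * k), 1L)
    expect_equal(categorizeTarget(scaled, 10 * k), 2L)
    expect_equal(categorizeTarget(scaled, 2 * k), 3L)
  }
  expect_error(categorizeTarget(list(counts = numeric(0)), 1), "empty")
})

test_that("target calling needs tags at the expected cleavage site", {
  set.seed(95)
  mir <- randSeq(21)
  tx <- c(tx1 = paste0(randSeq(200), rc(mir), randSeq(200)))
  cp <- 200 + 21 - 10  # 0-based expected cleavage tag 5' end
  sigTag <- substr(tx[["tx1"]], cp + 1, cp + 20)
  hit <- callTargets(mapDegradome(setNames(5, sigTag), tx),
                     c(mir1 = mir), tx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$cleavage_pos, cp)
  expect_equal(hit$site_count, 5)
  expect_equal(hit$category, 1L)
  # tags 5 nt away do not support the site
  farTag <- substr(tx[["tx1"]], cp + 6, cp + 25)
  miss <- callTargets(mapDegradome(setNames(5, farTag), tx),
                      c(mir1 = mir), tx)
  expect_equal(nrow(miss), 0L)
  # a single read is below the default support threshold
  one <- callTargets(mapDegradome(setNames(1, sigTag), tx),
                     c(mir1 = mir), tx)
  expect_equal(nrow(one), 0L)
})

test_that("planted cleavage signal is recovered as class 1 at 10x background", {
  for (seed in 1:3) {
    set.seed(seed)
    b <- makeGenome(seed, nKnown = 5L, nNovel = 1L, nDecoys = 1L,
                    nGenes = 5L, nTargets = 4L)
    tags <- simulateDegradome(b, signalDepth = 20, backgroundRate = 0.002)
    prof <- mapDegradome(tags, b$transcriptome)
    tr <- truthMirnas(b$truth)
    res <- callTargets(prof, setNames(tr$sequence, tr$name),
                       b$transcriptome)
    rec <- scoreRecovery(b$truth, targets = res)
    expect_equal(rec$targets$recall, 1.0)
    expect_true(all(rec$targets$classes == 1L))
  }
})

test_that("degradome summary partitions tags with printed-style percents", {
  set.seed(96)
  b <- makeGenome(96, nKnown = 3L, nNovel = 1L, nDecoys = 1L, nGenes = 3L,
                  nTargets = 2L)
  # all tags from one cDNA: summary is 100% cDNA_sense
  t1 <- b$transcriptome[[1]]
  tags <- UniqueTagSet(
    vapply(c(1, 41, 81), function(s) substr(t1, s, s + 19), character(1)),
    matrix(c(5L, 3L, 2L), 3, 1, dimnames = list(NULL, "deg")))
  s <- degradomeSummary(tags, b$transcriptome, b$ncrnaRefs, b$genome)
  expect_equal(s$unique_pct[s$category == "cDNA_sense"], 100)
  expect_equal(sum(s$read_count), 10)
  expect_equal(attr(s, "genome_mapped"), 3L)
  # worked percentage arithmetic from printed unique counts
  expect_equal(percentOf(1300884, 1971912, 2), 65.97)
  expect_equal(percentOf(650255, 1971912, 2), 32.98)
})
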