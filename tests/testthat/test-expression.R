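mkSE <- function(counts, totals, design = NULL) {
  tpmNormalize(counts, totals, design)
}

test_that("TPM normalization scales by clean totals", {
  cnt <- matrix(c(50, 0, 100, 10), 2, 2,
                dimnames = list(c("m1", "m2"), c("a", "b")))
  se <- mkSE(cnt, c(a = 1e6, b = 2e6))
  tpm <- SummarizedExperiment::assay(se, "tpm")
  expect_equal(tpm["m1", "a"], 50)
  expect_equal(tpm["m2", "a"], 0)
  expect_equal(tpm["m1", "b"], 50)
  # scale invariance: doubling counts and totals leaves TPM unchanged
  se2 <- mkSE(cnt * 2, c(a = 2e6, b = 4e6))
  expect_equal(SummarizedExperiment::assay(se2, "tpm"), tpm)
  # column sums bounded by 1e6 whenever totals cover all reads
  set.seed(71)
  cnt3 <- matrix(rpois(60, 50), 20, 3,
                 dimnames = list(paste0("m", 1:20), c("x", "y", "z")))
  tot3 <- colSums(cnt3) + rpois(3, 1000)
  se3 <- mkSE(cnt3, setNames(tot3, colnames(cnt3)))
  expect_true(all(colSums(SummarizedExperiment::assay(se3, "tpm")) <= 1e6))
  expect_error(mkSE(cnt, c(a = 0, b = 1)), "positive")
})

test_that("replicate correlation is 1 for identical or rescaled replicates", {
  set.seed(72)
  tpm <- exp(rnorm(100, 5, 1))
  expect_equal(replicateCorrelation(tpm, tpm), 1)
  # multiplying TPM shifts the log scale, leaving r at 1 (up to pseudocount)
  r <- replicateCorrelation(tpm, tpm * 2, pseudocount = 0)
  expect_equal(r, 1)
  expect_error(replicateCorrelation(c(1, 2, 0), c(0, 0, 1)), "at least 3")
  expect_error(replicateCorrelation(rep(5, 10), rep(5, 10), pseudocount = 0),
               "zero variance")
})

test_that("pooled t-test matches the closed form", {
  res <- tTestPooled(c(10, 12), c(20, 22))
  expect_equal(res$t, -7.0710678, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p, 0.0194, tolerance = 1e-2)
  # identical groups: t = 0, p = 1
  res0 <- tTestPooled(c(5, 7), c(5, 7))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # zero variance with different means is flagged degenerate
  resd <- tTestPooled(c(5, 5), c(9, 9))
  expect_true(resd$degenerate)
  expect_error(tTestPooled(1, c(1, 2)), "at least 2")
})

test_that("t-test type-I error is calibrated at the 0.05 level", {
  set.seed(73)
  p <- replicate(4000, tTestPooled(rnorm(2), rnorm(2))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.012)
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  set.seed(74)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bhFdr(p)
    expect_equal(q, oracleBH(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

deSim <- function(seed, nde = 20, fold = 3, n = 200, dispersion = 0.05,
                  sdlog = 1.5) {
  set.seed(seed)
  base <- exp(rnorm(n, log(200), sdlog))
  names(base) <- paste0("m", seq_len(n))
  fc <- matrix(1, n, 3, dimnames = list(names(base), paste0("stage", 1:3)))
  if (nde > 0) fc[seq_len(nde), ] <- fold
  sim <- simulateCounts(base, fc, dispersion = dispersion)
  tot <- colSums(sim$counts) + 2e4
  list(se = mkSE(sim$counts, setNames(tot, colnames(sim$counts)),
                 sim$design),
       de = paste0("m", seq_len(nde)))
}

test_that("planted fold changes are recovered with the correct sign", {
  # moderate abundances so every planted miRNA is quantifiable
  s <- deSim(75, nde = 10, fold = 3, dispersion = 0.01, sdlog = 0.8)
  de <- callDE(s$se)
  called <- de$mirna[de$is_de & de$log2_ratio > 0]
  expect_true(all(s$de %in% called))
})

test_that("the fold-change gate is strict and monotone", {
  cnt <- matrix(c(15, 10, 14, 11, 19, 21, 29, 31), 2, 4, byrow = TRUE,
                dimnames = list(c("m1", "m2"),
                                c("f_r1", "f_r2", "s_r1", "s_r2")))
  design <- data.frame(library = colnames(cnt),
                       line = rep(c("fertile", "sterile"), each = 2),
                       stage = 1L, replicate = rep(1:2, 2))
  se <- mkSE(cnt, setNames(rep(1e4, 4), colnames(cnt)), design)
  # m2 has fold change exactly 1.5 on pseudocounted means: not DE (strict >)
  tpm <- SummarizedExperiment::assay(se, "tpm")
  de <- callDE(se, pseudocount = 0)
  m2 <- de[de$mirna == "m2", ]
  expect_equal(m2$fold_change, 1.5)
  expect_false(m2$is_de)
  # an infinite threshold calls nothing
  s <- deSim(76, nde = 10, fold = 3, dispersion = 0.01)
  expect_equal(sum(callDE(s$se, fcThreshold = Inf)$is_de), 0L)
})

test_that("per-stage mode tests each stage separately", {
  s <- deSim(77, nde = 5, fold = 4, dispersion = 0.01)
  de <- callDE(s$se, mode = "per-stage")
  expect_equal(nrow(de), 200 * 3)
  expect_true(all(c("mirna", "stage", "q", "is_de") %in% names(de)))
  # q-values are BH over the pooled miRNA x stage family
  expect_equal(de$q, bhFdr(de$p))
})

test_that("log2 ratio matrix encodes down-regulation as negative", {
  cnt <- matrix(c(30, 30, 10, 10), 1, 4,
                dimnames = list("m1", c("f1", "f2", "s1", "s2")))
  design <- data.frame(library = colnames(cnt),
                       line = rep(c("fertile", "sterile"), each = 2),
                       stage = 1L, replicate = rep(1:2, 2))
  se <- mkSE(cnt, setNames(rep(1e6, 4), colnames(cnt)), design)
  rat <- log2RatioMatrix(se, pseudocount = 0)
  expect_equal(rat["m1", 1], log2(10 / 30), tolerance = 1e-12)
  # equal means give 0
  cnt2 <- matrix(rep(20, 4), 1, 4, dimnames = dimnames(cnt))
  se2 <- mkSE(cnt2, setNames(rep(1e6, 4), colnames(cnt)), design)
  expect_equal(unname(log2RatioMatrix(se2)[1, 1]), 0)
})

test_that("a miR167-like pattern shows stage-specific down-regulation", {
  set.seed(78)
  base <- exp(rnorm(50, log(500), 0.8))
  names(base) <- paste0("m", 1:50)
  fc <- matrix(1, 50, 3, dimnames = list(names(base), paste0("stage", 1:3)))
  fc["m1", 2:3] <- 1 / 3
  sim <- simulateCounts(base, fc, dispersion = 0.05, depth = 50000)
  se <- mkSE(sim$counts, setNames(colSums(sim$counts) + 5e4,
                                  colnames(sim$counts)), sim$design)
  rat <- log2RatioMatrix(se)
  expect_lt(rat["m1", "stage2"], -1)
  expect_lt(rat["m1", "stage3"], -1)
  expect_gt(rat["m1", "stage1"], -0.5)
})

test_that("average-linkage clustering matches brute-force UPGMA", {
  set.seed(79)
  # identical rows merge first
  x <- rbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2, 3, 4) * 2, r3 = c(4, 1, 3, 2))
  hc <- averageLinkageCluster(x)
  expect_equal(sort(hclustMerges(hc)[[1]]), c(1, 2))  # r2 = affine r1
  expect_error(averageLinkageCluster(x[1, , drop = FALSE]), "at least 2")
  for (i in 1:10) {
    m <- matrix(rnorm(8 * 5), 8, 5)
    d <- as.dist(1 - cor(t(m)))
    hc <- averageLinkageCluster(m)
    oracle <- oracleUPGMA(d)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
    expect_equal(hclustMerges(hc), oracle$merges)
    # UPGMA heights are non-decreasing on correlation distances here
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("expression correlation handles anticorrelation and degeneracy", {
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(exprCorrelation(x, -x)$r, -1)
  expect_true(exprCorrelation(x, rep(2, 6))$degenerate)
  # a planted repressor/target pair correlates strongly negatively
  set.seed(80)
  reg <- c(10, 9, 8, 4, 3, 2) * exp(rnorm(6, 0, 0.05))
  tgt <- c(2, 3, 3.5, 7, 9, 10) * exp(rnorm(6, 0, 0.05))
  expect_lt(exprCorrelation(reg, tgt)$r, -0.8)
})
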