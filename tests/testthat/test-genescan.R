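test_that("anchor blocks collect SNPs by |r| with the anchor", {
  labs <- paste0("rs", 1:4)
  R <- matrix(c(1, 0.3, 0.2, -0.5,
                0.3, 1, 0.1, 0.1,
                0.2, 0.1, 1, 0.1,
                -0.5, 0.1, 0.1, 1), 4, dimnames = list(labs, labs))
  R <- LDMatrix(nearestPDCorrelation(R))
  b <- anchorBlock(R, "rs1", threshold = 0.25)
  expect_setequal(members(b), c("rs1", "rs2", "rs4"))
  expect_equal(anchorSNP(b), "rs1")

  all_in <- anchorBlock(R, "rs1", threshold = 0)
  expect_equal(members(all_in), labs)

  expect_error(anchorBlock(R, "rs99"), "rs99")
})

test_that("a synthetic four-gene region reproduces the prescribed block sizes", {
  fix <- make_scan_ld(block_sizes = c(13, 36, 18, 30),
                      region_sizes = c(20, 50, 25, 40))
  sizes <- vapply(fix$anchors, function(a)
    length(members(anchorBlock(fix$ld, a, 0.25))), integer(1))
  expect_equal(unname(sizes), c(13, 36, 18, 30))
})

test_that("single-SNP blocks reduce every method to the SNP's own P-value", {
  R <- LDMatrix(diag(1), labels = "rs1")
  st <- data.frame(SNP = "rs1", Z = 2.1)
  b <- anchorBlock(R, "rs1", threshold = 0.25)
  res <- geneTest(st, b)
  p1 <- 2 * pnorm(-2.1)
  for (m in c("dot", "tq", "acat", "minp"))
    expect_equal(pValue(res[[m]]), p1, tolerance = 1e-6)
})

test_that("gene tests are invariant to the row order of the input", {
  fix <- make_scan_ld(block_sizes = c(8), region_sizes = c(12))
  b <- anchorBlock(fix$ld, fix$anchors[1], 0.25)
  set.seed(33)
  st <- data.frame(SNP = rownames(fix$ld), Z = rnorm(nrow(fix$ld), 0.5))
  res1 <- geneTest(st, b)
  res2 <- geneTest(st[sample(nrow(st)), ], b)
  for (m in names(res1))
    expect_equal(pValue(res1[[m]]), pValue(res2[[m]]), tolerance = 1e-10)
})

test_that("null gene-level P-values are calibrated and min-P dominates min(p)", {
  fix <- make_scan_ld(block_sizes = c(6), region_sizes = c(8))
  b <- anchorBlock(fix$ld, fix$anchors[1], 0.25)
  Rb <- unclass(blockLD(b))
  set.seed(61)
  n <- 400
  Ch <- chol(Rb)
  ps <- matrix(NA_real_, n, 4,
               dimnames = list(NULL, c("dot", "tq", "acat", "minp")))
  for (i in seq_len(n)) {
    z <- drop(crossprod(Ch, rnorm(6)))
    st <- data.frame(SNP = members(b), Z = z)
    res <- geneTest(st, b)
    ps[i, ] <- vapply(res, pValue, numeric(1))
    expect_gte(pValue(res$minp), min(2 * pnorm(-abs(z))))
  }
  for (m in c("dot", "tq")) {
    ks <- suppressWarnings(ks.test(ps[, m], "punif"))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("a strong signal on a weakly correlated member favours DOT over TQ", {
  # one-factor block: 9 SNPs in tight LD, the signal SNP nearly independent
  loadings <- c(rep(0.85, 9), 0.1)
  labs <- sprintf("rs%02d", 1:10)
  R <- factor_ld(loadings, labels = labs)
  mu <- c(rep(0, 9), 3.5)
  b <- anchorBlock(R, "rs01", threshold = 0)
  set.seed(91)
  Ch <- chol(unclass(R))
  wins <- 0
  n <- 300
  for (i in seq_len(n)) {
    z <- mu + drop(crossprod(Ch, rnorm(10)))
    st <- data.frame(SNP = labs, Z = z)
    res <- geneTest(st, b, methods = c("dot", "tq"))
    wins <- wins + (pValue(res$dot) < pValue(res$tq))
  }
  expect_gt(wins / n, 0.5 + 3 * mc_se(0.5, n))
})

test_that("top contributors decompose the DOT statistic exactly", {
  labs <- paste0("rs", 1:5)
  R <- LDMatrix(diag(5), labels = labs)
  z <- c(0.5, -3, 1, 2.2, -0.1)
  st <- data.frame(SNP = labs, Z = z)
  b <- anchorBlock(R, "rs1", threshold = 0)
  tc <- topContributors(st, b, nComponents = 3)
  # identity LD: components are the SNPs themselves, ranked by |Z|
  top_by_rank <- vapply(split(tc, tc$component),
                        function(d) d$snp[which.max(abs(d$term))], "")
  expect_equal(unname(top_by_rank), c("rs2", "rs4", "rs3"))

  # component terms always reconstruct the component value
  fix <- make_scan_ld(block_sizes = c(7), region_sizes = c(9))
  b2 <- anchorBlock(fix$ld, fix$anchors[1], 0.25)
  set.seed(8)
  st2 <- data.frame(SNP = rownames(fix$ld), Z = rnorm(nrow(fix$ld), 1))
  tc2 <- topContributors(st2, b2, nComponents = 3)
  for (d in split(tc2, tc2$component))
    expect_equal(sum(d$term), d$x[1], tolerance = 1e-8)
  # and the squared components sum to the DOT statistic over all components
  tc_all <- topContributors(st2, b2, nComponents = length(members(b2)))
  xs <- vapply(split(tc_all, tc_all$component), function(d) d$x[1], numeric(1))
  zb <- st2$Z[match(members(b2), st2$SNP)]
  expect_equal(sum(xs^2), testStatistic(dotTest(zb, blockLD(b2))),
               tolerance = 1e-8)
})

test_that("an isolated signal SNP dominates its decorrelated component", {
  loadings <- c(rep(0.85, 6), 0.05)
  labs <- sprintf("rs%02d", 1:7)
  R <- factor_ld(loadings, labels = labs)
  st <- data.frame(SNP = labs, Z = c(rep(0.3, 6), 4.5))
  b <- anchorBlock(R, "rs01", threshold = 0)
  tc <- topContributors(st, b, nComponents = 1)
  expect_equal(tc$snp[1], "rs07")
  expect_gt(abs(tc$term[1]), 3 * max(abs(tc$term[-1])))
})

test_that("the scan runs end to end, isolates failures, and is deterministic", {
  expect_length(scanGenes(data.frame(SNP = "rs1", Z = 1),
                          LDMatrix(diag(1), labels = "rs1"), list()), 0)

  fix <- make_scan_ld(block_sizes = c(5, 7), region_sizes = c(8, 10))
  set.seed(12)
  st <- data.frame(SNP = rownames(fix$ld), Z = rnorm(nrow(fix$ld)))
  genes <- list(list(label = "GENE1", anchor = fix$anchors[1]),
                list(label = "GENE2", anchor = fix$anchors[2]))
  pre <- withr::local_tempfile()
  reports <- scanGenes(st, fix$ld, genes, outPrefix = pre)
  expect_length(reports, 2)
  expect_s4_class(reports$GENE1, "GeneReport")
  expect_true(all(vapply(geneResults(reports$GENE1), pValue, 1) >= 0))
  g <- read.delim(paste0(pre, ".genes.tsv"))
  expect_equal(g$gene, c("GENE1", "GENE2"))
  expect_true(all(c("p_dot", "p_tq", "p_acat", "p_minp") %in% names(g)))

  # deterministic re-run: byte-identical outputs
  pre2 <- withr::local_tempfile()
  scanGenes(st, fix$ld, genes, outPrefix = pre2)
  expect_identical(readLines(paste0(pre, ".genes.tsv")),
                   readLines(paste0(pre2, ".genes.tsv")))
  expect_identical(readLines(paste0(pre, ".contributors.tsv")),
                   readLines(paste0(pre2, ".contributors.tsv")))

  # a bad gene is skipped with a warning, the rest proceed
  genes_bad <- c(genes, list(list(label = "BAD", anchor = "nope")))
  expect_warning(r3 <- scanGenes(st, fix$ld, genes_bad), "BAD")
  expect_length(r3, 2)
})

test_that("summary-statistic files parse, validate, and derive Z from P", {
  f <- withr::local_tempfile()
  writeLines(c("SNP\tP\tSIGN\textra",
               "rs1\t0.05\t-1\tfoo",
               "rs2\t0.5\t1\tbar"), f)
  d <- readSumStats(f)
  expect_equal(d$Z, c(-1, 1) * qnorm(c(0.975, 0.75)), tolerance = 1e-6)
  expect_true("extra" %in% names(d))

  f2 <- withr::local_tempfile()
  writeLines(c("SNP\tZ\tP", "rs1\t2\t0.9"), f2)
  expect_warning(readSumStats(f2), "disagree")

  f3 <- withr::local_tempfile()
  writeLines(c("SNP\tZ", "rs1\t1", "rs1\t2"), f3)
  expect_error(readSumStats(f3), "duplicate")
})
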