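test_that("genotype LD is the sample Pearson correlation of dosages", {
  # identical columns -> r = 1; balanced orthogonal columns -> r = 0
  G1 <- cbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1))
  expect_equal(unclass(ldFromGenotypes(G1))[1, 2], 1.0)
  G2 <- cbind(c(0, 0, 2, 2), c(0, 2, 0, 2))
  expect_equal(unclass(ldFromGenotypes(G2))[1, 2], 0.0)

  set.seed(11)
  G <- matrix(sample(0:2, 30 * 5, replace = TRUE), 30, 5,
              dimnames = list(NULL, paste0("rs", 1:5)))
  R <- ldFromGenotypes(G)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(unclass(R)[i, j], pearson_pair(G[, i], G[, j]),
                 tolerance = 1e-12)

  Gbad <- cbind(rs1 = c(1, 1, 1), rs2 = c(0, 1, 2))
  expect_error(ldFromGenotypes(Gbad), "rs1")
  Gna <- G; Gna[1, 1] <- NA
  expect_error(ldFromGenotypes(Gna), "impute")
})

test_that("haplotype LD matches the di-locus frequency definition", {
  # linkage equilibrium and complete LD
  le <- HaplotypeTable(c("11", "10", "01", "00"), rep(0.25, 4))
  expect_equal(unclass(ldFromHaplotypes(le))[1, 2], 0)
  cl <- HaplotypeTable(c("11", "00"), c(0.5, 0.5))
  expect_equal(unclass(ldFromHaplotypes(cl))[1, 2], 1)

  # 3-SNP table with arbitrary frequencies vs the enumeration oracle
  haps <- c("000", "001", "010", "100", "011", "101", "110", "111")
  f <- c(0.22, 0.05, 0.13, 0.18, 0.07, 0.11, 0.14, 0.10)
  R <- ldFromHaplotypes(HaplotypeTable(haps, f))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(unclass(R)[i, j], hap_corr_oracle(haps, f, i, j),
                 tolerance = 1e-12)

  mono <- HaplotypeTable(c("10", "10"), c(0.6, 0.4))
  expect_error(ldFromHaplotypes(mono), "monomorphic")
})

test_that("haplotype LD agrees with genotype LD on a large simulated sample", {
  haps <- c("00", "01", "10", "11")
  f <- c(0.35, 0.15, 0.2, 0.3)
  r_theory <- unclass(ldFromHaplotypes(HaplotypeTable(haps, f)))[1, 2]
  set.seed(42)
  N <- 5e4
  G <- draw_genotypes(haps, f, N)
  r_emp <- unclass(ldFromGenotypes(G))[1, 2]
  se <- (1 - r_theory^2) / sqrt(N)  # large-sample SE of a correlation
  expect_lt(abs(r_emp - r_theory), 3 * se)
})

test_that("covariate adjustment is the Schur-complement partial correlation", {
  # covariates uncorrelated with the SNPs leave the SNP block unchanged
  full <- diag(3)
  full[1, 2] <- full[2, 1] <- 0.6
  out <- covariateAdjustedLD(LDMatrix(full), 1:2)
  expect_equal(unclass(out), full[1:2, 1:2], tolerance = 1e-12)

  # 2 SNPs + 1 covariate: closed-form partial correlation
  r12 <- 0.5; r13 <- 0.4; r23 <- -0.3
  m <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  part <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  out2 <- covariateAdjustedLD(LDMatrix(m), 1:2)
  expect_equal(unclass(out2)[1, 2], part, tolerance = 1e-12)

  # full index set: identity of the operation, and idempotent when repeated
  out3 <- covariateAdjustedLD(LDMatrix(m), 1:3)
  expect_equal(unclass(out3), m, tolerance = 1e-12)
  expect_equal(unclass(covariateAdjustedLD(out3, 1:3)), unclass(out3),
               tolerance = 1e-12)

  sing <- matrix(1, 3, 3)
  expect_error(covariateAdjustedLD(structure(sing, class = NULL), 1:2),
               "ridge|singular|positive")
})

test_that("equicorrelation eigenstructure follows the closed form", {
  expect_equal(eigen(equicorrLD(3, 0.7))$values, c(2.4, 0.3, 0.3),
               tolerance = 1e-12)
  expect_equal(unclass(equicorrLD(4, 0)), diag(4))
  for (L in c(2, 10, 100)) {
    rho <- 0.7
    ev <- eigen(unclass(equicorrLD(L, rho)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(ev, c(1 + rho * (L - 1), rep(1 - rho, L - 1)),
                 tolerance = 1e-10)
  }
  expect_error(equicorrLD(5, 1), "rho")
  expect_error(equicorrLD(5, -0.3), "rho")
})

test_that("perturbed equicorrelation spreads correlations and stays valid", {
  L <- 20
  base <- perturbedEquicorrLD(L, 0.7, 0, 0, seed = 1)
  expect_equal(unclass(base), unclass(equicorrLD(L, 0.7)), tolerance = 1e-12)

  B <- perturbedEquicorrLD(L, 0.7, 0, 5, seed = 7)
  expect_s4_class(B, "LDMatrix")
  off <- unclass(B)[row(B) != col(B)]
  expect_gt(max(off) - min(off), 0.3)   # wide heterogeneity, as intended
  expect_true(all(off > 0) && all(off < 1))
  expect_equal(unclass(B), t(unclass(B)), tolerance = 1e-12)
  expect_identical(unclass(perturbedEquicorrLD(L, 0.7, 0, 5, seed = 7)),
                   unclass(B))
})

test_that("random positive-definite correlations are valid and reproducible", {
  expect_equal(unclass(randomPDLD(1)), matrix(1, 1, 1))
  A <- randomPDLD(10, seed = 3)
  B <- randomPDLD(10, seed = 3)
  expect_identical(unclass(A), unclass(B))
  ev <- eigen(unclass(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(unclass(A)), rep(1, 10))
})

test_that("panel resampling concentrates on the population LD", {
  pop <- equicorrLD(5, 0)
  est <- samplePanelLD(pop, nPanel = 2e5, seed = 2)
  expect_lt(max(abs(unclass(est)[upper.tri(est)])), 0.01)

  # Frobenius error shrinks with panel size (in expectation)
  pop2 <- equicorrLD(6, 0.5)
  frob <- function(n, seeds) mean(vapply(seeds, function(s)
    norm(unclass(samplePanelLD(pop2, n, seed = s)) - unclass(pop2), "F"),
    numeric(1)))
  seeds <- 1:100
  expect_gt(frob(30, seeds), frob(300, seeds))

  expect_warning(samplePanelLD(pop2, nPanel = 4, seed = 1), "singular")
  expect_identical(unclass(samplePanelLD(pop2, 50, seed = 9)),
                   unclass(samplePanelLD(pop2, 50, seed = 9)))
})

test_that("LD matrix files round-trip through the text format", {
  R <- perturbedEquicorrLD(4, 0.5, 0, 1, seed = 5,
                           labels = paste0("rs", 1:4))
  f <- withr::local_tempfile()
  writeLDMatrix(R, f)
  back <- readLDMatrix(f)
  expect_equal(rownames(back), paste0("rs", 1:4))
  expect_equal(unclass(back), unclass(R), tolerance = 1e-9)

  # headerless numeric matrix
  f2 <- withr::local_tempfile()
  writeLines(c("1 0.5", "0.5 1"), f2)
  expect_equal(unclass(readLDMatrix(f2))[1, 2], 0.5)
})

test_that("every constructor output satisfies the correlation invariants", {
  mats <- list(equicorrLD(7, 0.4),
               perturbedEquicorrLD(7, 0.4, 0, 2, seed = 1),
               randomPDLD(7, seed = 2),
               samplePanelLD(equicorrLD(7, 0.4), 100, seed = 3),
               ldFromHaplotypes(HaplotypeTable(
                 c("00", "01", "10", "11"), c(0.4, 0.1, 0.2, 0.3))))
  for (m in mats) {
    v <- unclass(m)
    expect_lt(max(abs(v - t(v))), 1e-12)
    expect_equal(diag(v), rep(1, nrow(v)), ignore_attr = TRUE)
    expect_true(all(abs(v[row(v) != col(v)]) <= 1))
    expect_gt(min(eigen(v, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})
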