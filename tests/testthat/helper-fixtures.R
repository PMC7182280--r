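# Shared fixtures and small independent oracles, all built in code.

mc_se <- function(p, n) sqrt(p * (1 - p) / n)

# Independent per-pair Pearson correlation (textbook formula, no cor()).
pearson_pair <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

# Enumeration oracle for haplotype LD: moments of the allele indicators
# computed row-by-row over the table (a code path independent of
# ldFromHaplotypes' matrix algebra).
hap_corr_oracle <- function(haps, freqs, i, j) {
  ai <- as.integer(substr(haps, i, i))
  aj <- as.integer(substr(haps, j, j))
  Eij <- sum(freqs * ai * aj)
  Ei <- sum(freqs * ai)
  Ej <- sum(freqs * aj)
  (Eij - Ei * Ej) / sqrt(Ei * (1 - Ei) * Ej * (1 - Ej))
}

# Draw genotype dosages (0/1/2) for N individuals as sums of two independent
# haplotypes from the table.
draw_genotypes <- function(ht_haps, ht_freqs, N) {
  A <- do.call(rbind, lapply(strsplit(ht_haps, ""), as.integer))
  i1 <- sample.int(length(ht_freqs), N, replace = TRUE, prob = ht_freqs)
  i2 <- sample.int(length(ht_freqs), N, replace = TRUE, prob = ht_freqs)
  A[i1, , drop = FALSE] + A[i2, , drop = FALSE]
}

# One-factor-model correlation matrix: r_ij = a_i a_j (PD by construction).
factor_ld <- function(loadings, labels = NULL) {
  R <- tcrossprod(loadings)
  diag(R) <- 1
  LDMatrix(R, labels = labels)
}

# Synthetic multi-gene LD fixture: block-diagonal one-factor regions whose
# anchor blocks (|r| >= 0.25 with the anchor) have prescribed sizes.
# Returns the LDMatrix and the per-gene anchor labels.
make_scan_ld <- function(block_sizes = c(13, 36, 18, 30),
                         region_sizes = c(20, 50, 25, 40)) {
  stopifnot(all(region_sizes >= block_sizes))
  blocks <- list()
  anchors <- character(0)
  labels_all <- character(0)
  for (g in seq_along(block_sizes)) {
    n <- region_sizes[g]
    k <- block_sizes[g]
    # anchor loading 0.9; in-block 0.5 (r = 0.45 >= 0.25); outside 0.1
    a <- c(0.9, rep(0.5, k - 1), rep(0.1, n - k))
    labs <- sprintf("g%d_rs%03d", g, seq_len(n))
    blocks[[g]] <- tcrossprod(a)
    diag(blocks[[g]]) <- 1
    anchors <- c(anchors, labs[1])
    labels_all <- c(labels_all, labs)
  }
  L <- sum(region_sizes)
  R <- matrix(0, L, L)
  at <- 1
  for (b in blocks) {
    idx <- at:(at + nrow(b) - 1)
    R[idx, idx] <- b
    at <- at + nrow(b)
  }
  dimnames(R) <- list(labels_all, labels_all)
  list(ld = LDMatrix(R), anchors = anchors)
}

# Benchmark mean patterns: near-homogeneous and heterogeneous effects.
mu_setting1 <- function(L) seq(2.3, 2.4, length.out = L)
mu_setting3 <- function(L) seq(1.0, 2.3, length.out = L)
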