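#' Construct an LDMatrix from a raw matrix
#'
#' Validates and wraps a square numeric matrix as an
#' \code{\linkS4class{LDMatrix}}. The matrix must already be a correlation
#' matrix (symmetric, unit diagonal, positive definite); use
#' \code{\link{nearestPDCorrelation}} first if it is not.
#'
#' @param values square numeric matrix of correlations.
#' @param labels optional character vector of SNP identifiers.
#' @return An \code{LDMatrix}.
#' @examples
#' LDMatrix(diag(3), labels = c("rs1", "rs2", "rs3"))
#' @export
LDMatrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- rownames(values)
  .as_corr(values, labels)
}

#' Construct a StatVector of association Z-scores
#'
#' @param z numeric vector of per-SNP Z-scores.
#' @param ids optional SNP identifiers.
#' @param weights optional nonnegative per-SNP weights; weighted tests absorb
#'   them as Y_i^2 = w_i Z_i^2.
#' @return A \code{\linkS4class{StatVector}}.
#' @examples
#' StatVector(c(1.2, -0.4), ids = c("rs1", "rs2"))
#' @export
StatVector <- function(z, ids = character(), weights = numeric()) {
  if (is.null(ids)) ids <- character()
  if (is.null(weights)) weights <- numeric()
  new("StatVector", z = as.numeric(z), ids = as.character(ids),
      weights = as.numeric(weights))
}

#' Construct a HaplotypeTable
#'
#' @param haplotypes character vector of 0/1 strings (1 = minor allele).
#' @param frequency numeric haplotype frequencies summing to 1.
#' @return A \code{\linkS4class{HaplotypeTable}}.
#' @examples
#' HaplotypeTable(c("00", "01", "10", "11"), rep(0.25, 4))
#' @export
HaplotypeTable <- function(haplotypes, frequency) {
  new("HaplotypeTable", haplotypes = as.character(haplotypes),
      frequency = as.numeric(frequency))
}

#' LD matrix from a genotype dosage matrix
#'
#' Pearson sample correlation of 0/1/2 allele dosages: the standard LD
#' estimate when individual-level genotypes are available. Missing entries
#' are rejected -- with missingness the sample correlation no longer reflects
#' the correlation among the statistics, so imputation must happen upstream.
#'
#' @param G N x L numeric matrix of dosages in {0, 1, 2}; columns are SNPs.
#'   Column names, when present, become SNP labels.
#' @return An \code{\linkS4class{LDMatrix}}.
#' @examples
#' G <- matrix(c(0, 1, 2, 2, 1, 0, 0, 1, 1, 2, 2, 1), ncol = 2)
#' ldFromGenotypes(G)
#' @export
ldFromGenotypes <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) < 2) stop("need at least 2 individuals")
  if (anyNA(G))
    stop("missing genotypes detected; impute before estimating LD")
  v <- apply(G, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(G)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("constant genotype column (no variation): ",
         paste(bad, collapse = ", "))
  }
  .as_corr(stats::cor(G), colnames(G))
}

#' LD matrix from haplotype frequencies
#'
#' Builds pairwise LD correlations from di-locus haplotype frequencies:
#' D_ij = P_ij - p_i p_j and r_ij = D_ij / sqrt(p_i(1-p_i) p_j(1-p_j)),
#' where P_ij is the total frequency of haplotypes carrying both minor
#' alleles and p_i the total frequency carrying minor allele i.
#'
#' @param ht a \code{\linkS4class{HaplotypeTable}}.
#' @param labels optional SNP identifiers.
#' @return An \code{\linkS4class{LDMatrix}}.
#' @examples
#' ht <- HaplotypeTable(c("11", "00"), c(0.5, 0.5))
#' ldFromHaplotypes(ht)   # complete LD: r = 1
#' @export
ldFromHaplotypes <- function(ht, labels = NULL) {
  A <- do.call(rbind, lapply(strsplit(ht@haplotypes, ""), as.integer))
  f <- ht@frequency
  p <- drop(crossprod(A, f))               # minor-allele frequencies
  if (any(p <= 0 | p >= 1)) {
    bad <- which(p <= 0 | p >= 1)
    stop("monomorphic SNP (allele frequency 0 or 1) at position ",
         paste(bad, collapse = ", "))
  }
  P <- crossprod(A * sqrt(f))              # P[i,j] = sum_h f_h a_hi a_hj
  D <- P - tcrossprod(p)
  r <- D / tcrossprod(sqrt(p * (1 - p)))
  .as_corr(r, labels)
}

#' Covariate-adjusted correlation among SNP statistics
#'
#' When single-SNP regressions include covariates, the correlation among the
#' association statistics is the Schur complement of the SNP block given the
#' covariates: invert the full predictor correlation matrix, select the SNP
#' submatrix, invert it back, and standardize to correlation.
#'
#' @param full \code{LDMatrix} (or matrix) over SNPs and covariates jointly.
#' @param snpIndices indices (or labels) of the SNP rows/columns.
#' @return \code{LDMatrix} over the selected SNPs, adjusted for the rest.
#' @examples
#' full <- equicorrLD(3, 0.3)
#' covariateAdjustedLD(full, 1:2)
#' @export
covariateAdjustedLD <- function(full, snpIndices) {
  m <- unclass(as.matrix(full))
  if (is.character(snpIndices)) snpIndices <- match(snpIndices, rownames(m))
  snpIndices <- as.integer(snpIndices)
  if (anyNA(snpIndices) || anyDuplicated(snpIndices) ||
      any(snpIndices < 1 | snpIndices > nrow(m)))
    stop("snpIndices must be distinct valid indices of the full matrix")
  if (length(snpIndices) == nrow(m)) {
    return(.as_corr(m[snpIndices, snpIndices, drop = FALSE],
                    rownames(m)[snpIndices]))
  }
  pri <- tryCatch(solve(m), error = function(e)
    stop("full predictor matrix is singular; consider a small ridge repair ",
         "(add epsilon to the diagonal) before adjusting"))
  sub <- pri[snpIndices, snpIndices, drop = FALSE]
  adj <- solve(sub)
  .cov2cor(adj) |> .as_corr(rownames(m)[snpIndices])
}

#' Equicorrelation matrix
#'
#' R_rho = (1 - rho) I + rho 11', the benchmark LD structure of the power
#' theory: eigenvalues are 1 + rho(L-1) (once) and 1 - rho (L-1 times).
#'
#' @param L dimension.
#' @param rho common pairwise correlation, in (-1/(L-1), 1).
#' @param labels optional SNP identifiers.
#' @return An \code{\linkS4class{LDMatrix}}.
#' @examples
#' eigen(equicorrLD(3, 0.7))$values  # 2.4, 0.3, 0.3
#' @export
equicorrLD <- function(L, rho, labels = NULL) {
  L <- as.integer(L)
  if (L >= 2 && (rho <= -1 / (L - 1) || rho >= 1))
    stop("rho must lie in (-1/(L-1), 1) for positive definiteness")
  m <- matrix(rho, L, L)
  diag(m) <- 1
  .as_corr(m, labels)
}

#' Rank-one perturbed equicorrelation matrix
#'
#' B = R_rho + U U' with U i.i.d. uniform(uLow, uHigh), standardized back to
#' correlation. Controlled heterogeneity around a common correlation rho:
#' small |U| jiggles the pairwise values, large ranges (e.g. uniform(0, 5))
#' spread them widely (roughly 0.14 to 0.98 around rho = 0.7).
#'
#' @param L dimension.
#' @param rho base common correlation.
#' @param uLow,uHigh bounds of the uniform perturbation vector U.
#' @param seed optional RNG seed (caller's stream is untouched).
#' @param labels optional SNP identifiers.
#' @return An \code{\linkS4class{LDMatrix}}.
#' @examples
#' perturbedEquicorrLD(5, 0.7, 0, 5, seed = 1)
#' @export
perturbedEquicorrLD <- function(L, rho, uLow = 0, uHigh = 5, seed = NULL,
                                labels = NULL) {
  if (uLow > uHigh) stop("uLow must not exceed uHigh")
  L <- as.integer(L)
  if (L >= 2 && (rho <= -1 / (L - 1) || rho >= 1))
    stop("rho must lie in (-1/(L-1), 1)")
  U <- .with_seed(seed, stats::runif(L, uLow, uHigh))
  B <- matrix(rho, L, L)
  diag(B) <- 1
  B <- B + tcrossprod(U)
  .as_corr(.cov2cor(B), labels)
}

#' Nearest positive-definite correlation repair
#'
#' Eigenvalue clipping: eigenvalues below 1e-10 of the largest are raised to
#' that floor, the matrix reconstructed and standardized back to unit
#' diagonal. Deterministic, and a no-op on matrices that are already
#' comfortably positive definite.
#'
#' @param m symmetric numeric matrix.
#' @param floorRel relative eigenvalue floor (fraction of the largest).
#' @return A positive-definite correlation matrix (plain matrix).
#' @examples
#' m <- matrix(c(1, 0.9, 0.9, 0.9, 1, 0.9, 0.9, 0.9, 1), 3)
#' nearestPDCorrelation(m)
#' @export
nearestPDCorrelation <- function(m, floorRel = 1e-8) {
  m <- (m + t(m)) / 2
  ee <- eigen(m, symmetric = TRUE)
  floorv <- floorRel * max(ee$values)
  if (min(ee$values) >= floorv) {
    out <- m
  } else {
    lam <- pmax(ee$values, floorv)
    out <- ee$vectors %*% (lam * t(ee$vectors))
  }
  out <- .cov2cor(out)
  dimnames(out) <- dimnames(m)
  out
}

#' Random positive-definite correlation matrix
#'
#' Draws a symmetric matrix of uniform(-1, 1) off-diagonals with unit
#' diagonal and repairs it to positive definiteness by eigenvalue clipping.
#' Used for type-I error checks where the tests must hold under arbitrary
#' valid correlation structure.
#'
#' @param L dimension.
#' @param seed optional RNG seed.
#' @param labels optional SNP identifiers.
#' @return An \code{\linkS4class{LDMatrix}}.
#' @examples
#' randomPDLD(4, seed = 7)
#' @export
randomPDLD <- function(L, seed = NULL, labels = NULL) {
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  .with_seed(seed, {
    m <- matrix(0, L, L)
    m[upper.tri(m)] <- stats::runif(L * (L - 1) / 2, -1, 1)
    m <- m + t(m)
    diag(m) <- 1
    .as_corr(nearestPDCorrelation(m), labels)
  })
}

# Internal fast path: raw matrix, no S4 validation (hot simulation loops).
.random_pd_corr <- function(L) {
  m <- matrix(0, L, L)
  m[upper.tri(m)] <- stats::runif(L * (L - 1) / 2, -1, 1)
  m <- m + t(m)
  diag(m) <- 1
  nearestPDCorrelation(m)
}

#' Reference-panel style resampled LD estimate
#'
#' Sample correlation matrix of \code{nPanel} multivariate normal draws with
#' the given population correlation -- the Gaussian-genotype surrogate for an
#' external reference panel of that size (equivalently a Wishart draw). When
#' \code{nPanel <= L} the estimate is singular; it is repaired to positive
#' definiteness and flagged with a warning, which mirrors what a practitioner
#' faces with an undersized panel.
#'
#' @param population \code{LDMatrix} (or matrix): the population LD.
#' @param nPanel panel sample size.
#' @param seed optional RNG seed.
#' @return An \code{\linkS4class{LDMatrix}} with attribute
#'   \code{"rankDeficient"} set to TRUE when the raw estimate was singular.
#' @examples
#' samplePanelLD(equicorrLD(4, 0.5), nPanel = 1000, seed = 1)
#' @export
samplePanelLD <- function(population, nPanel, seed = NULL) {
  R <- unclass(as.matrix(population))
  L <- nrow(R)
  est <- .with_seed(seed, .panel_corr(R, nPanel))
  deficient <- nPanel <= L
  if (deficient) {
    warning("panel size (", nPanel, ") <= number of SNPs (", L,
            "): singular LD estimate, repaired to positive definite")
    est <- nearestPDCorrelation(est)
  }
  out <- .as_corr(est, rownames(R))
  attr(out, "rankDeficient") <- deficient
  out
}

# Internal: one sample correlation estimate from nPanel Gaussian draws,
# computed as a Wishart draw when nPanel > L (fast), else from explicit draws.
.panel_corr <- function(R, nPanel) {
  L <- nrow(R)
  if (nPanel > L) {
    W <- stats::rWishart(1, df = nPanel - 1, Sigma = R)[, , 1]
    .cov2cor(W)
  } else {
    X <- matrix(stats::rnorm(nPanel * L), nPanel, L) %*% chol(R)
    .cov2cor(stats::cov(X))
  }
}
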