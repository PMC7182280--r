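#' @import methods
NULL

.SYM_TOL <- 1e-12
.PD_FLOOR_REL <- 1e-10  # lambda_min must exceed this fraction of lambda_max

#' LDMatrix: a validated correlation matrix
#'
#' An \code{LDMatrix} holds an L x L correlation matrix -- either linkage
#' disequilibrium among SNPs (correlation of 0/1/2 allele dosages), the
#' correlation among association statistics, or any other unit-diagonal
#' positive-definite correlation structure used by the tests. It extends
#' \code{matrix}, so ordinary matrix algebra applies; SNP identifiers, when
#' present, live in \code{dimnames}.
#'
#' Validity requires symmetry (within 1e-12), unit diagonal, off-diagonal
#' entries in [-1, 1], and positive semi-definiteness (no eigenvalue below
#' -1e-8 of the largest; perfect proxies make LD estimates singular, which
#' is legitimate). Operations that must invert the matrix -- the
#' decorrelating transform, DOT, analytic power -- additionally require
#' strict positive definiteness and direct the caller to
#' \code{\link{nearestPDCorrelation}} when it fails.
#'
#' @slot .Data numeric matrix of correlations.
#' @seealso \code{\link{LDMatrix}} (constructor), \code{\link{ldFromGenotypes}},
#'   \code{\link{equicorrLD}}, \code{\link{randomPDLD}}
#' @exportClass LDMatrix
setClass("LDMatrix", contains = "matrix")

.validate_corr <- function(object, require_pd = TRUE) {
  v <- unclass(object)
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("must be a square numeric matrix")
  if (anyNA(v) || any(!is.finite(v)))
    return("entries must be finite")
  if (max(abs(v - t(v))) > .SYM_TOL)
    return(sprintf("not symmetric within %g", .SYM_TOL))
  if (max(abs(diag(v) - 1)) > 1e-8)
    return("diagonal must be 1")
  off <- v[row(v) != col(v)]
  if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12))
    return("off-diagonal correlations must lie in [-1, 1]")
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (require_pd) {
    if (min(ev) <= .PD_FLOOR_REL * max(ev))
      return("matrix is not positive definite; consider nearestPDCorrelation()")
  } else if (min(ev) < -1e-8 * max(ev)) {
    return("matrix is not positive semi-definite")
  }
  TRUE
}

setValidity("LDMatrix", function(object) .validate_corr(object, require_pd = FALSE))

#' HaplotypeTable: haplotype frequencies over L biallelic SNPs
#'
#' Each haplotype is a string over {0,1} of common length L, with 1 denoting
#' the minor allele at that position; \code{frequency} holds the population
#' frequency of each haplotype. Frequencies must be nonnegative and sum to 1
#' within 1e-9. Pairwise LD follows from di-locus haplotype frequencies:
#' D_ij = P_ij - p_i p_j, where P_ij sums the frequencies of haplotypes
#' carrying both minor alleles and p_i those carrying minor allele i.
#'
#' @slot haplotypes character vector of 0/1 strings, one per haplotype.
#' @slot frequency numeric vector of haplotype frequencies.
#' @seealso \code{\link{ldFromHaplotypes}}, \code{\link{readHaplotypeTable}}
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
         representation(haplotypes = "character", frequency = "numeric"))

setValidity("HaplotypeTable", function(object) {
  h <- object@haplotypes; f <- object@frequency
  if (length(h) != length(f)) return("haplotypes and frequency differ in length")
  if (!length(h)) return("empty table")
  if (length(unique(nchar(h))) != 1L) return("haplotype strings differ in length")
  if (any(!grepl("^[01]+$", h))) return("haplotypes must be strings over {0,1}")
  if (any(f < 0)) return("frequencies must be nonnegative")
  if (abs(sum(f) - 1) > 1e-9) return("frequencies must sum to 1 within 1e-9")
  TRUE
})

#' StatVector: per-SNP association Z-scores
#'
#' Container for a length-L vector of per-SNP association Z-scores, with
#' optional SNP identifiers and optional nonnegative per-SNP weights.
#' Weighted analyses absorb the weights into the statistics
#' (Y_i^2 = w_i Z_i^2), so every downstream test sees a plain Z vector.
#'
#' @slot z numeric Z-scores (finite).
#' @slot ids character SNP identifiers (may be empty).
#' @slot weights numeric nonnegative weights (may be empty; not all zero).
#' @seealso \code{\link{StatVector}}, \code{\link{pvaluesToZ}},
#'   \code{\link{dotTest}}
#' @exportClass StatVector
setClass("StatVector",
         representation(z = "numeric", ids = "character", weights = "numeric"))

setValidity("StatVector", function(object) {
  z <- object@z
  if (!length(z)) return("z must be non-empty")
  if (any(!is.finite(z))) return("z must be finite")
  if (length(object@ids) && length(object@ids) != length(z))
    return("ids must match z in length")
  w <- object@weights
  if (length(w)) {
    if (length(w) != length(z)) return("weights must match z in length")
    if (any(!is.finite(w)) || any(w < 0)) return("weights must be finite and >= 0")
    if (all(w == 0)) return("weights must not be all zero")
  }
  TRUE
})

#' DecorTransform: the order-invariant decorrelating transform H
#'
#' Holds the symmetric inverse square root H = E diag(1/sqrt(lambda)) E' of a
#' correlation matrix R, together with the eigenvalues (descending) and
#' orthonormal eigenvectors it was built from. H satisfies H R H = I, and --
#' unlike the inverse Cholesky factor or E diag(1/sqrt(lambda)) alone -- is
#' invariant to the ordering of an equicorrelated input vector: permuting the
#' entries of Z permutes (at most) the decorrelated values without changing
#' them.
#'
#' @slot H symmetric L x L transform matrix.
#' @slot lambda eigenvalues of R, descending.
#' @slot vectors orthonormal eigenvector matrix of R (columns).
#' @seealso \code{\link{decorrelationTransform}}
#' @exportClass DecorTransform
setClass("DecorTransform",
         representation(H = "matrix", lambda = "numeric", vectors = "matrix"))

setValidity("DecorTransform", function(object) {
  H <- object@H
  if (nrow(H) != ncol(H)) return("H must be square")
  if (max(abs(H - t(H))) > 1e-10) return("H must be symmetric within 1e-10")
  if (any(object@lambda <= 0)) return("eigenvalues must be positive")
  if (is.unsorted(rev(object@lambda))) return("eigenvalues must be descending")
  E <- object@vectors
  if (max(abs(crossprod(E) - diag(ncol(E)))) > 1e-10)
    return("eigenvector columns must be orthonormal within 1e-10")
  TRUE
})

#' ChiSqMixture: a weighted noncentral chi-square mixture
#'
#' Distribution of a quadratic form Y'Y in correlated Gaussians: a weighted
#' sum of independent one-df noncentral chi-squares with weights
#' \code{lambda} (eigenvalues of the statistic correlation matrix R) and
#' noncentralities \code{gamma}. The total noncentrality
#' \code{gammaC = sum(gamma) = mu' R^-1 mu} is conserved under decorrelation
#' and equals the noncentrality of the DOT chi-square. For equicorrelated R
#' the Helmert closed forms \code{helmertDeltas} (and their tail sum
#' \code{deltaS}) are populated as well.
#'
#' @slot lambda positive mixture weights.
#' @slot gamma nonnegative noncentralities, one per weight.
#' @slot df integer-valued degrees of freedom per component (usually 1).
#' @slot gammaC total noncentrality mu' R^-1 mu.
#' @slot helmertDeltas closed-form per-component noncentralities (equicorrelation
#'   only; otherwise length 0).
#' @slot deltaS sum of the Helmert noncentralities beyond the first
#'   (equicorrelation only; otherwise NA).
#' @seealso \code{\link{tqAltMixture}}, \code{\link{equicorrNoncentralities}},
#'   \code{\link{quadformTail}}
#' @exportClass ChiSqMixture
setClass("ChiSqMixture",
         representation(lambda = "numeric", gamma = "numeric", df = "numeric",
                        gammaC = "numeric", helmertDeltas = "numeric",
                        deltaS = "numeric"))

setValidity("ChiSqMixture", function(object) {
  if (length(object@lambda) != length(object@gamma)) return("lambda/gamma length mismatch")
  if (length(object@df) != length(object@lambda)) return("df length mismatch")
  if (any(object@lambda <= 0)) return("lambda must be positive")
  if (any(object@gamma < -1e-12)) return("gamma must be nonnegative")
  if (abs(sum(object@gamma) - object@gammaC) > 1e-8 * max(1, object@gammaC))
    return("sum(gamma) must equal gammaC within 1e-8")
  TRUE
})

#' EffectModel: regression effects behind a set of association statistics
#'
#' Describes the trait model y = beta0 + sum_j beta_j SNP_j + epsilon used to
#' induce noncentralities: regression coefficients \code{beta}, predictor
#' correlation matrix \code{sigma} (LD), sample size \code{n}, and trait type.
#' For a binary trait analysed on the liability scale, \code{threshold} is
#' the liability cut point and noncentralities are attenuated by
#' \code{\link{binaryAttenuation}}.
#'
#' @slot beta numeric regression coefficients (length L).
#' @slot sigma \code{LDMatrix} of predictor correlations.
#' @slot n sample size (individuals).
#' @slot trait "continuous" or "binary".
#' @slot threshold liability threshold (binary trait only; NA otherwise).
#' @seealso \code{\link{noncentralityFromEffects}},
#'   \code{\link{altStatisticCorrelation}}
#' @exportClass EffectModel
setClass("EffectModel",
         representation(beta = "numeric", sigma = "LDMatrix", n = "numeric",
                        trait = "character", threshold = "numeric"))

setValidity("EffectModel", function(object) {
  if (length(object@beta) != nrow(object@sigma))
    return("beta length must match sigma dimension")
  if (any(!is.finite(object@beta))) return("beta must be finite")
  if (length(object@n) != 1L || object@n < 1) return("n must be a scalar >= 1")
  if (!object@trait %in% c("continuous", "binary"))
    return("trait must be 'continuous' or 'binary'")
  if (object@trait == "binary" && !is.finite(object@threshold))
    return("binary trait requires a finite liability threshold")
  TRUE
})

#' AssocTest: result of a gene-level association test
#'
#' @slot method test name ("dot", "tq", "acat", "minp", "rtp").
#' @slot statistic observed test statistic.
#' @slot df degrees of freedom when the null is a (central) chi-square;
#'   NA when the null is a mixture or simulated.
#' @slot mixture the null \code{ChiSqMixture} (TQ) or NULL.
#' @slot pValue P-value in [0, 1].
#' @slot decorrelated decorrelated statistics X = H Z (DOT/RTP only).
#' @seealso \code{\link{dotTest}}, \code{\link{tqTest}}, \code{\link{acatTest}}
#' @exportClass AssocTest
setClass("AssocTest",
         representation(method = "character", statistic = "numeric",
                        df = "numeric", mixture = "ANY", pValue = "numeric",
                        decorrelated = "numeric"))

setValidity("AssocTest", function(object) {
  if (!is.finite(object@statistic)) return("statistic must be finite")
  if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0, 1]")
  TRUE
})

#' PowerEstimate: analytic or empirical power of a gene-level test
#'
#' @slot method test name.
#' @slot alpha test size.
#' @slot power power (or type-I error when the alternative is null) in [0,1].
#' @slot mode "exact", "approx", "asymptotic", or "empirical".
#' @slot mcSE Monte-Carlo standard error; NA unless mode == "empirical".
#' @seealso \code{\link{dotPower}}, \code{\link{tqPower}},
#'   \code{\link{estimatePower}}
#' @exportClass PowerEstimate
setClass("PowerEstimate",
         representation(method = "character", alpha = "numeric",
                        power = "numeric", mode = "character", mcSE = "numeric"))

setValidity("PowerEstimate", function(object) {
  if (object@power < 0 || object@power > 1) return("power must be in [0, 1]")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0, 1)")
  if (!object@mode %in% c("exact", "approx", "asymptotic", "empirical"))
    return("unknown mode")
  if (object@mode == "empirical" && !is.finite(object@mcSE))
    return("empirical estimates must carry mcSE")
  if (object@mode != "empirical" && is.finite(object@mcSE))
    return("mcSE is only meaningful for empirical estimates")
  TRUE
})

#' GeneBlock: an anchor-SNP LD block
#'
#' SNPs whose LD correlation with a designated anchor SNP meets a threshold
#' (|r| >= threshold), in the order they appear in the LD matrix, together
#' with the restricted LD submatrix.
#'
#' @slot anchor anchor SNP identifier.
#' @slot members member SNP identifiers (anchor included).
#' @slot threshold |r| threshold used.
#' @slot ld restricted \code{LDMatrix} over the members.
#' @seealso \code{\link{anchorBlock}}, \code{\link{geneTest}}
#' @exportClass GeneBlock
setClass("GeneBlock",
         representation(anchor = "character", members = "character",
                        threshold = "numeric", ld = "LDMatrix"))

setValidity("GeneBlock", function(object) {
  if (!object@anchor %in% object@members) return("anchor must be a member")
  if (length(object@members) != nrow(object@ld))
    return("ld dimension must match members")
  TRUE
})

#' GeneReport: all per-gene results of a scan
#'
#' @slot gene gene label.
#' @slot block the \code{GeneBlock} analysed.
#' @slot results named list of \code{AssocTest}, one per method.
#' @slot contributors data.frame of top-component contributor SNPs
#'   (columns: component, rank, x, snp, term, sameSign, selected).
#' @seealso \code{\link{geneTest}}, \code{\link{topContributors}},
#'   \code{\link{scanGenes}}
#' @exportClass GeneReport
setClass("GeneReport",
         representation(gene = "character", block = "GeneBlock",
                        results = "list", contributors = "data.frame"))

setValidity("GeneReport", function(object) {
  ok <- vapply(object@results, function(r) is(r, "AssocTest"), TRUE)
  if (length(ok) && !all(ok)) return("results must be AssocTest objects")
  TRUE
})
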