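#' DOT: decorrelation by orthogonal transformation
#'
#' Decorrelates the Z-scores with the symmetric inverse square root H of
#' their correlation matrix, X = H Z, and sums the squares:
#' DOT = sum X_i^2 = Z' R^-1 Z. Under the null, X has independent standard
#' normal entries, so DOT is a central chi-square with L degrees of freedom
#' -- no mixture evaluation needed. The decorrelated vector is stored for
#' contributor analysis.
#'
#' @param z \code{\linkS4class{StatVector}} or numeric Z-scores.
#' @param R \code{\linkS4class{LDMatrix}} or correlation matrix (positive
#'   definite).
#' @return An \code{\linkS4class{AssocTest}}.
#' @examples
#' dotTest(c(2, -1, 0.5), equicorrLD(3, 0.4))
#' @export
dotTest <- function(z, R) {
  y <- .z_vector(z)
  Rm <- unclass(as.matrix(R))
  .check_dims(y, Rm)
  tr <- decorrelationTransform(Rm)
  x <- drop(tr@H %*% y)
  names(x) <- names(y)
  stat <- sum(x^2)
  new("AssocTest", method = "dot", statistic = stat, df = length(y),
      mixture = NULL,
      pValue = stats::pchisq(stat, df = length(y), lower.tail = FALSE),
      decorrelated = x)
}

#' TQ: the quadratic-form (VEGAS-style) sum of squared Z-scores
#'
#' TQ = sum Z_i^2; its null distribution is the weighted sum of independent
#' one-df chi-squares with weights equal to the eigenvalues of R. The
#' P-value is computed either by Imhof-type inversion of the characteristic
#' function ("imhof", the production path) or empirically by simulating
#' null multivariate normal vectors ("montecarlo", the VEGAS approach); the
#' two agree within Monte-Carlo error.
#'
#' @param z \code{\linkS4class{StatVector}} or numeric Z-scores.
#' @param R correlation matrix (positive semi-definite).
#' @param method P-value path: "imhof" or "montecarlo".
#' @param nNull null replicates for the Monte-Carlo path.
#' @param seed optional RNG seed for the Monte-Carlo path.
#' @return An \code{\linkS4class{AssocTest}} carrying the null
#'   \code{\linkS4class{ChiSqMixture}}.
#' @examples
#' tqTest(c(2, -1, 0.5), equicorrLD(3, 0.4))
#' @export
tqTest <- function(z, R, method = c("imhof", "montecarlo"), nNull = 1e6,
                   seed = NULL) {
  method <- match.arg(method)
  y <- .z_vector(z)
  Rm <- unclass(as.matrix(R))
  .check_dims(y, Rm)
  stat <- sum(y^2)
  lam <- eigen(Rm, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12 * max(lam)]   # PSD allowed: drop null directions
  mix <- new("ChiSqMixture", lambda = lam, gamma = rep(0, length(lam)),
             df = rep(1, length(lam)), gammaC = 0,
             helmertDeltas = numeric(), deltaS = NA_real_)
  p <- if (method == "imhof") {
    quadformTail(lam, 0, stat)
  } else {
    .with_seed(seed, {
      null_tq <- colSums(matrix(stats::rnorm(nNull * length(lam)),
                                length(lam)) ^ 2 * lam)
      (sum(null_tq > stat) + 1) / (nNull + 1)
    })
  }
  new("AssocTest", method = "tq", statistic = stat, df = NA_real_,
      mixture = mix, pValue = p, decorrelated = numeric())
}

#' ACAT: Cauchy combination of P-values
#'
#' P-values are mapped to standard Cauchy variates, tan((0.5 - p) pi),
#' averaged with the given weights, and the average referred back to the
#' Cauchy upper tail. The heavy-tailed transform makes the combination
#' insensitive to correlation among the P-values, especially at small alpha.
#' Degenerate P-values of exactly 0 or 1 are clamped to [1e-300, 1 - 1e-16]
#' with a warning.
#'
#' @param p P-values in (0, 1).
#' @param weights optional nonnegative weights (default equal).
#' @return An \code{\linkS4class{AssocTest}}.
#' @examples
#' pValue(acatTest(c(0.05, 0.05, 0.05)))  # 0.05
#' @export
acatTest <- function(p, weights = NULL) {
  p <- as.numeric(p)
  if (any(p <= 0 | p >= 1)) {
    warning("P-values of exactly 0 or 1 clamped to [1e-300, 1 - 1e-16]")
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  }
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  if (length(weights) != length(p) || any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative, not all zero, and match p in length")
  weights <- weights / sum(weights)
  stat <- sum(weights * tan((0.5 - p) * pi))
  new("AssocTest", method = "acat", statistic = stat, df = NA_real_,
      mixture = NULL,
      pValue = stats::pcauchy(stat, lower.tail = FALSE),
      decorrelated = numeric())
}

#' Bonferroni min-P combination
#'
#' min(1, L * min(p)): the Bonferroni-style adjustment of the smallest
#' P-value, the conservative baseline of the gene-level comparisons.
#'
#' @param p P-values in (0, 1].
#' @return An \code{\linkS4class{AssocTest}}.
#' @examples
#' pValue(minpTest(c(0.01, 0.5)))  # 0.02
#' @export
minpTest <- function(p) {
  p <- as.numeric(p)
  if (any(p <= 0 | p > 1)) stop("P-values must lie in (0, 1]")
  new("AssocTest", method = "minp", statistic = min(p), df = NA_real_,
      mixture = NULL, pValue = min(1, length(p) * min(p)),
      decorrelated = numeric())
}

#' Rank truncated product on decorrelated statistics
#'
#' Decorrelation yields independent one-df chi-squares X_i^2, whose P-values
#' can be fed to any combiner for independent tests. The rank truncated
#' product takes the k smallest of them: T = sum_{i=1..k} -ln P_(i). Because
#' -ln P_(i) for the ordered subset is no longer chi-square, the null is
#' simulated: the P-value is the add-one-corrected proportion of null
#' statistics (from independent uniforms) exceeding the observed one.
#'
#' @param z \code{\linkS4class{StatVector}} or numeric Z-scores.
#' @param R correlation matrix (positive definite).
#' @param k number of smallest P-values combined (1 <= k <= L).
#' @param nNull null replicates for the simulated reference distribution.
#' @param seed optional RNG seed.
#' @return An \code{\linkS4class{AssocTest}} (decorrelated vector stored).
#' @examples
#' rtpTest(c(2.5, 1, 0.2, -0.3), equicorrLD(4, 0.3), k = 2, nNull = 1e4,
#'         seed = 1)
#' @export
rtpTest <- function(z, R, k, nNull = 1e4, seed = NULL) {
  y <- .z_vector(z)
  Rm <- unclass(as.matrix(R))
  .check_dims(y, Rm)
  L <- length(y)
  if (k < 1 || k > L) stop("k must satisfy 1 <= k <= L")
  if (nNull < 1e4) stop("nNull must be at least 10^4")
  x <- drop(.inv_sqrt(Rm) %*% y)
  names(x) <- names(y)
  px <- stats::pchisq(x^2, df = 1, lower.tail = FALSE)
  stat <- sum(-log(sort(px)[seq_len(k)]))
  r <- .with_seed(seed, {
    nullp <- matrix(stats::runif(nNull * L), nNull, L)
    nullstat <- apply(nullp, 1, function(u) sum(-log(sort(u)[seq_len(k)])))
    sum(nullstat >= stat)
  })
  new("AssocTest", method = "rtp", statistic = stat, df = NA_real_,
      mixture = NULL, pValue = (r + 1) / (nNull + 1), decorrelated = x)
}
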