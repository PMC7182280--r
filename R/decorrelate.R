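#' The order-invariant decorrelating transform
#'
#' Builds H = E diag(1/sqrt(lambda)) E', the symmetric inverse square root of
#' the correlation matrix R, where E holds the orthonormal eigenvectors of R
#' and lambda its eigenvalues. H satisfies H R H = I, so X = H Z has
#' independent standard normal entries under the null. Among valid
#' decorrelating transforms, the symmetric root is the one with the
#' "invariance to order" property: for an equicorrelated R, permuting the
#' entries of Z permutes the entries of X without changing their values --
#' the inverse Cholesky factor and E diag(1/sqrt(lambda)) alone both fail
#' this. Eigenvalues are sorted descending and each eigenvector's sign is
#' fixed by making its largest-magnitude entry positive, so the
#' decomposition (though not H itself, which is basis-independent) is
#' reproducible.
#'
#' @param R \code{\linkS4class{LDMatrix}} or correlation matrix, positive
#'   definite.
#' @return A \code{\linkS4class{DecorTransform}}.
#' @examples
#' tr <- decorrelationTransform(equicorrLD(4, 0.5))
#' max(abs(transformMatrix(tr) %*% equicorrLD(4, 0.5) %*%
#'         transformMatrix(tr) - diag(4)))  # ~1e-16
#' @export
decorrelationTransform <- function(R) {
  Rm <- unclass(as.matrix(R))
  ee <- eigen(Rm, symmetric = TRUE)   # eigenvalues already descending
  if (min(ee$values) <= .PD_FLOOR_REL * max(ee$values))
    stop("correlation matrix is numerically singular ",
         "(smallest eigenvalue <= 1e-10 of largest); ",
         "repair with nearestPDCorrelation() first")
  E <- ee$vectors
  # deterministic eigenvector signs: largest-magnitude entry positive
  sgn <- apply(E, 2, function(v) sign(v[which.max(abs(v))]))
  E <- sweep(E, 2, sgn, `*`)
  H <- E %*% (1 / sqrt(ee$values) * t(E))
  H <- (H + t(H)) / 2
  dimnames(H) <- dimnames(Rm)
  new("DecorTransform", H = H, lambda = ee$values, vectors = E)
}

# Internal: H alone, raw matrix in, raw matrix out.
.inv_sqrt <- function(Rm) {
  ee <- eigen(Rm, symmetric = TRUE)
  H <- ee$vectors %*% (1 / sqrt(ee$values) * t(ee$vectors))
  (H + t(H)) / 2
}

#' Convert P-values to normal scores
#'
#' P_i -> Z_i by the chi-square(1) upper quantile: |Z_i| =
#' sqrt(qchisq(p_i, 1, lower = FALSE)), i.e. the two-sided standard normal
#' score. If effect-direction signs are supplied (e.g. from a TDT or from
#' regression coefficients), they are attached: Z_i = sign_i |Z_i|.
#'
#' @param p P-values in (0, 1].
#' @param signs optional vector of +/-1 effect directions.
#' @param ids optional SNP identifiers.
#' @return A \code{\linkS4class{StatVector}}.
#' @examples
#' zScores(pvaluesToZ(0.05))  # 1.959964
#' @export
pvaluesToZ <- function(p, signs = NULL, ids = character()) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("P-values must lie in (0, 1] (p = 0 would map to an infinite score)")
  z <- sqrt(stats::qchisq(p, df = 1, lower.tail = FALSE))
  if (!is.null(signs)) {
    if (length(signs) != length(p)) stop("signs must match p in length")
    if (any(!signs %in% c(-1, 1))) stop("signs must be +1 or -1")
    z <- signs * z
  }
  StatVector(z, ids = ids)
}
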