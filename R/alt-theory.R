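#' Construct an EffectModel
#'
#' @param beta regression coefficients (length L).
#' @param sigma predictor correlation matrix (\code{LDMatrix} or matrix).
#' @param n sample size.
#' @param trait "continuous" (default) or "binary".
#' @param threshold liability threshold, binary traits only.
#' @return An \code{\linkS4class{EffectModel}}.
#' @examples
#' EffectModel(c(0.3, 0), equicorrLD(2, 0.5), n = 500)
#' @export
EffectModel <- function(beta, sigma, n, trait = c("continuous", "binary"),
                        threshold = NA_real_) {
  trait <- match.arg(trait)
  if (!is(sigma, "LDMatrix")) sigma <- LDMatrix(sigma)
  new("EffectModel", beta = as.numeric(beta), sigma = sigma, n = as.numeric(n),
      trait = trait, threshold = as.numeric(threshold))
}

#' Attenuation of noncentralities for a dichotomized trait
#'
#' When a normally distributed liability is thresholded at l into a binary
#' outcome, the correlation between each SNP and the observed trait shrinks
#' by d = phi(l) / sqrt(Phi(l) (1 - Phi(l))); noncentralities scale by the
#' same factor. Symmetric in +/- l; at l = 0 (a 50/50 split), d = 2 phi(0)
#' = 0.798.
#'
#' @param l liability threshold.
#' @return The attenuation factor d.
#' @examples
#' binaryAttenuation(0)  # 0.7978846
#' @export
binaryAttenuation <- function(l) {
  stopifnot(is.finite(l))
  stats::dnorm(l) / sqrt(stats::pnorm(l) * stats::pnorm(l, lower.tail = FALSE))
}

#' Noncentralities of association statistics from regression effects
#'
#' The mean of the j-th single-SNP association statistic under the trait
#' model y = beta0 + sum beta_j SNP_j + eps is mu_j = sqrt(N) b_j with
#' b_j = (Sigma_j beta) / sqrt(beta' Sigma beta + 1), where Sigma_j is the
#' j-th row of the predictor correlation matrix -- i.e. b_j = cor(y, SNP_j).
#' For binary traits the correlations are attenuated by
#' \code{\link{binaryAttenuation}} of the liability threshold.
#'
#' @param model an \code{\linkS4class{EffectModel}}.
#' @return List with components \code{mu} (noncentral means, length L) and
#'   \code{b} (trait-SNP correlations).
#' @examples
#' noncentralityFromEffects(EffectModel(c(0.3, 0), equicorrLD(2, 0.5), 500))
#' @export
noncentralityFromEffects <- function(model) {
  beta <- model@beta
  S <- unclass(as.matrix(model@sigma))
  denom <- drop(t(beta) %*% S %*% beta) + 1
  if (denom <= 0) stop("beta' Sigma beta + 1 must be positive")
  b <- drop(S %*% beta) / sqrt(denom)
  if (model@trait == "binary") b <- b * binaryAttenuation(model@threshold)
  list(mu = sqrt(model@n) * b, b = b)
}

#' Correlation among association statistics under the alternative
#'
#' Under association, the correlation among single-SNP statistics is no
#' longer the LD matrix Sigma: it is the delta-method correlation of two
#' sample correlations r(y, SNP_i) and r(y, SNP_j) sharing the outcome
#' (Olkin-Siotani form),
#' cov_ij = rho_ij (1 - b_i^2 - b_j^2)
#'          - (b_i b_j / 2)(1 - b_i^2 - b_j^2 - rho_ij^2),
#' standardized by the variances (1 - b_i^2)^2. At beta = 0 this reduces to
#' Sigma exactly; for rho_ij = 0 but nonzero effects, the statistics
#' correlate with sign opposite to b_i b_j. A result pushed out of positive
#' definiteness by rounding is repaired with a warning.
#'
#' @param model an \code{\linkS4class{EffectModel}}.
#' @return An \code{\linkS4class{LDMatrix}}: the statistic correlation R.
#' @examples
#' altStatisticCorrelation(EffectModel(c(0.3, 0.2), equicorrLD(2, 0.5), 1000))
#' @export
altStatisticCorrelation <- function(model) {
  S <- unclass(as.matrix(model@sigma))
  b <- noncentralityFromEffects(model)$b
  if (any(abs(b) >= 1)) stop("trait-SNP correlations must satisfy |b| < 1")
  B2 <- outer(b^2, b^2, `+`)           # b_i^2 + b_j^2
  BB <- tcrossprod(b)                  # b_i b_j
  cov <- S * (1 - B2) - 0.5 * BB * (1 - B2 - S^2)
  v <- (1 - b^2)^2
  R <- cov / tcrossprod(sqrt(v))
  diag(R) <- 1
  chk <- .validate_corr(structure(R, class = NULL))
  if (!isTRUE(chk)) {
    warning("statistic correlation not positive definite (", chk,
            "); applying nearest-PD repair")
    R <- nearestPDCorrelation(R)
  }
  .as_corr(R, rownames(S))
}

#' Mixture distribution of TQ under the alternative
#'
#' Eigen-decomposes the statistic correlation R and projects the mean vector
#' onto its eigenvectors: TQ = sum lambda_i chisq_{1, gamma_i} with
#' gamma_i = (E_i' mu)^2 / lambda_i. The noncentralities conserve the total
#' sum(gamma) = mu' R^-1 mu = gammaC, the DOT noncentrality.
#'
#' @param mu mean vector of the statistics.
#' @param R statistic correlation matrix (positive definite).
#' @return A \code{\linkS4class{ChiSqMixture}}.
#' @examples
#' tqAltMixture(rep(2, 3), equicorrLD(3, 0.5))
#' @export
tqAltMixture <- function(mu, R) {
  Rm <- unclass(as.matrix(R))
  .check_dims(mu, Rm)
  ee <- eigen(Rm, symmetric = TRUE)
  if (min(ee$values) <= .PD_FLOOR_REL * max(ee$values))
    stop("R is numerically singular; repair with nearestPDCorrelation()")
  proj <- drop(crossprod(ee$vectors, mu))
  gam <- proj^2 / ee$values
  new("ChiSqMixture", lambda = ee$values, gamma = gam,
      df = rep(1, length(gam)), gammaC = sum(gam),
      helmertDeltas = numeric(), deltaS = NA_real_)
}

#' Closed-form Helmert noncentralities under equicorrelation
#'
#' For R_rho = (1 - rho) I + rho 11' the eigenvectors can be taken as the
#' Helmert basis, giving closed-form DOT noncentralities:
#' delta_1 = L mubar^2 / (1 + (L-1) rho) on the leading eigenvalue, and for
#' j > 1, delta_j = (sum_{i<j} mu_i - (j-1) mu_j)^2 / (j (j-1) (1 - rho)).
#' Their tail sum is deltaS = (L-1) dbar / (2 (1 - rho)), with dbar the mean
#' squared pairwise difference of the means, and the total is
#' gammaC = delta_1 + deltaS = mu' R_rho^-1 mu. With equal means the
#' noncentrality sits entirely on the first component (deltaS = 0): the
#' cancellation that caps TQ-style tests and starves DOT.
#'
#' @param mu mean vector.
#' @param rho common correlation, in (-1/(L-1), 1).
#' @return A \code{\linkS4class{ChiSqMixture}} with \code{helmertDeltas} and
#'   \code{deltaS} populated (lambda holds the two distinct eigenvalues
#'   expanded to length L).
#' @examples
#' gammaC(equicorrNoncentralities(seq(2.3, 2.4, length.out = 20), 0.7)) / 20
#' @export
equicorrNoncentralities <- function(mu, rho) {
  L <- length(mu)
  if (L >= 2 && (rho <= -1 / (L - 1) || rho >= 1))
    stop("rho must lie in (-1/(L-1), 1)")
  lam1 <- 1 + (L - 1) * rho
  d1 <- L * mean(mu)^2 / lam1
  if (L >= 2) {
    cums <- cumsum(mu)
    j <- 2:L
    hel <- (cums[j - 1] - (j - 1) * mu[j])^2 / (j * (j - 1))
    deltas <- c(d1, hel / (1 - rho))
    dbar <- mean((stats::dist(mu))^2)
    deltaS <- (L - 1) * dbar / (2 * (1 - rho))
  } else {
    deltas <- d1
    deltaS <- 0
  }
  new("ChiSqMixture", lambda = c(lam1, rep(1 - rho, L - 1)),
      gamma = deltas, df = rep(1, L), gammaC = sum(deltas),
      helmertDeltas = deltas, deltaS = deltaS)
}

#' Exact power of the DOT test
#'
#' DOT = X'X is chi-square with L degrees of freedom and noncentrality
#' gammaC = mu' R^-1 mu, so power at size alpha is the noncentral upper tail
#' at the central chi-square(L) 1 - alpha quantile.
#'
#' @param mu mean vector of the statistics under the alternative.
#' @param R statistic correlation matrix.
#' @param alpha test size.
#' @return A \code{\linkS4class{PowerEstimate}} (mode "exact").
#' @examples
#' dotPower(seq(2.3, 2.4, length.out = 20), equicorrLD(20, 0.7), 0.05)
#' @export
dotPower <- function(mu, R, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  Rm <- unclass(as.matrix(R))
  .check_dims(mu, Rm)
  L <- length(mu)
  gc <- drop(t(mu) %*% solve(Rm, mu))
  pow <- stats::pchisq(stats::qchisq(1 - alpha, df = L), df = L, ncp = gc,
                       lower.tail = FALSE)
  new("PowerEstimate", method = "dot", alpha = alpha, power = pow,
      mode = "exact", mcSE = NA_real_)
}

#' Exact power of the TQ test
#'
#' The null 1 - alpha quantile of the central eigenvalue mixture is found by
#' root search on \code{\link{quadformTail}} (absolute tolerance 1e-9), and
#' power is the alternative mixture's upper tail there. For equicorrelated R
#' the two-distinct-eigenvalue reduction is used automatically, which is
#' exact and much faster than the full L-component mixture.
#'
#' @param mu mean vector under the alternative.
#' @param R statistic correlation matrix.
#' @param alpha test size.
#' @return A \code{\linkS4class{PowerEstimate}} (mode "exact").
#' @examples
#' tqPower(seq(2.3, 2.4, length.out = 20), equicorrLD(20, 0.7), 0.05)
#' @export
tqPower <- function(mu, R, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  Rm <- unclass(as.matrix(R))
  .check_dims(mu, Rm)
  off <- Rm[row(Rm) != col(Rm)]
  if (length(off) && max(abs(off - off[1])) < 1e-12) {
    return(tqEquicorrPower(mu, off[1], alpha))
  }
  mix <- tqAltMixture(mu, Rm)
  q <- .quadform_quantile(mix@lambda, mix@df, alpha)
  pow <- quadformTail(mix@lambda, mix@gamma, q)
  new("PowerEstimate", method = "tq", alpha = alpha, power = pow,
      mode = "exact", mcSE = NA_real_)
}

#' Exact TQ power under equicorrelation (two-component reduction)
#'
#' With only two distinct eigenvalues, the TQ mixture collapses to
#' (1 + (L-1) rho) chisq_{1, gamma_1} + (1 - rho) chisq_{L-1, gammaC - gamma_1},
#' which is evaluated exactly. Agrees with \code{\link{tqPower}} on the full
#' eigenvalue mixture to numerical tolerance.
#'
#' @param mu mean vector.
#' @param rho common correlation.
#' @param alpha test size.
#' @return A \code{\linkS4class{PowerEstimate}} (mode "exact").
#' @examples
#' tqEquicorrPower(seq(2.3, 2.4, length.out = 20), 0.3, 0.05)  # ~0.98
#' @export
tqEquicorrPower <- function(mu, rho, alpha = 0.05) {
  L <- length(mu)
  mix <- equicorrNoncentralities(mu, rho)
  if (L == 1) {
    pow <- stats::pchisq(stats::qchisq(1 - alpha, 1), 1, ncp = mix@gammaC,
                         lower.tail = FALSE)
  } else {
    lam <- c(1 + (L - 1) * rho, 1 - rho)
    df <- c(1, L - 1)
    gam <- c(mix@gamma[1], mix@gammaC - mix@gamma[1])
    q <- .quadform_quantile(lam, df, alpha)
    pow <- quadformTail(lam, gam, q, df = df)
  }
  new("PowerEstimate", method = "tq", alpha = alpha, power = pow,
      mode = "exact", mcSE = NA_real_)
}

# rho* (root-mean-square off-diagonal correlation) and mu* ((mean |mu|)^2)
.rho_star <- function(R) {
  Rm <- unclass(as.matrix(R))
  off <- Rm[row(Rm) != col(Rm)]
  sqrt(mean(off^2))
}
.mu_star <- function(mu) mean(abs(mu))^2

#' One-df location-scale approximation to the null of TQ
#'
#' For large L the non-leading part of the TQ mixture concentrates, so the
#' standardized statistic (TQ - (L-1)(1 - rho*)) / ((L-1) rho* + 1) is
#' approximately chi-square with one degree of freedom under the null. This
#' gives an approximate P-value (and rejection rule) without any mixture
#' evaluation.
#'
#' @param tq observed TQ value(s).
#' @param L number of SNPs.
#' @param rhoStar root-mean-square pairwise correlation (see
#'   \code{\link{tqPowerApprox}}); pass the common rho under equicorrelation.
#' @return Approximate upper-tail P-value(s).
#' @examples
#' tqOneDfApprox(180, L = 100, rhoStar = 0.7)
#' @export
tqOneDfApprox <- function(tq, L, rhoStar) {
  stopifnot(L >= 2)
  stat <- (tq - (L - 1) * (1 - rhoStar)) / ((L - 1) * rhoStar + 1)
  stats::pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
}

#' Approximate power of the TQ test (one-df approximation)
#'
#' Approximates TQ power by a single noncentral one-df chi-square: with
#' mu* = (mean |mu_i|)^2 and rho* = sqrt(mean rho_ij^2), the noncentrality
#' is L mu* / ((L-1) rho* + 1) and the threshold is the central one-df
#' 1 - alpha quantile lowered by the heterogeneity correction
#' (1 - rho*) dbar / (2 rho*^2), where dbar is the mean squared pairwise
#' difference of the means. (The common location shift of the non-leading
#' mixture mass cancels between the null and alternative, so only the
#' dbar term survives.)
#'
#' @param mu mean vector under the alternative.
#' @param R statistic correlation matrix (or a scalar common rho).
#' @param alpha test size.
#' @return A \code{\linkS4class{PowerEstimate}} (mode "approx").
#' @examples
#' tqPowerApprox(seq(2.3, 2.4, length.out = 20), equicorrLD(20, 0.7))
#' @export
tqPowerApprox <- function(mu, R, alpha = 0.05) {
  L <- length(mu)
  stopifnot(L >= 2)
  rs <- if (is.matrix(R) || is(R, "LDMatrix")) .rho_star(R) else as.numeric(R)
  dbar <- mean((stats::dist(mu))^2)
  ncp <- L * .mu_star(mu) / ((L - 1) * rs + 1)
  t <- stats::qchisq(1 - alpha, df = 1) - 0.5 * (1 - rs) * dbar / rs^2
  pow <- stats::pchisq(max(t, 0), df = 1, ncp = ncp, lower.tail = FALSE)
  new("PowerEstimate", method = "tq", alpha = alpha, power = pow,
      mode = "approx", mcSE = NA_real_)
}

#' Asymptotic ceiling of TQ power
#'
#' As L grows with a fixed pattern of effects, the TQ noncentrality
#' converges to gamma* = mu* / rho*: added SNPs stop adding power. The
#' asymptotic power is the one-df noncentral chi-square upper tail at the
#' central one-df 1 - alpha quantile. \code{tqCeilingNoncentrality} returns
#' gamma*; \code{tqCeilingPower} the corresponding power.
#'
#' @param muStar squared mean absolute effect, (mean |mu_i|)^2.
#' @param rhoStar root-mean-square pairwise correlation (> 0; at rho* = 0
#'   there is no ceiling and power grows with L).
#' @param alpha test size.
#' @return \code{tqCeilingNoncentrality}: the scalar gamma*.
#'   \code{tqCeilingPower}: a \code{\linkS4class{PowerEstimate}} (mode
#'   "asymptotic").
#' @examples
#' tqCeilingNoncentrality(2.35^2, 0.7)
#' powerValue(tqCeilingPower(2.35^2, 0.7))  # 0.802
#' @export
tqCeilingNoncentrality <- function(muStar, rhoStar) {
  if (rhoStar <= 0)
    stop("rhoStar must be positive: at rho* = 0 there is no power ceiling")
  muStar / rhoStar
}

#' @rdname tqCeilingNoncentrality
#' @export
tqCeilingPower <- function(muStar, rhoStar, alpha = 0.05) {
  g <- tqCeilingNoncentrality(muStar, rhoStar)
  pow <- stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1, ncp = g,
                       lower.tail = FALSE)
  new("PowerEstimate", method = "tq", alpha = alpha, power = pow,
      mode = "asymptotic", mcSE = NA_real_)
}
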