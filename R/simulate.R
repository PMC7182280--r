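#' SimDesign: a Monte-Carlo simulation design
#'
#' Bundles everything a power or type-I error simulation needs: how the mean
#' vector is formed, how the correlation matrix is formed, the number of
#' SNPs, replicates, test sizes, noise model and (for regression-mode
#' simulations) the per-replicate sample size.
#'
#' @slot muSpec list describing the mean vector: \code{list(type =
#'   "equispaced", lo, hi)}, \code{list(type = "explicit", values)},
#'   \code{list(type = "uniform", lo, hi)} (redrawn every replicate),
#'   \code{list(type = "beta", model)} (an \code{EffectModel}; the mean and
#'   statistic correlation then come from the alternative-hypothesis theory),
#'   or \code{list(type = "null")}.
#' @slot corSpec list describing the correlation: \code{list(type =
#'   "equicorr", rho)}, \code{list(type = "perturbed", rho, uLow, uHigh)}
#'   (rank-one perturbation drawn once per design), \code{list(type =
#'   "randomPD")} (fresh random positive-definite matrix every replicate),
#'   or \code{list(type = "matrix", values)}.
#' @slot L number of SNPs.
#' @slot nReps Monte-Carlo replicates.
#' @slot alpha vector of test sizes.
#' @slot seed RNG seed.
#' @slot noise "normal" or "laplace" (regression mode; unit variance).
#' @slot nIndividuals sample size for regression-mode replicates.
#' @seealso \code{\link{simDesign}}, \code{\link{estimatePower}}
#' @exportClass SimDesign
setClass("SimDesign",
         representation(muSpec = "list", corSpec = "list", L = "numeric",
                        nReps = "numeric", alpha = "numeric", seed = "numeric",
                        noise = "character", nIndividuals = "numeric"))

setValidity("SimDesign", function(object) {
  if (object@nReps < 1) return("nReps must be >= 1")
  if (object@L < 1) return("L must be >= 1")
  if (any(object@alpha <= 0 | object@alpha >= 1)) return("alpha must be in (0,1)")
  if (!object@noise %in% c("normal", "laplace")) return("unknown noise model")
  if (is.null(object@muSpec$type) || is.null(object@corSpec$type))
    return("muSpec and corSpec must carry a 'type' field")
  TRUE
})

#' Construct a SimDesign
#'
#' @param muSpec,corSpec see \code{\linkS4class{SimDesign}}.
#' @param L number of SNPs.
#' @param nReps Monte-Carlo replicates.
#' @param alpha test size(s).
#' @param seed RNG seed.
#' @param noise "normal" or "laplace".
#' @param nIndividuals regression-mode sample size.
#' @return A \code{\linkS4class{SimDesign}}.
#' @examples
#' simDesign(list(type = "equispaced", lo = 2.3, hi = 2.4),
#'           list(type = "equicorr", rho = 0.7), L = 20, nReps = 1e4)
#' @export
simDesign <- function(muSpec, corSpec, L, nReps = 1e5, alpha = 0.05,
                      seed = 1, noise = "normal", nIndividuals = 500) {
  new("SimDesign", muSpec = muSpec, corSpec = corSpec, L = as.numeric(L),
      nReps = as.numeric(nReps), alpha = as.numeric(alpha),
      seed = as.numeric(seed), noise = noise,
      nIndividuals = as.numeric(nIndividuals))
}

#' Sample association statistics from their multivariate normal law
#'
#' Draws \code{nReps} independent vectors from MVN(mu, R): the direct
#' simulation shortcut for association statistics that avoids generating
#' individual-level data (the mean and correlation under the alternative
#' come from \code{\link{noncentralityFromEffects}} and
#' \code{\link{altStatisticCorrelation}}).
#'
#' @param mu mean vector (length L).
#' @param R correlation matrix.
#' @param nReps number of draws.
#' @param seed optional RNG seed.
#' @return nReps x L matrix; one statistic vector per row.
#' @examples
#' Z <- sampleStatistics(rep(0, 4), equicorrLD(4, 0.5), 100, seed = 1)
#' @export
sampleStatistics <- function(mu, R, nReps, seed = NULL) {
  Rm <- unclass(as.matrix(R))
  .check_dims(mu, Rm)
  L <- length(mu)
  .with_seed(seed, {
    Z <- matrix(stats::rnorm(nReps * L), nReps, L) %*% chol(Rm)
    sweep(Z, 2, mu, `+`)
  })
}

# Unit-variance noise for the regression generator.
.noise <- function(n, kind) {
  switch(kind,
         normal = stats::rnorm(n),
         laplace = (stats::rexp(n) - stats::rexp(n)) / sqrt(2),
         stop("unknown noise model: ", kind))
}

#' Simulate marginal regression statistics from individual-level data
#'
#' Generates predictor data X ~ MVN(0, Sigma), forms the trait
#' y = X beta + eps with unit-variance normal or Laplace noise, and returns
#' the per-SNP marginal association statistics t_j = r_j sqrt((n-2)/(1-r_j^2))
#' with r_j = cor(y, X_j) -- the regression route that the direct MVN
#' sampling of \code{\link{sampleStatistics}} replaces.
#'
#' @param model an \code{\linkS4class{EffectModel}} (uses beta, sigma and n).
#' @param noise "normal" or "laplace".
#' @param nReps number of replicate datasets.
#' @param seed optional RNG seed.
#' @return nReps x L matrix of statistics, one replicate per row.
#' @examples
#' m <- EffectModel(c(0.3, 0), equicorrLD(2, 0.5), n = 200)
#' simulateRegressionStatistics(m, nReps = 5, seed = 1)
#' @export
simulateRegressionStatistics <- function(model, noise = "normal", nReps = 1,
                                         seed = NULL) {
  S <- unclass(as.matrix(model@sigma))
  L <- nrow(S)
  n <- as.integer(model@n)
  if (n < L + 2) stop("need at least L + 2 individuals")
  U <- chol(S)
  beta <- model@beta
  .with_seed(seed, {
    out <- matrix(NA_real_, nReps, L)
    for (i in seq_len(nReps)) {
      X <- matrix(stats::rnorm(n * L), n, L) %*% U
      sdx <- sqrt(colSums(scale(X, scale = FALSE)^2))
      if (any(sdx == 0)) stop("degenerate predictor column in replicate ", i)
      y <- drop(X %*% beta) + .noise(n, noise)
      r <- drop(stats::cor(y, X))
      out[i, ] <- r * sqrt((n - 2) / (1 - r^2))
    }
    out
  })
}

# ---- internal fast engine ---------------------------------------------------

# Structure-aware sampler state for a fixed correlation matrix. Returns a
# list with: draw(n, mu) -> n x L matrix, Rm (the matrix), lambda
# (eigenvalues), dotQuad(Z) -> vector of Z' R^-1 Z.
.corr_engine <- function(corSpec, L) {
  type <- corSpec$type
  if (type == "equicorr") {
    rho <- corSpec$rho
    lam1 <- 1 + (L - 1) * rho
    Rm <- unclass(equicorrLD(L, rho))
    list(
      Rm = Rm,
      lambda = c(lam1, rep(1 - rho, L - 1)),
      draw = function(n, mu) {
        Z <- sqrt(1 - rho) * matrix(stats::rnorm(n * L), n, L) +
          sqrt(rho) * stats::rnorm(n)
        if (is.matrix(mu)) Z + mu else sweep(Z, 2, mu, `+`)
      },
      dotQuad = function(Z) {
        (rowSums(Z^2) - rho * rowSums(Z)^2 / lam1) / (1 - rho)
      })
  } else if (type == "perturbed") {
    rho <- corSpec$rho
    U <- stats::runif(L, corSpec$uLow, corSpec$uHigh)
    B <- matrix(rho, L, L); diag(B) <- 1
    B <- B + tcrossprod(U)
    d <- 1 / sqrt(diag(B))
    Rm <- .cov2cor(B)
    Rinv <- solve(Rm)
    list(
      Rm = Rm,
      lambda = eigen(Rm, symmetric = TRUE, only.values = TRUE)$values,
      draw = function(n, mu) {
        # B = (1-rho) I + rho 11' + UU' is the covariance; scale rows by d
        Z <- (sqrt(1 - rho) * matrix(stats::rnorm(n * L), n, L) +
                sqrt(rho) * stats::rnorm(n) +
                tcrossprod(stats::rnorm(n), U))
        Z <- sweep(Z, 2, d, `*`)
        if (is.matrix(mu)) Z + mu else sweep(Z, 2, mu, `+`)
      },
      dotQuad = function(Z) rowSums((Z %*% Rinv) * Z))
  } else if (type == "matrix") {
    Rm <- unclass(as.matrix(corSpec$values))
    Ch <- chol(Rm)
    Rinv <- chol2inv(Ch)
    list(
      Rm = Rm,
      lambda = eigen(Rm, symmetric = TRUE, only.values = TRUE)$values,
      draw = function(n, mu) {
        Z <- matrix(stats::rnorm(n * L), n, L) %*% Ch
        if (is.matrix(mu)) Z + mu else sweep(Z, 2, mu, `+`)
      },
      dotQuad = function(Z) rowSums((Z %*% Rinv) * Z))
  } else stop("corSpec type '", type, "' has no fixed-matrix engine")
}

# Mean vector per design; "uniform" and "beta" resolved by the caller.
.resolve_mu <- function(muSpec, L) {
  switch(muSpec$type,
         equispaced = seq(muSpec$lo, muSpec$hi, length.out = L),
         explicit = {
           stopifnot(length(muSpec$values) == L)
           as.numeric(muSpec$values)
         },
         null = rep(0, L),
         stop("muSpec type '", muSpec$type, "' must be resolved upstream"))
}

# Per-row |Z| maximum without apply().
.row_max_abs <- function(Z) {
  A <- abs(Z)
  A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
}

# Rejection indicators for one chunk of statistic vectors, all methods and
# alphas. Thresholds precomputed by the caller.
.chunk_rejections <- function(Z, eng, thresholds, methods, alpha) {
  out <- list()
  if ("tq" %in% methods) tqs <- rowSums(Z^2)
  if ("dot" %in% methods) dots <- eng$dotQuad(Z)
  if ("acat" %in% methods || "minp" %in% methods) {
    P <- 2 * stats::pnorm(-abs(Z))
  }
  if ("acat" %in% methods) acats <- rowMeans(tan((0.5 - P) * pi))
  if ("minp" %in% methods)
    minps <- pmin(1, ncol(Z) * 2 * stats::pnorm(-.row_max_abs(Z)))
  for (a in seq_along(alpha)) {
    for (m in methods) {
      out[[paste(m, a, sep = ".")]] <- switch(
        m,
        tq = sum(tqs > thresholds$tq[a]),
        dot = sum(dots > thresholds$dot[a]),
        acat = sum(acats > thresholds$acat[a]),
        minp = sum(minps < alpha[a]))
    }
  }
  out
}

#' Estimate power (or size) of the gene-level tests by Monte Carlo
#'
#' Runs the design's replicates, applies each requested method to every
#' simulated statistic vector, and reports rejection proportions with
#' Monte-Carlo standard errors. Statistic vectors are drawn directly from
#' their multivariate normal law (mode "mvn", the fast path justified by the
#' alternative-hypothesis theory) or computed from simulated
#' individual-level regressions (mode "regression"; the tests then use the
#' replicate's sample LD, as in same-data practice). Under muSpec type
#' "uniform" the mean vector is redrawn every replicate; under corSpec type
#' "randomPD" a fresh random positive-definite correlation is drawn every
#' replicate. All methods see the same simulated vectors (common random
#' numbers).
#'
#' @param design a \code{\linkS4class{SimDesign}}.
#' @param methods subset of "tq", "dot", "acat", "minp".
#' @param mode "mvn" or "regression".
#' @param chunkSize replicates per vectorized block (memory knob).
#' @return data.frame: method, alpha, power, mcSE, nReps, seed.
#' @examples
#' d <- simDesign(list(type = "equispaced", lo = 2.3, hi = 2.4),
#'                list(type = "equicorr", rho = 0.7), L = 20, nReps = 2000)
#' estimatePower(d, methods = c("tq", "dot"))
#' @export
estimatePower <- function(design, methods = c("tq", "dot", "acat", "minp"),
                          mode = c("mvn", "regression"), chunkSize = 2e4) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("tq", "dot", "acat", "minp"),
                       several.ok = TRUE)
  L <- as.integer(design@L)
  alpha <- design@alpha
  nReps <- as.integer(design@nReps)
  .with_seed(design@seed, {
    if (design@corSpec$type == "randomPD") {
      return(.estimate_random_pd(design, methods))
    }
    if (mode == "regression") {
      return(.estimate_regression(design, methods))
    }
    if (design@muSpec$type == "beta") {
      model <- design@muSpec$model
      mu <- noncentralityFromEffects(model)$mu
      eng <- .corr_engine(list(type = "matrix",
                               values = altStatisticCorrelation(model)), L)
    } else {
      eng <- .corr_engine(design@corSpec, L)
      mu <- NULL
      if (design@muSpec$type != "uniform") mu <- .resolve_mu(design@muSpec, L)
    }
    thresholds <- list(
      tq = vapply(alpha, function(a)
        .quadform_quantile(eng$lambda, rep(1, L), a), numeric(1)),
      dot = stats::qchisq(1 - alpha, df = L),
      acat = stats::qcauchy(1 - alpha))
    counts <- NULL
    done <- 0L
    while (done < nReps) {
      n <- min(chunkSize, nReps - done)
      mu_chunk <- if (is.null(mu)) {
        matrix(stats::runif(n * L, design@muSpec$lo, design@muSpec$hi), n, L)
      } else mu
      Z <- eng$draw(n, mu_chunk)
      cc <- .chunk_rejections(Z, eng, thresholds, methods, alpha)
      counts <- if (is.null(counts)) cc else Map(`+`, counts, cc)
      done <- done + n
    }
    .mc_table(counts, methods, alpha, nReps, design@seed)
  })
}

.mc_table <- function(counts, methods, alpha, nReps, seed) {
  rows <- expand.grid(method = methods, alphaIdx = seq_along(alpha),
                      stringsAsFactors = FALSE)
  p <- mapply(function(m, a) counts[[paste(m, a, sep = ".")]] / nReps,
              rows$method, rows$alphaIdx)
  data.frame(method = rows$method, alpha = alpha[rows$alphaIdx],
             power = p, mcSE = sqrt(p * (1 - p) / nReps),
             nReps = nReps, seed = seed, row.names = NULL)
}

# Per-replicate random positive-definite correlation: the type-I error
# design. One eigendecomposition per replicate serves sampling, the TQ
# mixture P-value and the DOT quadratic form.
.estimate_random_pd <- function(design, methods) {
  L <- as.integer(design@L)
  alpha <- design@alpha
  nReps <- as.integer(design@nReps)
  if (design@muSpec$type != "null")
    stop("randomPD correlation mode is a null (type-I error) design")
  counts <- matrix(0L, length(methods), length(alpha),
                   dimnames = list(methods, NULL))
  qc <- stats::qchisq(1 - alpha, df = L)
  zero <- rep(0, L)
  ones <- rep(1, L)
  for (i in seq_len(nReps)) {
    Rm <- .random_pd_corr(L)
    ch <- chol(Rm)
    z <- drop(crossprod(ch, stats::rnorm(L)))
    if ("tq" %in% methods) {
      stat <- sum(z^2)
      lam_lb <- max(1, sum(Rm) / L)  # 1'R1/L <= lambda_1
      if (stats::pchisq(stat / lam_lb, 1, lower.tail = FALSE) <=
            max(alpha)) {
        lam <- eigen(Rm, symmetric = TRUE, only.values = TRUE)$values
        ptq <- .imhof_tail(lam, ones, zero, stat, absTol = 1e-6)
        counts["tq", ] <- counts["tq", ] + (ptq < alpha)
      }
    }
    if ("dot" %in% methods) {
      dotstat <- sum(backsolve(ch, z, transpose = TRUE)^2)
      counts["dot", ] <- counts["dot", ] + (dotstat > qc)
    }
    if ("acat" %in% methods) {
      pz <- 2 * stats::pnorm(-abs(z))
      pa <- stats::pcauchy(mean(tan((0.5 - pz) * pi)), lower.tail = FALSE)
      counts["acat", ] <- counts["acat", ] + (pa < alpha)
    }
    if ("minp" %in% methods) {
      pm <- min(1, L * 2 * stats::pnorm(-max(abs(z))))
      counts["minp", ] <- counts["minp", ] + (pm < alpha)
    }
  }
  cl <- as.list(as.vector(t(counts)))
  names(cl) <- as.vector(outer(seq_along(alpha), methods,
                               function(a, m) paste(m, a, sep = ".")))
  .mc_table(cl, methods, alpha, nReps, design@seed)
}

# Regression-mode power: statistics and the LD used by the tests both come
# from the same simulated dataset.
.estimate_regression <- function(design, methods) {
  L <- as.integer(design@L)
  alpha <- design@alpha
  nReps <- as.integer(design@nReps)
  if (design@muSpec$type != "beta")
    stop("regression mode requires muSpec type 'beta' (an EffectModel)")
  model <- design@muSpec$model
  S <- unclass(as.matrix(model@sigma))
  n <- as.integer(model@n)
  U <- chol(S)
  beta <- model@beta
  counts <- matrix(0L, length(methods), length(alpha),
                   dimnames = list(methods, NULL))
  qc <- stats::qchisq(1 - alpha, df = L)
  for (i in seq_len(nReps)) {
    X <- matrix(stats::rnorm(n * L), n, L) %*% U
    y <- drop(X %*% beta) + .noise(n, design@noise)
    r <- drop(stats::cor(y, X))
    z <- r * sqrt((n - 2) / (1 - r^2))
    Rhat <- stats::cor(X)
    ee <- eigen(Rhat, symmetric = TRUE)
    if ("tq" %in% methods) {
      ptq <- .imhof_tail(ee$values, rep(1, L), rep(0, L), sum(z^2),
                         absTol = 1e-6)
      counts["tq", ] <- counts["tq", ] + (ptq < alpha)
    }
    if ("dot" %in% methods) {
      dotstat <- sum(drop(crossprod(ee$vectors, z))^2 / ee$values)
      counts["dot", ] <- counts["dot", ] + (dotstat > qc)
    }
    if ("acat" %in% methods) {
      pz <- 2 * stats::pnorm(-abs(z))
      pa <- stats::pcauchy(mean(tan((0.5 - pz) * pi)), lower.tail = FALSE)
      counts["acat", ] <- counts["acat", ] + (pa < alpha)
    }
    if ("minp" %in% methods) {
      pm <- min(1, L * 2 * stats::pnorm(-max(abs(z))))
      counts["minp", ] <- counts["minp", ] + (pm < alpha)
    }
  }
  cl <- as.list(as.vector(t(counts)))
  names(cl) <- as.vector(outer(seq_along(alpha), methods,
                               function(a, m) paste(m, a, sep = ".")))
  .mc_table(cl, methods, alpha, nReps, design@seed)
}

#' Null type-I error of the gene-level tests
#'
#' Convenience wrapper around \code{\link{estimatePower}} with a zero mean
#' vector: reports the empirical rejection rate of each method at the given
#' alpha levels. With \code{correlation = "randomPD"} a fresh random
#' positive-definite correlation matrix is drawn for every replicate -- the
#' stress test that the mixture machinery holds under arbitrary valid LD.
#'
#' @param L number of SNPs.
#' @param nReps replicates.
#' @param alpha test size(s).
#' @param correlation "randomPD", or a list/corSpec as in
#'   \code{\linkS4class{SimDesign}}, or a correlation matrix.
#' @param methods subset of "tq", "dot", "acat", "minp".
#' @param seed RNG seed.
#' @return data.frame as \code{\link{estimatePower}}.
#' @examples
#' estimateType1(5, nReps = 500, correlation = list(type = "equicorr",
#'               rho = 0.5), seed = 2)
#' @export
estimateType1 <- function(L, nReps = 1e5, alpha = 0.05,
                          correlation = "randomPD",
                          methods = c("tq", "dot"), seed = 1) {
  corSpec <- if (identical(correlation, "randomPD")) {
    list(type = "randomPD")
  } else if (is.list(correlation)) {
    correlation
  } else {
    list(type = "matrix", values = correlation)
  }
  d <- simDesign(list(type = "null"), corSpec, L = L, nReps = nReps,
                 alpha = alpha, seed = seed)
  estimatePower(d, methods = methods)
}

#' Type-I error under reference-panel LD misspecification
#'
#' Statistics are drawn under the true population correlation, but every
#' replicate's tests use a freshly resampled panel estimate of it (sample
#' correlation of \code{panelMultiplier * L} surrogate genotypes). This
#' reproduces the practical situation where summary statistics come from the
#' study but LD from an external panel: TQ and ACAT stay near nominal while
#' DOT inflates unless the panel is many times larger than the SNP count.
#'
#' @param population population correlation matrix (\code{LDMatrix} or
#'   matrix).
#' @param panelMultiplier k >= 2; the panel size is N = k L.
#' @param alpha test size(s) (small alphas are where DOT inflation bites).
#' @param nReps replicates.
#' @param methods subset of "tq", "dot", "acat".
#' @param seed RNG seed.
#' @return data.frame: method, alpha, power (the type-I rate), mcSE, nReps,
#'   seed, panelMultiplier, nRepaired (panel estimates needing PD repair).
#' @examples
#' referencePanelExperiment(equicorrLD(5, 0.5), panelMultiplier = 10,
#'                          alpha = 0.05, nReps = 500, seed = 3)
#' @export
referencePanelExperiment <- function(population, panelMultiplier, alpha = 1e-3,
                                     nReps = 1e5,
                                     methods = c("tq", "dot", "acat"),
                                     seed = 1) {
  if (panelMultiplier < 2) stop("panelMultiplier must be >= 2")
  Rm <- unclass(as.matrix(population))
  L <- nrow(Rm)
  N <- as.integer(panelMultiplier * L)
  Ch <- chol(Rm)
  counts <- matrix(0L, length(methods), length(alpha),
                   dimnames = list(methods, NULL))
  repaired <- 0L
  qc <- stats::qchisq(1 - alpha, df = L)
  zero <- rep(0, L)
  ones <- rep(1, L)
  .with_seed(seed, {
    chunk <- 1000L
    done <- 0L
    while (done < nReps) {
      nb <- min(chunk, nReps - done)
      Z <- matrix(stats::rnorm(nb * L), nb, L) %*% Ch
      Wh <- stats::rWishart(nb, df = N - 1, Sigma = Rm)
      for (i in seq_len(nb)) {
        z <- Z[i, ]
        Sighat <- .cov2cor(Wh[, , i])
        ch <- tryCatch(chol(Sighat), error = function(e) NULL)
        if (is.null(ch)) {
          Sighat <- nearestPDCorrelation(Sighat)
          ch <- chol(Sighat)
          repaired <- repaired + 1L
        }
        if ("tq" %in% methods) {
          stat <- sum(z^2)
          # rigorous screen: p >= P(lambda_1 chisq_1 > t) and
          # lambda_1 >= 1'S1/L, so most null replicates skip the inversion
          lam_lb <- max(1, sum(Sighat) / L)
          if (stats::pchisq(stat / lam_lb, 1, lower.tail = FALSE) <=
                max(alpha)) {
            lam <- eigen(Sighat, symmetric = TRUE,
                         only.values = TRUE)$values
            ptq <- .imhof_tail(lam, ones, zero, stat, absTol = 1e-5)
            counts["tq", ] <- counts["tq", ] + (ptq < alpha)
          }
        }
        if ("dot" %in% methods) {
          dotstat <- sum(backsolve(ch, z, transpose = TRUE)^2)
          counts["dot", ] <- counts["dot", ] + (dotstat > qc)
        }
        if ("acat" %in% methods) {
          pz <- 2 * stats::pnorm(-abs(z))
          pa <- stats::pcauchy(mean(tan((0.5 - pz) * pi)),
                               lower.tail = FALSE)
          counts["acat", ] <- counts["acat", ] + (pa < alpha)
        }
      }
      done <- done + nb
    }
  })
  cl <- as.list(as.vector(t(counts)))
  names(cl) <- as.vector(outer(seq_along(alpha), methods,
                               function(a, m) paste(m, a, sep = ".")))
  out <- .mc_table(cl, methods, alpha, nReps, seed)
  out$panelMultiplier <- panelMultiplier
  out$nRepaired <- repaired
  out
}
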