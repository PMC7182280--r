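test_that("liability attenuation follows the threshold closed form", {
  expect_equal(binaryAttenuation(0), 2 * dnorm(0), tolerance = 1e-12)
  expect_equal(binaryAttenuation(1.5), binaryAttenuation(-1.5),
               tolerance = 1e-12)
  l <- 1
  direct <- exp(-l^2 / 2) / sqrt(2 * pi) /
    sqrt(pnorm(l) * (1 - pnorm(l)))
  expect_equal(binaryAttenuation(1), direct, tolerance = 1e-12)
})

test_that("noncentral means scale the trait-SNP correlations by sqrt(N)", {
  # one causal, one proxy SNP: moderate LD separates the means
  m <- EffectModel(c(0.3, 0), equicorrLD(2, 0.5), n = 500)
  nc <- noncentralityFromEffects(m)
  expect_equal(round(nc$b, 2), c(0.29, 0.14))
  expect_equal(nc$mu, sqrt(500) * nc$b)

  # near-perfect LD makes them indistinguishable (both close to 0.29)
  m99 <- EffectModel(c(0.3, 0), equicorrLD(2, 0.99), n = 500)
  b99 <- noncentralityFromEffects(m99)$b
  expect_lt(abs(b99[1] - b99[2]), 0.005)
  expect_lt(max(abs(b99 - 0.29)), 0.01)

  m0 <- EffectModel(c(0, 0, 0), equicorrLD(3, 0.4), n = 1000)
  expect_equal(noncentralityFromEffects(m0)$mu, rep(0, 3))

  # binary trait: multiplicative attenuation
  mb <- EffectModel(c(0.3, 0), equicorrLD(2, 0.5), n = 500,
                    trait = "binary", threshold = 1)
  expect_equal(noncentralityFromEffects(mb)$mu,
               nc$mu * binaryAttenuation(1), tolerance = 1e-12)
})

test_that("statistic correlation reduces to LD at beta = 0 and departs under effects", {
  S <- perturbedEquicorrLD(4, 0.3, 0, 1, seed = 3)
  m0 <- EffectModel(rep(0, 4), S, n = 800)
  expect_equal(unclass(altStatisticCorrelation(m0)), unclass(S),
               tolerance = 1e-12)

  # no LD but shared outcome: statistics correlate, sign opposite to b_i b_j
  m <- EffectModel(c(0.4, 0.4), equicorrLD(2, 0), n = 800)
  r <- unclass(altStatisticCorrelation(m))[1, 2]
  expect_lt(r, 0)
  m2 <- EffectModel(c(0.4, -0.4), equicorrLD(2, 0), n = 800)
  expect_gt(unclass(altStatisticCorrelation(m2))[1, 2], 0)
})

test_that("regression simulations validate the mean and correlation theory", {
  # small standardized effects: the regime where the MVN law of the
  # statistics (unit variances) holds to within Monte-Carlo resolution
  model <- EffectModel(c(0.06, 0.04), equicorrLD(2, 0.5), n = 1000)
  nreps <- 2e4
  Z <- simulateRegressionStatistics(model, noise = "laplace", nReps = nreps,
                                    seed = 77)
  mu <- noncentralityFromEffects(model)$mu
  # means match Eq-2-style noncentralities
  for (j in 1:2)
    expect_lt(abs(mean(Z[, j]) - mu[j]), 3 * sd(Z[, j]) / sqrt(nreps))
  # correlation matches the delta-method alternative correlation
  r_theory <- unclass(altStatisticCorrelation(model))[1, 2]
  r_emp <- cor(Z[, 1], Z[, 2])
  se_r <- (1 - r_theory^2) / sqrt(nreps)
  expect_lt(abs(r_emp - r_theory), 3 * se_r)
})

test_that("TQ mixture noncentralities conserve mu' R^-1 mu", {
  mix0 <- tqAltMixture(rep(0, 5), randomPDLD(5, seed = 8))
  expect_equal(noncentralities(mix0), rep(0, 5))

  # equal means under equicorrelation: everything loads on the first component
  mixE <- tqAltMixture(rep(2, 6), equicorrLD(6, 0.5))
  expect_equal(gammaC(mixE), noncentralities(mixE)[1], tolerance = 1e-8)
  expect_equal(noncentralities(mixE)[-1], rep(0, 5), tolerance = 1e-8)

  set.seed(31)
  for (i in 1:5) {
    L <- sample(3:12, 1)
    # shrink towards identity for a well-conditioned random structure
    R <- LDMatrix(0.5 * unclass(randomPDLD(L, seed = 100 + i)) +
                    0.5 * diag(L))
    mu <- rnorm(L)
    mix <- tqAltMixture(mu, R)
    direct <- drop(t(mu) %*% solve(unclass(R), mu))
    expect_equal(sum(noncentralities(mix)), direct, tolerance = 1e-8)
    expect_equal(gammaC(mix), direct, tolerance = 1e-8)
  }
})

test_that("Helmert closed forms equal the matrix noncentralities", {
  mu_eq <- rep(1.7, 9)
  mix <- equicorrNoncentralities(mu_eq, 0.6)
  expect_equal(mix@deltaS, 0, tolerance = 1e-12)
  expect_equal(gammaC(mix), 9 * 1.7^2 / (1 + 8 * 0.6), tolerance = 1e-10)

  set.seed(14)
  mu <- rnorm(7, 1)
  mixr <- equicorrNoncentralities(mu, 0.4)
  direct <- drop(t(mu) %*% solve(unclass(equicorrLD(7, 0.4)), mu))
  expect_equal(gammaC(mixr), direct, tolerance = 1e-10)
  expect_equal(sum(mixr@helmertDeltas), gammaC(mixr), tolerance = 1e-10)
  expect_equal(mixr@helmertDeltas[1] + mixr@deltaS, gammaC(mixr),
               tolerance = 1e-10)

  # benchmark per-SNP noncentralities, to the two printed decimals
  expect_equal(round(gammaC(equicorrNoncentralities(mu_setting1(20), 0.7))
                     / 20, 2), 0.39)
  expect_equal(round(gammaC(equicorrNoncentralities(mu_setting1(500), 0.7))
                     / 500, 2), 0.02)
})

test_that("analytic DOT and TQ power reproduce the equicorrelated benchmarks", {
  # comparisons at the precision the benchmark values are stated to
  expect_lt(abs(powerValue(dotPower(mu_setting1(20), equicorrLD(20, 0.7))) -
                0.306), 0.0005)
  expect_lt(abs(powerValue(tqPower(mu_setting1(500), equicorrLD(500, 0.7))) -
                0.802), 0.0005)
  expect_lt(abs(powerValue(dotPower(mu_setting3(100), equicorrLD(100, 0.7))) -
                0.920), 0.0005)
  expect_lt(abs(powerValue(tqPower(mu_setting3(500), equicorrLD(500, 0.7))) -
                0.525), 0.0005)
  # lower common correlation: both methods gain, TQ dramatically
  expect_lt(abs(powerValue(tqEquicorrPower(mu_setting1(20), 0.3)) - 0.98),
            0.005)
  expect_lt(abs(powerValue(dotPower(mu_setting1(20), equicorrLD(20, 0.3))) -
                0.67), 0.005)
  # size under the null
  expect_equal(powerValue(dotPower(rep(0, 10), equicorrLD(10, 0.5))), 0.05,
               tolerance = 1e-8)
  expect_equal(powerValue(tqPower(rep(0, 10), equicorrLD(10, 0.5))), 0.05,
               tolerance = 1e-6)
})

test_that("two-component reduction agrees with the full eigenvalue mixture", {
  for (L in c(20, 100)) {
    mu <- mu_setting1(L)
    rho <- 0.7
    p_two <- powerValue(tqEquicorrPower(mu, rho))
    # full-eigenvalue route, built from the generic mixture machinery
    mix <- tqAltMixture(mu, equicorrLD(L, rho))
    m <- sum(mixtureWeights(mix))
    s <- sqrt(2 * sum(mixtureWeights(mix)^2))
    q <- uniroot(function(t) quadformTail(mixtureWeights(mix), 0, t) - 0.05,
                 c(m, m + 100 * s), tol = 1e-9)$root
    p_full <- quadformTail(mixtureWeights(mix), noncentralities(mix), q)
    expect_equal(p_two, p_full, tolerance = 1e-6)
  }
})

test_that("the one-df approximation tracks the TQ null and power", {
  # null calibration of the location-scale rule
  L <- 100; rho <- 0.7
  nrep <- 1e5
  set.seed(41)
  Z <- sqrt(1 - rho) * matrix(rnorm(nrep * L), nrep, L) + sqrt(rho) * rnorm(nrep)
  rej <- mean(tqOneDfApprox(rowSums(Z^2), L, rho) < 0.05)
  expect_lt(abs(rej - 0.05), 3 * mc_se(0.05, nrep))

  # power via the location-scale threshold: matches the printed 0.526 +/- 0.002
  L5 <- 500
  thr <- qchisq(0.95, 1) * ((L5 - 1) * rho + 1) + (L5 - 1) * (1 - rho)
  mix <- equicorrNoncentralities(mu_setting3(L5), rho)
  p_approx <- quadformTail(c(1 + (L5 - 1) * rho, 1 - rho),
                           c(mix@helmertDeltas[1], mix@deltaS), thr,
                           df = c(1, L5 - 1))
  expect_lt(abs(p_approx - 0.526), 0.002)
})

test_that("approximate TQ power reproduces the printed approximation column", {
  expect_lt(abs(powerValue(tqPowerApprox(mu_setting1(20),
                                         equicorrLD(20, 0.7))) - 0.794),
            0.001)
  expect_lt(abs(powerValue(tqPowerApprox(mu_setting1(500),
                                         equicorrLD(500, 0.7))) - 0.802),
            0.001)
  # with equal effects and large L the approximation is near exact
  mu <- rep(2.2, 150)
  expect_lt(abs(powerValue(tqPowerApprox(mu, equicorrLD(150, 0.7))) -
                powerValue(tqEquicorrPower(mu, 0.7))), 0.01)
})

test_that("the TQ power ceiling is mu*/rho*", {
  expect_equal(tqCeilingNoncentrality(2.35^2, 0.7), 2.35^2 / 0.7)
  expect_lt(abs(powerValue(tqCeilingPower(2.35^2, 0.7)) - 0.802), 0.0005)
  expect_lt(abs(powerValue(tqCeilingPower(2.35^2, 0.3)) - 0.99), 0.005)
  expect_equal(powerValue(tqCeilingPower(0, 0.7)), 0.05, tolerance = 1e-10)
  expect_error(tqCeilingNoncentrality(1, 0), "rho")
})

test_that("DOT gains with L while TQ converges to its ceiling", {
  rho <- 0.7
  Ls <- c(20, 50, 100, 300)
  dot_pow <- vapply(Ls, function(L)
    powerValue(dotPower(mu_setting3(L), equicorrLD(L, rho))), numeric(1))
  tq_pow <- vapply(Ls, function(L)
    powerValue(tqEquicorrPower(mu_setting3(L), rho)), numeric(1))
  expect_true(all(diff(dot_pow) > 0))
  # TQ stays pinned near its asymptotic ceiling across the whole L range
  ceiling_pow <- powerValue(tqCeilingPower(mean(abs(mu_setting3(300)))^2, rho))
  expect_lt(max(tq_pow) - min(tq_pow), 0.01)
  expect_true(all(abs(tq_pow - ceiling_pow) < 0.06))

  # homogeneous effects favour TQ; heterogeneous effects favour DOT at large L
  expect_gt(powerValue(tqEquicorrPower(mu_setting1(100), rho)),
            powerValue(dotPower(mu_setting1(100), equicorrLD(100, rho))))
  expect_gt(powerValue(dotPower(mu_setting3(300), equicorrLD(300, rho))),
            powerValue(tqEquicorrPower(mu_setting3(300), rho)))
})

test_that("DOT power increases with the total noncentrality", {
  L <- 15
  R <- equicorrLD(L, 0.4)
  g <- seq(2, 40, length.out = 8)
  pows <- vapply(g, function(gc) {
    mu <- rep(sqrt(gc / drop(t(rep(1, L)) %*% solve(unclass(R), rep(1, L)))), L)
    powerValue(dotPower(mu, R))
  }, numeric(1))
  expect_true(all(diff(pows) > 0))
})
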