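---
title: "Gene-set association by decorrelation: models, power theory, and design notes"
author: "dotgsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set association by decorrelation: models, power theory, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotgsa)
```

## The problem

A gene-based (or SNP-set) association test asks whether a group of L SNPs is
jointly associated with a trait, using only per-SNP summary statistics
$Z_1,\dots,Z_L$ (or equivalently P-values) and the linkage-disequilibrium
(LD) correlation matrix among the SNPs. Under the usual large-sample
arguments the vector $\mathbf Z$ is multivariate normal with correlation
matrix $\mathbf R$; with no covariates, $\mathbf R$ equals the LD matrix
$\boldsymbol\Sigma$ of 0/1/2 allele dosages, and with covariates it is the
Schur complement of the SNP block of the full predictor correlation matrix
(`covariateAdjustedLD()`).

Two families of statistics are covered:

* **TQ** ("test by quadratic form", the VEGAS-style statistic):
  $T_Q = \sum_i Z_i^2$. Its null law is the weighted mixture
  $\sum_i \lambda_i \chi^2_{1}$ with $\lambda_i$ the eigenvalues of
  $\mathbf R$.
* **DOT** (decorrelation by orthogonal transformation):
  $\mathbf X = \mathbf H \mathbf Z$ with
  $\mathbf H = \mathbf E\,\mathrm{diag}(1/\sqrt{\lambda})\,\mathbf E'$ the
  *symmetric* inverse square root of $\mathbf R$, and
  $\mathrm{DOT} = \sum_i X_i^2 = \mathbf Z'\mathbf R^{-1}\mathbf Z$, a central
  $\chi^2_L$ under the null.

The package also provides the Cauchy combination (ACAT), Bonferroni min-P,
and the rank truncated product (RTP) applied to the decorrelated
statistics, plus the alternative-hypothesis theory that explains when DOT
dominates TQ and by how much.

## Why the symmetric square root

Any $\mathbf H$ with $\mathbf{HRH}' = \mathbf I$ decorrelates, but most
choices (inverse Cholesky factor, $\mathbf E\,\mathrm{diag}(1/\sqrt\lambda)$
alone, Helmert rotations) make the individual values $X_i$ depend on the
arbitrary ordering of the input SNPs. The symmetric root is invariant to
order for equicorrelated inputs: permuting $\mathbf Z$ permutes the $X_i$
without changing their values. That matters beyond aesthetics, because the
follow-up machinery treats individual components seriously: RTP truncates
the ordered component P-values, and the contributor analysis
(`topContributors()`) reads per-SNP terms $h_{ij} Z_j$ off single
components. Within the eigendecomposition we sort eigenvalues descending
and fix each eigenvector's sign by making its largest-magnitude entry
positive; $\mathbf H$ itself is basis-independent, but this makes the
stored decomposition reproducible across platforms.

## Alternative-hypothesis theory

For the trait model $y = \beta_0 + \sum_j \beta_j \mathrm{SNP}_j +
\epsilon$ with standardized predictors, the mean of the $j$-th marginal
statistic is $\mu_j = \sqrt N\, b_j$ where
$b_j = (\boldsymbol\Sigma_j \boldsymbol\beta) / \sqrt{\boldsymbol
\beta'\boldsymbol\Sigma\boldsymbol\beta + 1} = \mathrm{cor}(y,
\mathrm{SNP}_j)$ (`noncentralityFromEffects()`). For a binary trait
obtained by thresholding a latent liability at $l$, the correlations are
attenuated by $d = \phi(l)/\sqrt{\Phi(l)(1 - \Phi(l))}$
(`binaryAttenuation()`).

Under association, the correlation among statistics is *not*
$\boldsymbol\Sigma$. We implement it as the delta-method (Olkin–Siotani)
covariance of two sample correlations that share the outcome,

$$\mathrm{cov}_{ij} \propto \rho_{ij}(1 - b_i^2 - b_j^2) -
\tfrac{1}{2} b_i b_j (1 - b_i^2 - b_j^2 - \rho_{ij}^2),$$

standardized to unit diagonal (`altStatisticCorrelation()`). It reduces to
$\boldsymbol\Sigma$ exactly at $\boldsymbol\beta = 0$, and for unlinked
SNPs with nonzero effects it induces a correlation with sign opposite to
$b_i b_j$ — the statistics of two independent causal SNPs are negatively
correlated through the shared outcome. The regression simulator
(`simulateRegressionStatistics()`) exists largely to validate these two
results: the test suite checks both against 20,000 simulated marginal
regressions. The MVN law with unit variances is itself a small-$b$
approximation (the marginal $t$-statistic has mean $\approx \sqrt N
b/\sqrt{1-b^2}$), so the validation runs at standardized effects below
0.1, the regime GWAS summary statistics live in; at $|b| \gtrsim 0.3$ the
approximation visibly bends.

Noncentralities: projecting $\boldsymbol\mu$ on the eigenvectors gives the
TQ mixture noncentralities $\gamma_i = (\mathbf E_i'\boldsymbol\mu)^2 /
\lambda_i$, and their total is conserved,
$\sum_i \gamma_i = \gamma_c = \boldsymbol\mu'\mathbf
R^{-1}\boldsymbol\mu$, which is exactly the DOT noncentrality. This
conservation is the crux of the power story: TQ's rejection region weights
the leading mixture component $(1 + (L-1)\rho)\chi^2_{1,\gamma_1}$ so
heavily that only $\gamma_1$ — driven by the *mean* effect — matters,
while DOT spreads $\gamma_c$ over a $\chi^2_L$ and therefore profits from
every unit of noncentrality, including the part generated by
heterogeneity.

For equicorrelated $\mathbf R_\rho = (1-\rho)\mathbf I + \rho\mathbf{11}'$
the Helmert basis gives closed forms (`equicorrNoncentralities()`):
$\delta_1 = L\bar\mu^2 / (1 + (L-1)\rho)$ and, summed over the remaining
components, $\delta_s = (L-1)\bar d / (2(1-\rho))$ with $\bar d$ the mean
squared pairwise difference of the means. As $L$ grows, $\delta_1 \to
\bar\mu^2/\rho$ (TQ's ceiling) while $\delta_s$ grows linearly in $L$
(DOT's gain). The asymptotic TQ power ceiling uses $\gamma^* = \mu^* /
\rho^*$ with $\mu^* = (\overline{|\mu|})^2$ and $\rho^* =
\sqrt{\overline{\rho_{ij}^2}}$, the root-mean-square pairwise correlation;
we adopted the RMS reading because it is the one that makes the ceiling
consistent with the exact mixture computation across the benchmark grid.

The one-degree-of-freedom approximation to TQ (`tqOneDfApprox()`,
`tqPowerApprox()`) treats the non-leading mixture mass as a location
shift: under the null the standardized statistic $(T_Q -
(L-1)(1-\rho^*)) / ((L-1)\rho^* + 1)$ is approximately $\chi^2_1$; under
the alternative the extra shift $(1-\rho^*)\bar d / (2\rho^{*2})$ appears
on the alternative side only, so in the power formula we *lower* the
$\chi^2_1$ threshold by that amount rather than raising it — the common
$(1-\rho^*)/\rho^*$ shift cancels between null and alternative. With
this composition the approximation tracks the exact mixture power to
three decimals across the benchmark grid (the test suite pins both).

## Evaluating the mixture tail

`quadformTail()` computes $\Pr(\sum \lambda_i \chi^2_{df_i,\gamma_i} > t)$
by numerical inversion of the characteristic function (Imhof's integrand).
Numerical choices, in order of importance:

* **Equal weights short-circuit.** If all $\lambda_i$ coincide the mixture
  *is* $\lambda\,\chi^2_{\sum df, \sum\gamma}$ and is evaluated by
  `pchisq()` exactly. This covers identity LD and every reduction test.
* **Fixed-step midpoint rule** (Davies-style) rather than adaptive
  quadrature: the integrand oscillates with frequency $t/2$ over a long
  range, which defeats generic adaptive integrators. The step is
  $\Delta = 2\pi/D$ with $D$ chosen so the aliasing images of the
  distribution sit $\approx 70$ top-eigenvalue units past the far tail
  (aliasing error below the target tolerance).
* **Truncation with an endpoint correction.** The integral beyond the
  truncation point $U$ is approximated by its leading
  integration-by-parts term $\cos\theta(U) / (\theta'(U)\, U \rho(U))$;
  $U$ grows (geometrically) until the next-order bound clears the target
  absolute tolerance, default `absTol = 1e-9`. Monte-Carlo loops pass `absTol` between
  `1e-5` and `1e-6`, which is ample for rejection decisions at
  $\alpha \ge 10^{-3}$ (orders of magnitude below the Monte-Carlo
  resolution) and several times cheaper.
* **Fallback.** If the truncation bound cannot be met (pathologically
  small $t$ with tiny tolerance), the tail is estimated from $10^7$
  Monte-Carlo draws with a warning. None of the shipped analyses hit this
  path.
* The null quantile needed by `tqPower()` is bracketed from the mixture
  mean and found by `uniroot()` to $10^{-9}$.

For equicorrelated matrices the two-distinct-eigenvalue reduction
(grouped `df`) is used automatically; the suite verifies it against the
full L-component mixture.

## Monte-Carlo engine

`estimatePower()` samples statistic vectors directly from
$\mathrm{MVN}(\boldsymbol\mu, \mathbf R)$ — the shortcut the
alternative-hypothesis theory licenses — or, in regression mode, computes
marginal statistics from simulated individual-level data and lets the
tests use that replicate's sample LD (same-data practice). Structure-aware
samplers keep large designs cheap: equicorrelation uses the one-factor
representation, the perturbed matrix $\mathbf B = \mathbf R_\rho +
\mathbf{UU}'$ a two-factor one, so a $10^5 \times 500$ design never
materializes a Cholesky product. All methods see the same simulated
vectors (common random numbers), which is both faster and sharper for
method comparisons. Every path takes an explicit seed and is bitwise
reproducible; seeds are applied without disturbing the caller's RNG
stream.

Defaults and scales: simulations default to $10^5$ replicates
(`nReps`), which resolves power to a Monte-Carlo standard error of about
$0.0013$ at $p = 0.8$ and type-I error at $\alpha = 10^{-3}$ to about
$10^{-4}$; the unit tests run smaller ($10^3$–$2\times10^4$) with
tolerances scaled accordingly, and the acceptance checks run the full
$10^5$. The Laplace noise option is parameterized with scale $1/\sqrt2$
so its variance is exactly 1, making "unit variance noise" literal.

The reference-panel experiment (`referencePanelExperiment()`) redraws, for
every replicate, a surrogate panel estimate of the LD matrix as a Wishart
draw with $N = kL$ degrees of freedom (a Gaussian-genotype surrogate —
first-order equivalent to resampling discrete genotypes for this purpose)
and recomputes all tests with the misspecified matrix. This reproduces the
practical failure mode: DOT's type-I error inflates when the panel is only
a few times larger than the SNP count and resolves (turning conservative)
around $N \approx 100L$, while TQ and ACAT stay near nominal.

## What the synthetic designs emulate — and what they do not

The simulation designs mirror four benchmark regimes: near-homogeneous
effects under equicorrelation (where DOT deliberately underperforms),
rank-one-perturbed LD with 0.14–0.98 pairwise spread, heterogeneous
effects under equicorrelation, and tiny effects redrawn uniformly from
$(-0.15, 0.15)$ each replicate under strongly heterogeneous LD. Random
positive-definite matrices (uniform off-diagonals, eigenvalue-clipped and
restandardized) stress the type-I machinery under arbitrary valid
correlation; the recipe behind such matrices is a free choice, and type-I
conclusions should not depend on it.

What none of this emulates: real LD block structure (the synthetic
matrices are low-rank perturbations or unstructured), allele-frequency
spectra, genotype discreteness, population stratification, or missing
data. A passing suite therefore certifies the distribution theory and the
implementation, not robustness to real-genome idiosyncrasies; the
gene-scan tests use factor-model LD fixtures labelled as synthetic
throughout.

## Gene-scan workflow

`anchorBlock()` collects SNPs with $|r| \ge$ threshold (default 0.25)
around a previously reported risk variant; the absolute value is
deliberate, since the sign of $r$ flips with allele coding.
`geneTest()` applies the chosen methods to the block, converting P-values
to Z-scores via the two-sided $\chi^2_1$ quantile when no Z column exists
(signed conversion is available when effect directions are known, e.g.
from a TDT; whether to carry signs is the caller's decision and both
modes are supported). When both Z and P are present, Z wins and a
consistency check warns on disagreement beyond $10^{-6}$.
`topContributors()` ranks decorrelated components by $X_i^2$ (ties broken
by lower component index), decomposes each into per-SNP terms
$h_{ij}Z_j$, and flags as "selected" the terms sharing the component's
sign with magnitude at least 25% of the largest such term — a reportable,
configurable stand-in for the judgement call of reading large weights off
a linear combination.

Degenerate inputs: blocks whose restricted LD is singular (e.g. from an
undersized panel) error with a pointer to `nearestPDCorrelation()`; a
monomorphic SNP in a haplotype table errors; missing genotypes error
rather than being imputed, because LD estimated on incomplete dosages no
longer matches the correlation of the statistics — imputation belongs
upstream.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `threshold` | `anchorBlock` | 0.25 | conventional moderate-LD cut for anchor blocks |
| `absTol` | `quadformTail` | 1e-9 | absolute tail accuracy; 1e-5 to 1e-6 inside MC loops |
| `floorRel` | `nearestPDCorrelation` | 1e-8 | eigenvalue clipping floor (fraction of largest) |
| PD acceptance | transforms/power | 1e-10 | smallest/largest eigenvalue ratio below this is treated as singular |
| `termFraction` | `topContributors` | 0.25 | contributor selection cutoff within a component |
| `nNull` | `rtpTest` | 1e4 (min) | simulated null size; P-values use the add-one correction $(r+1)/(n+1)$ |
| `nReps` | simulation engine | 1e5 | MC SE ≈ 0.0013 at p = 0.8 |
| `k` | `referencePanelExperiment` | — | panel size multiplier, N = kL; ≥ 50–100 needed for DOT |

## Known limitations

* DOT requires the LD matrix and the summary statistics to come from the
  same sample; with external-panel LD its type-I error is unreliable
  unless the panel is 50–100 times larger than the block. TQ and ACAT are
  the robust choices in that situation.
* Prioritized contributor SNPs are statistical, not causal: a large
  weight can sit on a proxy in high LD with the causal variant.
* ACAT's null is computed under independence; under strong LD its size at
  $\alpha = 0.05$ can drift to roughly 0.07, improving as $\alpha$
  shrinks.
* The equicorrelation closed forms are benchmarks, not biology; they are
  kept because they make the power mechanics transparent and exactly
  checkable.
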