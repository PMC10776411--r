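---
title: "Bias-corrected differential abundance analysis: models and methods"
author: "BCDA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-corrected differential abundance analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BCDA)
```

## The problem

Sequencing counts measure a microbial ecosystem through two multiplicative
distortions. Each specimen captures an unknown *sampling fraction* of the
ecosystem (library size, extraction yield), and each taxon is read with an
unknown *sequencing efficiency* (for example, gram-positive cell walls
resist extraction). Writing the observed count of taxon $j$ in sample $i$ as

$$O_{ij} = S_i \, C_j \, A_{ij} \, E_{ij},$$

with $A_{ij}$ the absolute abundance, $S_i$ the sampling fraction, $C_j$
the efficiency and $E_{ij}$ multiplicative noise, a log transform turns the
nuisances into additive offsets. Differential abundance (DA) analysis asks
how $A_{ij}$ varies with covariates; any method that ignores $S_i$ or $C_j$
confounds biology with measurement.

## The model and the two-stage bias removal

For positive counts, $o_{ij} = \log O_{ij}$ follows the offset log-linear
model $o_{ij} = s_i + c_j + \mathbf{b}_j^\top \mathbf{x}_i + e_{ij}$ with
independent, heteroskedastic errors. BCDA removes the two offsets in two
exact or asymptotically exact steps:

1. **Efficiency:** centering each taxon's log counts around its own
   observed mean eliminates $c_j$ exactly (`centerLogCounts()`). The
   centered response is $y_{ij} = \theta_i + \beta_j^\top x_i +
   \epsilon_{ij}$, where $\theta_i$ is the centered log sampling fraction.
2. **Sampling fraction:** $\theta$ and the $\beta_j$ are obtained by
   alternating the per-sample update $\theta \leftarrow
   \tfrac1d \sum_j (y_j - X\beta_j)$ with per-taxon least squares of
   $y_j - \theta$ on the design (`iterativeEstimation()`).

The fixed point identifies $\theta$ only up to a component in the design
space: the preliminary coefficients $\beta_j^*$ all carry the same additive
bias $\delta$. Pooling across taxa, each covariate's coefficients are
modeled as a three-component Gaussian mixture — a null component centered
at $\delta_k$ with per-taxon spread equal to the coefficient's standard
error, and down-/up-regulated components at $\delta_k + l_1$ ($l_1 < 0$)
and $\delta_k + l_2$ ($l_2 > 0$) with inflated spreads
$\nu_{j0} + \kappa_1$ and $\nu_{j0} + \kappa_2$. The EM estimate of the
null-component location is the bias (`emBiasCorrection()`), subtracted from
every taxon's coefficient (never from the intercept, which estimates
$\mathbf{b}_j^\top\bar{\mathbf{x}}$ rather than a fold change). Per-taxon
covariances are heteroskedasticity-consistent sandwich estimates
(`estimateSigma()`); the uncertainty of the bias estimate itself is ignored,
which is justified when many taxa are null.

Numerical notes, all deliberate choices:

* The mixture component spreads are *additive on the SD scale*
  ($\nu_{j1} = \nu_{j0} + \kappa_1$), taken literally from the model
  statement. The E-step uses properly normalised normal densities.
* The M-step is an ECM: $\pi$, $\delta$, $l_1$, $l_2$ have closed-form
  weighted updates ($l_1, l_2$ clipped to their sign constraints), while
  $\kappa_1, \kappa_2$ are each maximised by a one-dimensional search.
  Initialisation: $\delta$ at the median coefficient,
  $\pi = (0.75, 0.125, 0.125)$, $l_1/l_2$ at the 10th/90th centered
  percentiles, $\kappa = 1$. Convergence is declared when the
  log-likelihood moves by less than `tol` (default `1e-5`); on difficult
  data the `MixtureFit` may report `converged = FALSE` at the iteration cap
  while the location estimate has long plateaued — the estimate is still
  usable, and the flag is informational.
* The sampling-fraction iteration stops when
  $\max_i |\Delta\theta_i| <$ `tol` (default `1e-5`, cap 100 iterations).
  In the mixed-effects variant the update is additionally constrained
  orthogonal to the design space: GLS residuals are oblique to it, so the
  raw update would accumulate an unidentifiable design-space component
  (exactly the $\delta$-bias the EM step estimates); the constraint pins one
  fixed point without changing any bias-corrected quantity.
* Rank-deficient designs fall back to pseudo-inverses; taxa whose observed
  rows cannot support the design (too few positive samples, or a group
  never observed) are excluded with a warning.

## Zeros

Zeros are handled in three stages (`assessZeros()`, `sensitivityAnalysis()`):

1. **Structural zeros** (opt-in, `structZero = TRUE`): a taxon absent from
   an entire group is declared DA by presence/absence alone and excluded
   from modeling. The default rule is "every count zero in the group"; a
   normal-approximation lower confidence bound on the presence proportion
   (nominal coverage configurable, default 0.95) is available behind
   `structZeroAsymptotic`. This stage is off by default: in modest group
   sizes, rare null taxa are routinely all-zero in one group by chance, and
   auto-declaring them DA is not a defensible default.
2. **Prevalence filter:** taxa present in fewer than `prvCut` (default
   10%) of samples are removed; the boundary is inclusive.
3. **Pseudo-count sensitivity analysis** (the *SS filter*): the complete-data
   fit treats zeros as missing. For every pseudo-count $c \in \{0.01,
   0.02, \ldots, 0.50\}$ the zeros are replaced by $c$, the full fit is
   re-run on all samples, and the per-taxon p-value recorded. The
   sensitivity score is the fraction of grid runs with $p > \alpha$. A
   taxon is insensitive only when the grid verdict is unanimous (score
   exactly 0 or 1) and agrees with the complete-data verdict; sensitive
   taxa are declared non-significant under the SS-filter variant. In
   multigroup and pattern modes the score is computed on the taxon-level
   screening p-value (one score per taxon); in plain covariate mode, per
   covariate. Grid runs reuse the main fit's Monte-Carlo seeds, and in the
   mixed model they hold the variance components at their complete-data
   estimates, so score differences reflect pseudo-counts only.

The two method variants are one switch: `ssFilter = TRUE` (conservative,
recommended for large samples and repeated measures) adds stage 3;
`ssFilter = FALSE` is the more powerful unfiltered variant.

## Testing

Per-covariate tests are Wald z statistics on the bias-corrected
coefficients. Following the moderated-statistics tradition, the denominator
is regularized additively: $z = \hat\beta_{jk}/(\mathrm{se}_{jk} + s_0)$
with $s_0$ the 5th percentile of that covariate's standard errors across
taxa, guarding against spurious significance from unrealistically small
standard errors. The regularization applies to the scalar z statistics
(covariate tests, pairwise and Dunnett comparisons); the global chi-square
screen and the pattern-analysis variances use the plain covariance. Holm
adjustment is the default (robust to arbitrary p-value dependence); BH is
available.

For $g + 1$ groups:

* **Global test:** chi-square statistic with the identity contrast on the
  $g$ group coefficients.
* **All pairwise comparisons / reference-only (Dunnett-type):** z statistics
  whose denominators combine the two coefficients' variances (no covariance
  term). mdFDR — the expected proportion of taxa with any type-I *or*
  directional error among discoveries — is controlled by the three-step
  procedure: BH on the screening p-values at level $\alpha$ ($R$
  discoveries), a familywise procedure (Holm default, Hochberg optional)
  within each discovered taxon at level $R\alpha/d$, and sign assignment
  from the pairwise statistic. In reference-only mode the screen is a
  Monte-Carlo Dunnett-type test of $\max_k |W_k|$ whose null draws are
  independent standard normals per coordinate, exactly as specified —
  a fidelity choice, although the observed statistics are correlated.
* **Pattern (trend) analysis:** a hypothesised trend over ordered groups is
  a polyhedral cone, e.g. $0 \le \beta_1 \le \cdots \le \beta_g$ (simple
  order), $\beta_k \ge 0$ (tree), or an umbrella with a peak. The group
  effects are projected onto the closed cone in the Mahalanobis metric of
  their covariance; "at least one strict inequality" defines the
  alternative, not the feasible set, so projections land in the closed cone
  and a zero statistic simply never rejects. The statistic is the
  largest difference between constrained estimates of *linked* parameters
  (pairs whose order the pattern specifies, including the reference where
  the cone bounds coefficients away from 0), maximised over the candidate
  patterns (default: simple increasing and simple decreasing). Its null
  distribution is simulated by drawing the group effects coordinate-wise
  from centered normals with the estimated variances and scoring each draw
  identically. The projection is solved through the dual as non-negative
  least squares; simple orders with diagonal covariance take a weighted
  isotonic-regression (pool-adjacent-violators) fast path, and the
  two-group case uses a closed-form case analysis over the cone faces,
  which makes the bootstrap effectively vectorised.

## Repeated measures

With repeated observations per subject the per-taxon model gains a subject
random intercept (optionally plus a random slope in a continuous variable,
unstructured covariance). Coefficients and variance components are
estimated by ReML — the variance ratio is profiled out on the log scale,
which reduces the random-intercept case to a one-dimensional search with
closed-form GLS at each candidate — inside the same sampling-fraction
iteration; the per-taxon covariance becomes the GLS covariance
$(X^\top H_j^{-1} X)^{-1}$. Variance components are estimated in the first
sweep and re-estimated once after the sampling-fraction iteration
converges; intermediate sweeps hold them fixed, since the
sampling-fraction shift moves the response by per-observation constants
and leaves variance ratios essentially unchanged. Wald tests keep the
asymptotic normal/chi-square reference (no small-sample degrees-of-freedom
correction). Sampling fractions are estimated per observation: each
repeated specimen is sequenced separately and has its own fraction.
Downstream inference — EM bias correction, global/pairwise/mdFDR/pattern
machinery — is identical to the fixed-effects path.

## The synthetic-data generator

`simulatePLN()` draws log absolute abundances from a multivariate normal
(Poisson log-normal counts): per sample,
$\log A_{\cdot i} \sim N(\mu + \beta x_i \,[+\, \text{subject effects}],
\Sigma)$, and $O_{ij} \sim \text{Poisson}(S_i C_j A_{ij})$. Defaults, chosen
once as study conditions:

* $\mu$: an evenly spaced ladder on $[-2, 7.5]$, covering rare taxa (high
  zero fraction, exercising the zero machinery) through dominant ones. At
  $d = 200$, $n = 30$ this yields roughly 15–25% zeros overall.
* $\Sigma$: rank-2 factor loadings $N(0, \sqrt{0.2})$ plus a diagonal
  $\mathrm{Uniform}(0.3, 1)$ — correlated taxa with log-scale SDs around 1,
  typical of OTU-level data.
* $\log S_i \sim \mathrm{Uniform}(-1, 1)$ and
  $\log C_j \sim N(0, 0.5^2)$: both bias sources are always present, so a
  method that ignores them fails visibly.
* DA taxa are drawn uniformly; effects are uniform magnitudes in
  $[0.5, 2]$ with directions split evenly up/down, or the ordered design
  ($\delta$ for group 2, $\delta + 1$ for group 3) for trend studies.
  An optional continuous covariate affects a random 10% of taxa. Subject
  random intercepts/slopes are drawn per taxon per subject (a shared
  per-subject shift would be indistinguishable from a sampling fraction).

What the generator does *not* emulate: taxonomic correlation structure
beyond the low-rank factor, zero inflation beyond what PLN sparsity
produces, compositional saturation at extreme depths, and real-data feature
distributions (the `empiricalParams()` helper can substitute mean/covariance
estimated from any count table). Passing the simulation benchmarks therefore
shows correct behavior under a *fair* generative model that is not the
method's own, not performance guarantees on arbitrary real data.

## Benchmarks and problem sizes

`runBenchmark()` reproduces the package's reference studies at the
following sizes, chosen so the full suite runs comfortably on a laptop:
continuous/binary FDR at $d = 200$, $n = 30$ (per group), 10% DA, 50
replicates; all-pairwise mdFDR with three groups and a continuous covariate
at $n = 30$ per group, 50 replicates; ordered-trend power at 20% DA,
$n = 50$ per group, 500 bootstrap draws, 30 replicates; random-intercept
mdFDR at 30 subjects per group, two observations each, 30 replicates.
Replicate seeds are derived from the master seed with a fixed stride of
1000. Under these conditions the SS-filtered variant holds FDR/mdFDR at or
below the nominal 0.05 within Monte-Carlo error and the trend analysis
detects monotone patterns with high power; the exact numbers are computed,
not quoted, by `scripts/acceptance.R` and the acceptance test suite.

## Known limitations

* The complete-data policy (zeros as missing) attenuates large effects in
  rare taxa: conditioning on positivity truncates the lower tail of the
  suppressed condition. This costs power on rare taxa (the SS filter
  demotes many of them) but does not inflate the false discovery rate.
* Bias correction presumes a sufficient pool of null taxa per covariate
  (at least 10, realistically dozens); with a majority of DA taxa the
  mixture location drifts and power degrades.
* The mdFDR step-2 level $R\alpha/d$ is strict when few taxa are
  discovered; with small panels the pairwise stage can be conservative.
* Only one grouping factor with a random intercept or intercept+slope is
  supported; no crossed random effects or serial correlation.
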