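---
title: "Optimally weighted permutation tests for gene-environment interaction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimally weighted permutation tests for gene-environment interaction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(towge)
library(dplyr)
```

# The problem

Sequencing association studies routinely test whether the variants in a
region (a gene, exon set, or pathway) modify the effect of an environmental
exposure on a trait — a gene-environment (GE) interaction. For common
variants this is a standard product-term regression. For rare variants
(sample minor allele frequency, MAF, below 0.05) the per-variant interaction
terms are individually uninformative, and tests must aggregate them across
the region. Aggregation immediately raises two design questions:

* **Direction.** Burden-style tests that sum interaction terms before
  testing are powerful when all causal effects point the same way and can
  lose essentially all power when risk and protective interactions mix.
* **Rare vs common.** A weighting scheme tuned to up-weight rare variants
  will down-weight a genuinely causal common-variant interaction, and vice
  versa.

`towge` implements a pair of permutation score tests built around an
analytically optimal data-adaptive weighting — TOW-GE for rare-variant
interactions and its variable-weight extension VW-TOW-GE for regions where
both rare and common interactions may matter — together with modified
weighted-sum (WSS) and collapsing (CMC) burden comparators and the
simulation harness used to calibrate all of them.

# Model and residualization

For individual $i$ with trait $y_i$, covariates $X_i$ (length $q$),
environment $E_i$, and region dosages $G_i = (g_{i1},\dots,g_{im})$, the
working generalized linear model is

$$ g\!\left(\mathrm{E}\,[y_i]\right) = X_i^T\alpha_1 + E_i\,\alpha_2 +
   G_i^T\alpha_3 + S_i^T\beta, \qquad
   S_i = (E_i g_{i1},\dots,E_i g_{im})^T ,$$

and the null hypothesis of no GE interaction is $\beta = 0$. All main
effects — covariates, environment, and every variant's dosage — are nuisance
terms. `residualize()` projects the trait and every interaction column onto
the orthogonal complement of the design $\tilde X = [1, X, E, G]$ by least
squares, yielding $\tilde y_i$ and $\tilde S_i$; testing $\beta = 0$ then
reduces to testing association between $\tilde y$ and $\tilde S$.

Numerical choices worth knowing:

* Residuals come from a pivoted QR factorization. With many rare variants
  the $G$ block is often numerically rank deficient; residuals are the
  projection onto the complement of the design's column space and are
  identical for every least-squares solution, so no column pruning or
  regularization is needed (or performed).
* An interaction column that is itself (numerically) a linear combination of
  design columns has a residual of zero; such columns are dropped with a
  warning when their residual variance falls below
  $10^{-12}\max(1,\mathrm{var(raw)})$, and the drop is reported in every
  downstream result.
* A binary trait is residualized by the same linear projection by default.
  This is deliberate: the inference below is permutation-based, so validity
  does not rest on the Gaussian linear model, only on exchangeability of the
  residualized trait under the null. Pearson residuals from a logistic fit
  are available via `binary_link = "logistic"` for users who prefer the
  GLM-scale residual; the default keeps the quantitative and binary paths
  identical.

# The TOW-GE statistic

For a weighted combination $\tilde s_i = \sum_j w_j \tilde s_{ij}$ the score
statistic is

$$ S(w) = \frac{n\left(\sum_i (\tilde y_i - \bar{\tilde y})
  (\tilde s_i - \bar{\tilde s})\right)^2}
  {\sum_i (\tilde y_i - \bar{\tilde y})^2 \sum_i (\tilde s_i - \bar{\tilde s})^2}. $$

Rare-variant interaction columns are close to mutually orthogonal (two rare
variants rarely co-occur in one carrier), so the variance of the combination
is approximately diagonal, $\sum_j w_j^2 V_j$ with
$V_j = \sum_i (\tilde s_{ij} - \bar{\tilde s}_j)^2$. Under that
approximation $S(w)$ is maximized in closed form at

$$ w_j^0 = U_j / V_j, \qquad
   U_j = \sum_i (\tilde y_i - \bar{\tilde y})(\tilde s_{ij} - \bar{\tilde s}_j), $$

a weight that is signed by the trait-interaction association (hence robust
to mixed effect directions) and inversely proportional to the column's
variation (hence up-weighting rare variants). The reported statistic drops
the permutation-constant factor $\sum_i (\tilde y_i - \bar{\tilde y})^2$:

$$ T = \sum_i (\tilde y_i - \bar{\tilde y})(\tilde s_i^0 - \bar{\tilde s}^0)
     = \sum_j U_j^2 / V_j \;\ge\; 0 .$$

The algebraic identity on the right is both an implementation shortcut and a
test oracle: the suite checks it to $10^{-10}$ on random fixtures, along
with invariance to rescaling any interaction column (the optimal weight
absorbs the scale) and a brute-force grid search confirming no weight
direction beats $w^0$ on the diagonal objective.

$T$ has no usable closed-form null distribution (the weights are estimated
from the same data), so p-values are by permutation: the residualized trait
is shuffled, the weights are re-estimated inside every permutation, and

$$ p = \frac{1 + \#\{b : T^{(b)} \ge T^{(0)}\}}{B + 1} $$

under the default add-one convention, which guarantees a valid test with
$p \ge 1/(B+1)$. The raw convention $\#\{T^{(b)} > T^{(0)}\}/B$ — which can
return an unusable 0 — is available behind `convention = "raw"` for exact
agreement with the printed formulas of the source method. Because the
interaction columns are fixed under permutation, the engine computes the
per-column cross-products for all shuffles as one matrix product, making a
500-permutation test on $n = 2000$ a few milliseconds.

A practical note on the permutation target: the trait is residualized once
and its residuals are shuffled. Re-residualizing the raw trait inside every
permutation would cost $B$ extra regressions and produce the same null
ensemble, since the interaction residuals are orthogonal to the design
either way.

# VW-TOW-GE: combining rare and common sides

TOW-GE's $1/V_j$ weighting deliberately down-weights common-variant
interactions. When both rare and common interactions may be causal, the
variable-weight test splits the columns at the MAF threshold, computes
TOW-GE statistics $T_r$ and $T_c$ on the two sides, and scans the mixtures

$$ T_\lambda = \lambda \frac{T_r}{\mathrm{var}(T_r)} +
   (1-\lambda) \frac{T_c}{\mathrm{var}(T_c)}, \qquad
   \lambda_k = k/K,\; k = 0,\dots,K, $$

taking as its statistic the minimum over the grid of the p-values
$p_{\lambda_k}$. Minimizing over $\lambda$ would inflate type-I error if
calibrated naively, so the whole min-p construction is repeated inside the
permutation ensemble: one shared permutation stream yields
$(T_r^{(b)}, T_c^{(b)})$ jointly for $b = 0,\dots,B$ (preserving the
dependence between the two sides — the suite contains a regression test
proving independent streams change the answer), each $T_{\lambda_k}^{(b)}$
is rank-transformed against the full ensemble with strict `>`, the minimum
over $k$ gives $p^{(b)}$, and the final p-value compares $p^{(0)}$ against
the permuted minima.

Design choices:

* **Grid size `K = 10`.** The grid only has to locate the best mixing
  weight to within the resolution that the $B$-permutation rank transform
  can distinguish; a $\lambda$ resolution of 0.1 is ample, and because the
  side ensembles are reused across $k$ the marginal cost of a finer grid is
  negligible. The observed minimum cannot increase under grid refinement
  (tested).
* **Ensemble variances include $b = 0$**, so the observed data contribute
  one degree of freedom to the standardization; with $B \ge 100$ this is
  numerically irrelevant but keeps the transformation exactly symmetric in
  $b$.
* **Final comparison.** The raw convention uses strict `<` over all
  $b = 0..B$ as printed; the default add-one analogue uses `<=` on
  $b \ge 1$, the conservative direction for ties (min-p ensembles are
  heavily tied because the rank transform is discrete).
* `lambda_star`, the observed argmin, is reported for interpretation only —
  a value near 1 says the rare side carried the signal — and has no
  inferential status.
* If either side of the split is empty the test refuses and directs the
  user to plain TOW-GE; `ge_region_test(methods = "vw")` performs that
  fallback automatically with a warning.

# The modified burden comparators

The comparison tests keep the classical aggregation rules but evaluate them
as permutation score tests on the residualized data; their exact statistics
are this package's reconstructions (documented as such), since the classical
forms — a case/control rank-sum for WSS, a Hotelling $T^2$ for CMC — do not
apply to residualized interaction columns.

* **WSS-GE** collapses with Madsen-Browning weights,
  $\tilde s^W_i = \sum_j \tilde s_{ij} / \sqrt{n q_j (1-q_j)}$, using
  whole-sample MAF $q_j$ (there is no case/control split for a quantitative
  trait), and tests the squared signed score
  $(\sum_i (\tilde y_i - \bar{\tilde y}) \tilde s^W_i)^2$. Summing before
  squaring makes it direction-sensitive by construction; the suite contains
  a fixture where two strong opposite-sign interactions cancel the WSS
  statistic while TOW-GE detects them.
* **CMC-GE** collapses rare interactions to the single column
  $E_i \cdot 1\{\text{any rare minor allele}\}$ (indicator collapse, per the
  original CMC), residualizes it against the same design as every other
  interaction column, keeps common-variant interaction columns as-is, and
  tests the multivariate score $U^T V^{-1} U$ with
  $V = (\sum_i \tilde y_i^2 / n)\, C^T C$ for the centered column matrix
  $C$. $V$ is permutation-invariant, so any such normalization yields a
  valid permutation test; the choice above makes the one-column case reduce
  exactly to the standardized squared score. A singular $V$ falls back to
  the Moore-Penrose pseudo-inverse with a warning.

# What the synthetic generator emulates — and what it does not

The generator reproduces the simulation design used to calibrate the
methods, which in turn emulates a 10-variant gene panel (8 rare, 2 common) of
the kind found in mini-exome reference data:

* Dosages are independent $\mathrm{Binomial}(2, \mathrm{MAF}_j)$ draws.
  Default panel MAFs are drawn once per scenario: 8 rare from
  $\mathrm{U}(0.001, 0.05)$, 2 common from $\mathrm{U}(0.05, 0.5)$ — the
  empirical panel's MAFs are not published, so the scenario seed fixes a
  concrete panel in the stated ranges.
* The trait is
  $y = 0.5 x_1 + 0.5 x_2 + 0.015\,E + G^T\alpha_2 + S^T\beta + \epsilon$,
  with $x_1, E, \epsilon \sim N(0,1)$, $x_2 \sim \mathrm{Bernoulli}(0.5)$,
  $\sigma^2_\epsilon = 1$. With main effects present, rare variants get
  $|\alpha_{2j}| = 0.3$ with signs drawn randomly each replicate; the
  environment coefficient 0.015 makes the exposure a realistic but weak
  main effect.
* Alternatives set `causal_count` rare interaction coefficients to $\pm c$
  (a stated fraction positive; the causal subset is drawn once per scenario
  since the original design does not say which rare variants carry effects)
  and optionally one common interaction coefficient to $+2c$.

Deliberate simplifications, hence limits on what passing calibration shows:
dosages are independent across variants (no linkage disequilibrium,
whereas real exome panels carry LD), MAFs
are exact population parameters rather than an empirical site-frequency
spectrum, the environment is independent of genotype (no gene-environment
correlation), and the trait model is exactly linear and homoscedastic.
Calibration under this generator demonstrates the permutation machinery and
the adjustment for main effects; it does not certify behaviour under LD,
population structure, or exposure-genotype dependence.

# Monte-Carlo sizes

The experiment harness reports the empirical rejection rate $r$ with its
Monte-Carlo standard error $\sqrt{r(1-r)/\text{replicates}}$, and
`binomial_ci()` gives the matching nominal-level band (at 10,000 replicates,
$0.05 \pm 1.96\sqrt{0.05 \cdot 0.95/10^4} = (0.046, 0.054)$).

The package's own calibration runs — the acceptance script and test suite —
use 500 replicates of 500 permutations for type-I error and 300 replicates
for the power-ordering checks: at 500 replicates the MCSE of a rate near
0.05 is about 0.01, which separates a calibrated test from a broken one
(a naive min-p over $\lambda$ without the nested transform roughly doubles
the rate) while keeping a full run in minutes. The reference-scale study
(10,000 replicates for type-I error; 1,000 replicates of 10,000 permutations
for power curves) is reachable by setting `replicates` and `B` in
`ge_scenario()`; nothing else changes.

```{r type1, eval = FALSE}
# the with-main-effects rare-variant calibration cell, reference scale
scen <- ge_scenario(n = 2000, include_main = TRUE,
                    replicates = 10000, B = 10000, seed = 1)
run_type1_experiment(scen, methods = c("tow", "wss"), scope = "rare")
```

A desk-scale example, small enough to run while reading:

```{r small}
scen <- ge_scenario(n = 300, replicates = 50, B = 200, seed = 9)
ex <- run_type1_experiment(scen, methods = c("tow", "wss"), scope = "rare")
tidy(ex) |> filter(alpha == 0.05)
```

# Known limitations

* Only one environmental exposure is supported; the score construction
  extends to several in principle, but no multi-exposure form is
  implemented.
* No analytic p-values: the optimal weights make the statistic's null law
  data-dependent, so every p-value costs $B$ permutations. The `step_up`
  option of `ge_region_test()` (escalate to $10B$ when the first-pass
  $p < 0.1$) is this package's convenience heuristic for screening many
  regions, not part of the calibrated procedure.
* The CMC normalization with several collapsed columns is one of several
  permutation-valid choices; power (not validity) could differ under
  another convention.
* Kinship/mixed-model adjustment and imputation to a reference panel are
  out of scope; individuals are assumed unrelated and genotypes called.
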