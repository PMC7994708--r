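---
title: "Estimating cross-sectional and temporal symptom networks from short ordinal panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cross-sectional and temporal symptom networks from short ordinal panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

# The problem

Clinician-rated symptom scales such as the Young Mania Rating Scale (YMRS)
produce short ordinal panels: a handful of measurement waves, around a
hundred subjects, and a dozen items scored 0--4. The network approach to
psychopathology treats such items as mutually interacting components rather
than interchangeable indicators of a latent disease, and asks three
questions this package operationalizes:

1. **Which symptoms are conditionally associated at a given moment?**
   Answered by a Gaussian graphical model (GGM) per wave: an undirected
   network whose edge weights are partial correlations.
2. **Does overall connectivity change between occasions?** Answered by a
   permutation Network Comparison Test (NCT) on *global strength*, the sum
   of absolute edge weights.
3. **Which symptoms predict which over time?** Answered by a panel
   graphical vector autoregression (GVAR), whose lag-1 coefficient matrix
   has a Granger-causal reading: a nonzero entry means one symptom's past
   improves the prediction of another's present beyond everything else's
   past.

Because clinical panels of this kind are rarely public, the package ships a
synthetic generator with *known* network structure, so every estimator can
be validated end-to-end by parameter recovery rather than by eyeballing.

# Cross-sectional networks

## Model

For standardized scores with correlation matrix $C$, the GGM edge weight
between items $i$ and $j$ is

$$ w_{ij} \;=\; -\,\frac{K_{ij}}{\sqrt{K_{ii}K_{jj}}},\qquad K = C^{-1}, $$

the partial correlation given all remaining items. The default estimator is
**nonregularized**: invert the correlation matrix and report every partial
correlation. Regularization is deliberately not the default for
low-dimensional clinical scales (11 nodes, $n \approx 100$), where the
saturated estimate is stable and shrinkage mainly biases edge weights; an
optional Fisher-z screen (`ggm_edge_test()`, off by default, $\alpha=0.05$,
no multiplicity correction unless Holm is requested) marks edges a reader
may treat as noise.

Ordinal 0--4 scores with treatment-driven floor effects are skewed, so the
default correlation input is **Spearman's rank correlation** (average ranks
for ties); Pearson input is available where a comparison with
regularized-network conventions is wanted. Rank-based matrices can be
indefinite in small samples: before any inversion the matrix is repaired by
eigenvalue clipping at $10^{-8}$ followed by rescaling to unit diagonal,
and the `repaired` flag is carried into the network metadata. The clipping
floor only needs to clear numerical noise; results are insensitive to it
over several orders of magnitude.

## EBIC graphical lasso

`ebic_glasso()` provides the regularized alternative: $\ell_1$-penalized
precision estimation (graphical lasso, block coordinate descent implemented
in compiled code, diagonal unpenalized) over a 100-point log-spaced penalty
grid from $\lambda_{\max}$ (the largest absolute off-diagonal correlation,
where the network is empty) down to $\lambda_{\max}/100$, selecting by

$$\mathrm{EBIC}_\gamma = -2\,\ell(\hat\Theta) + E\log n + 4\gamma E\log p,$$

with $E$ the number of nonzero upper-triangle precision entries,
$\ell$ the Gaussian profile log-likelihood against the sample correlation,
and $\gamma = 0.5$, the literature's default. Two properties pin the
implementation down and are asserted in the test suite: the fit at
$\lambda \ge \lambda_{\max}$ is exactly empty, and the fit as
$\lambda \to 0$ reproduces the unregularized partial correlations to
$10^{-4}$.

Two behaviors of EBIC selection are worth knowing. First, at $n = 2000$ it
recovers sparse supports well but admits occasional small false-positive
edges; single-dataset support F1 is therefore itself a random variable, and
the package's recovery benchmark reports F1 *averaged over independent
panels* (an 11-node ring of partial correlations 0.15, ten replicates),
where the expected value is about 0.93. Second, at $n = 100$ with the
modest, discretization-attenuated correlations typical of ordinal clinical
data, the EBIC minimum can be the *empty* model — $\gamma = 0.5$ is
conservative at this sample size. That is the method's honest answer, not a
failure mode, but it matters for the NCT default below.

## Node predictability

`node_predictability()` reports, per node, the proportion of variance
explained by all other nodes: under a Gaussian working model on
standardized variables $R^2_j = 1 - 1/K_{jj}$, identical to the OLS
$R^2$ of node $j$ on the rest (asserted to $10^{-8}$ against a brute-force
regression oracle). Mixed-graphical-model implementations used in the
applied literature estimate the same quantity through regularized
node-specific regressions and can return exact zeros for weakly connected
nodes; the Gaussian $R^2$ here is small-but-positive instead, so published
mixed-model tables are comparable only qualitatively.

# Comparing networks: the permutation NCT

`nct_global_strength()` tests $H_0$: equal global strength, with the
observed statistic $|S_1 - S_2|$ and a permutation null:

* **paired** (the default when the two samples carry the same subject ids
  — the honest null for two waves of one cohort): each subject's two wave
  vectors are swapped independently with probability 1/2;
* **unpaired**: all rows are pooled and re-split at the original sizes.

The p-value is +1-corrected, $p = (1 + \#\{T^\pi \ge T\})/(1 + B)$, never
exactly zero, and bit-reproducible given the seed.

**Standardization before permutation.** The strength statistic is
location- and scale-invariant, but the permutation scheme is not: swapping
*raw* wave vectors when wave means differ (the defining feature of treated
acute mania — high admission scores, low discharge scores) mixes two
shifted distributions, inflates every permuted correlation, and drives the
test toward $p = 1$ regardless of the networks. Each sample's columns are
therefore standardized before permuting; the observed statistic is
unchanged and exchangeability under the equal-network null is restored.
Calibration is verified by simulation in the acceptance suite: 400
replicates of an exchangeable-waves null ($n = 100$, 11 variables, 250
permutations) give an empirical type-I error within $[0.03, 0.08]$ at
$\alpha = 0.05$, and doubling all partial correlations at $n = 300$ is
rejected in well over half of replicates.

The default internal estimator mirrors the convention of regularized
Pearson networks inside published comparison tests; it can and often should
be switched to the package's main nonregularized Spearman estimator
(`estimator = estimator_config("nonregularized", "spearman")`), because
with $n \approx 100$ ordinal waves the EBIC-selected networks on both sides
can be empty (see above), in which case the regularized test is maximally
conservative ($p = 1$). The calibration simulations use the nonregularized
internal estimator: the permutation construction, not the network
estimator, is what calibration validates, and any location/scale-invariant
statistic inherits it.

# Stability and accuracy

`edge_ci_bootstrap()` resamples subjects with replacement and reports
2.5%/97.5% quantiles per edge; failed resamples (e.g. a zero-variance
column) are redrawn and counted. `case_drop_stability()` subsamples without
replacement at drop proportions $0.05, 0.10, \dots, 0.75$, re-estimates
strength centrality, and correlates it (Spearman, robust to ties across 11
nodes) with the full-sample strength. The **CS-coefficient** is the largest
drop proportion at which that correlation is $\ge 0.7$ in $\ge 95\%$ of
resamples, required monotonically from the smallest drop up; values outside
the grid are reported as `"<0.05"` or `">0.75"`. The 0.7/0.95 thresholds
follow the established subsampling guidelines for psychological networks.

One subtlety the test suite documents: at a 5% drop the subsample shares
95% of its rows with the full sample, so *any* estimator — including one
applied to pure noise — shows correlated strength vectors through shared
sampling error. With the saturated estimator, white noise therefore gives
erratic, sometimes high, stability proportions. The stability benchmark
accordingly runs under the EBIC-glasso estimator (the convention of the
guidelines the procedure follows): on white noise the selected networks are
empty, strength vectors carry no ordering, and CS is robustly `<0.05`,
while a strong 11-node structure at $n = 2000$ yields CS at the top of the
grid.

# The temporal network

`estimate_panel_gvar()` stacks all consecutive wave transitions
($t_0\to t_1$, $t_1\to t_2$) and fits one multivariate least-squares
regression of wave-$t$ scores on wave-$(t-1)$ scores:

$$ y_t = \mu + B\,y_{t-1} + \varepsilon_t,\qquad
   \hat\Sigma = \widehat{\mathrm{Cov}}(\varepsilon), $$

with $B[j,k]$ the effect of symptom $k$'s past on symptom $j$'s present
(exports label direction explicitly as `from`/`to`). The contemporaneous
residual network is the partial-correlation matrix of $\hat\Sigma$.
`check_stationarity()` reports the spectral radius of $\hat B$;
`temporal_edge_test()` gives per-coefficient Wald tests from the
least-squares standard errors (df $= N - p - 1$; Holm optional).

This pooled estimator was chosen over latent-variable ML panel estimators
deliberately: it is closed-form, desk-scale, and exactly the
"multivariate regression on the previous occasion" reading of a temporal
network; it does not decompose within- from between-person structure. The
consequences are explicit and tested:

* With stable person effects present and no centering, pooled
  autoregression is biased upward (person effects masquerade as
  persistence). `centering = "subject_mean"` removes them, but with only
  three waves the within transformation over-corrects (Nickell-type bias
  downward). Both directions are demonstrated in the test suite; the
  default is `centering = "none"` with the option exposed.
* Pooling transitions assumes stationary means; on mean-declining panels
  the shared intercept absorbs an average of two different wave intercepts
  and $B$ picks up an omitted-time-dummy bias. The parameter-recovery
  benchmark therefore generates under stationary means (the model's
  assumptions): with a sparse $B$ of spectral radius 0.6, no person
  effects and $n = 5000$ subjects, the entrywise mean absolute error of
  $\hat B$ is below 0.03 (measured ≈ 0.008), and under $B = 0$ the largest
  spurious coefficient stays below 0.05.

# The synthetic generator

`generate_panel()` draws, per subject $i$: a stable person effect
$\mu_i \sim N(0, \mathrm{diag}(\sigma_b^2))$; a wave-0 latent deviation
from the stationary distribution of the within-subject VAR(1) (discrete
Lyapunov solution); then
$y_t = m_t + \mu_i + B(y_{t-1} - m_{t-1} - \mu_i) + \varepsilon_t$ with
$\varepsilon_t \sim N(0, \Sigma)$, $\Sigma$ implied by the configured
contemporaneous partial-correlation matrix under unit partial variances.
Latent scores are discretized by four fixed thresholds
($-1.5, -0.5, 0.5, 1.5$) into 0--4; the continuous latent array is
attached to the returned panel for use as an estimation oracle.

The default configuration emulates the design of an acute-mania inpatient
study: $n = 100$ subjects, three waves (admission, middle of stay,
discharge), the 11 YMRS symptoms, clinically flavored sparse structure
(irritability–aggression, thought disorder–content, mood–motor–insight),
modest cross-lags converging on mood, motor activity and sleep, and high
wave-0 latent means declining linearly by wave 2 — deliberately
*nonstationary* means, because that is the situation the analysis pipeline
must survive. These defaults were fixed once, on clinical plausibility,
and are not calibrated to any published table.

What the generator does **not** emulate: item-specific threshold shifts,
rater effects, dropout/missingness (the reader supports missing cells;
the generator produces complete panels), regime changes in dynamics
(treatment alters $B$ itself in reality), and heavier-tailed or
zero-inflated score distributions. Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under their
own assumptions, not robustness to everything real data can do.
Discretization attenuates correlations (ordinal Spearman below latent
Pearson on average — asserted in the suite), which is also why
predictability and strength values on ordinal panels sit below their
latent-scale counterparts.

# The full pipeline

`run_full_study()` executes descriptives, three wave-wise GGMs,
predictability, optional stability bootstraps, all pairwise NCTs, and the
panel GVAR; every stage failure is recorded while independent stages
continue, and the report embeds the full configuration, making the
pipeline a pure function of (panel, config). `export_report()` writes
labeled weight matrices, edge lists (full and display-filtered at the
conventional 0.1 reporting threshold — a reporting filter only, the model
keeps all edges), GraphML, a predictability table (one row per symptom,
one column per wave), NCT JSONs, the directed temporal edge list, and a
summary JSON. A thin command-line wrapper with subcommands
(`validate`, `estimate`, `predictability`, `stability`, `compare`,
`temporal`, `simulate`, `run-all`) ships in `inst/cli/symptomnet.R`.

## Problem sizes used in validation

Chosen to make Monte-Carlo error small relative to each tolerance while
keeping the suite quick: 200 random 11-node matrices for the
oracle-equivalence checks ($10^{-8}$); 400 null and 150 alternative
replicates × 250 permutations for NCT calibration; $n = 5000$ panels for
GVAR recovery; $n = 2000$ for glasso support recovery (10 replicates) and
case-drop stability; $n = 100$ fixtures for end-to-end shape and
determinism checks.

# Known limitations

* Spearman input treats ordinal scores as exchangeable ranks; polychoric
  correlations would model the latent scale explicitly and are not
  implemented.
* Predictability under the Gaussian working model will not reproduce
  mixed-graphical-model tables exactly (see above).
* The pooled GVAR's stationarity assumption is likely violated in treated
  acute samples; the package surfaces the spectral radius and the
  centering trade-off rather than hiding them, but three waves cannot
  support a latent within/between decomposition.
* The NCT tests global strength only; edge-level and centrality-invariance
  variants are out of scope.
* All inference is conditional on complete cases per wave (listwise
  deletion); no imputation is provided.
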