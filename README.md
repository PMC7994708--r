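# symptomnet

Network analysis of ordinal symptom panels: cross-sectional Gaussian
graphical models, node predictability, permutation comparison of network
connectivity, and a Granger-causal temporal network from a few measurement
waves.

The package is written for researchers in psychiatric epidemiology and
clinimetrics who collect short repeated-measures scales — the motivating
case is the 11-item Young Mania Rating Scale (YMRS, items scored 0–4)
administered at hospital admission, mid-stay and discharge — and who want
to treat symptoms as a network of mutually interacting components rather
than as interchangeable indicators of one latent severity.

## What it computes

**Cross-sectional networks.** Per wave, a Gaussian graphical model: the
edge between symptoms *i* and *j* is their partial correlation

    w_ij = -K_ij / sqrt(K_ii K_jj),   K = C^-1,

with *C* a Spearman (default, robust for skewed ordinal scores) or Pearson
correlation matrix, PSD-repaired by eigenvalue clipping before inversion.
The default estimator is nonregularized (all partial correlations
reported); an EBIC graphical lasso (`ebic_glasso()`, block coordinate
descent in compiled code, EBIC with gamma = 0.5 over a 100-point penalty
grid) provides the sparse alternative.

**Node predictability.** Per node, the shared variance with all remaining
nodes, `R2_j = 1 - 1/K_jj` — the OLS R² of each symptom on the rest.

**Network Comparison Test.** A permutation test of equal *global strength*
(sum of absolute edge weights) between two waves or groups, with a paired
scheme (per-subject wave swapping — the honest null for repeated measures)
and an unpaired pool-and-resplit scheme; samples are standardized before
permuting so mean differences between waves cannot masquerade as network
change. p-values are +1-corrected and bit-reproducible given a seed.

**Stability.** Bootstrap edge-weight confidence intervals and case-drop
subsampling of strength centrality with the CS-coefficient (largest drop
proportion keeping subsample/full strength correlation ≥ 0.7 in ≥ 95% of
resamples).

**Temporal network.** A panel graphical VAR fit by pooled least squares on
all consecutive wave transitions: `y_t = mu + B y_{t-1} + eps`, where a
nonzero `B[j, k]` means symptom *k* Granger-predicts symptom *j* across
waves; the residual partial-correlation matrix is the contemporaneous
network, with Wald tests per directed edge and a stationarity (spectral
radius) check.

**Synthetic panels.** A latent-Gaussian generator with configurable true
contemporaneous network, temporal matrix, person effects and declining
wave means, discretized to 0–4 scores — so every estimator is validated by
parameter recovery against known truth. See the vignette
(`vignettes/symptom-networks.Rmd`) for the models, assumptions and design
decisions.

## Worked example

```r
library(symptomnet)

panel <- generate_panel(generator_config(seed = 7))  # study-mimicking fixture
panel
#> <symptom_panel> 100 subjects x 3 waves x 11 symptoms
#>   waves:    t0, t1, t2
#>   symptoms: Mood, Motor, Sexual, Sleep, Irritable, Speech, LgTtAbn, Content, ...

head(summarize_panel(panel, "t0"), 4)
#>   symptom mean    sd min max   n
#> 1    Mood 3.53 0.784   1   4 100
#> 2   Motor 3.09 1.006   0   4 100
#> 3  Sexual 1.30 1.133   0   4 100
#> 4   Sleep 2.84 1.143   0   4 100

net <- fit_network(wave_matrix(panel, "t0"))   # nonregularized Spearman GGM
net
#> <network_model> nonregularized (spearman input), 11 nodes, 55 nonzero edges, n = 100
#>   global strength = 5.920

round(sort(node_predictability(spearman_matrix(wave_matrix(panel, "t0"))),
           decreasing = TRUE)[1:4], 3)
#> Content   Motor    Mood Insight
#>   0.309   0.264   0.246   0.244

nct_global_strength(wave_matrix(panel, "t0"), wave_matrix(panel, "t2"),
                    n_perm = 1000, seed = 11,
                    estimator = estimator_config("nonregularized", "spearman"))
#> <nct_result> paired Network Comparison Test on global strength
#>   S1 = 5.920, S2 = 5.013, |S1 - S2| = 0.908
#>   p = 0.2977 (1000 permutations, seed 11, estimator nonregularized/spearman)

estimate_panel_gvar(panel)
#> <temporal_model> 11 nodes, 200 pooled transitions (centering none)
#>   spectral radius of B = 0.631 (stationary)
```

Reading the numbers: admission-wave severity is high (mean Mood 3.53 of 4)
and the saturated admission network carries a global strength of 5.92;
`Content` is the most predictable symptom at admission (31% of its variance
explained by the other ten). The paired NCT finds no significant
global-strength difference between admission and discharge on this
synthetic cohort (p = 0.30), and the pooled temporal model is comfortably
stationary (spectral radius 0.63) — as expected, since this panel was
*generated* with equal contemporaneous structure at every wave.

`run_full_study()` chains all of the above (three networks, an 11 × 3
predictability table, three pairwise NCTs, one temporal model) and
`export_report()` writes CSV / GraphML / JSON artifacts. A command-line
wrapper lives at `inst/cli/symptomnet.R`:

```sh
Rscript inst/cli/symptomnet.R simulate --nsubjects 100 --seed 1 --out demo
Rscript inst/cli/symptomnet.R run-all --input demo/panel.csv --out demo
```

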