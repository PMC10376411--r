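# clpnet

Cross-lagged panel network (CLPN) analysis for two-wave questionnaire
symptom data.

Longitudinal symptom networks ask a directed question that cross-sectional
networks cannot: which symptom at time 1 *predicts* which other symptoms at
time 2? clpnet implements the full workflow around that question for
matched two-wave Likert panels — the motivating setting is a 20-item
Internet-addiction test (items scored 1–5) administered to adolescents at
the start and end of a four-month online-learning period, with a 9-item
depression screener (items 0–3, total 0–27, cutoff 8) selecting the
analysed subgroup. It is aimed at researchers in psychometric network
analysis and psychiatric epidemiology who want a reproducible, scriptable
version of this pipeline with a built-in simulation test bed.

## The model

For items $x_1,\dots,x_p$ measured at waves 1 and 2, each wave-2 item is
regressed on all wave-1 items plus covariates with an L1 penalty:

$$x^{(2)}_j = \beta_{0j} + \textstyle\sum_i w_{ij}\,x^{(1)}_i +
\gamma_{1j}\,\text{age} + \gamma_{2j}\,\text{gender} + \varepsilon_j,
\qquad \hat w_{\cdot j} = \arg\min \tfrac1{2n}\|r_j\|^2 +
\lambda_j \|w_{\cdot j}\|_1 .$$

The $p \times p$ matrix $W$ is the directed network: $w_{ij}$ ($i \ne j$)
are cross-lagged edges, $w_{jj}$ autoregressive self-loops. Node importance
is summarized by out- and in-expected influence, $\mathrm{OEI}_i =
\sum_{j\ne i} w_{ij}$ and $\mathrm{IEI}_j = \sum_{i\ne j} w_{ij}$.
Around the CLPN the package provides:

* cohort tools: CSV ingestion with validation, matching waves on a
  participant key, screener-based subgroup selection, Table-1 style
  descriptives (paired t, Cohen's $d_z = t/\sqrt n$), Cronbach's alpha;
* per-wave undirected networks: EBIC-selected graphical-lasso partial
  correlations (own compiled implementation);
* a paired permutation network comparison test (global strength $S$,
  structure $M$, per-edge invariance);
* case-dropping bootstrap stability (CS coefficients) and nonparametric
  bootstrap edge CIs with difference tests;
* a synthetic two-wave generator with known sparse cross-lagged ground
  truth, planted OEI/IEI hub nodes, covariate effects, and a calibrated
  correlated screener — so the entire pipeline is testable end to end
  without any external data.

The lasso is solved by an in-package coordinate-descent implementation
(compiled), validated in the tests against closed-form oracles and glmnet.

## Worked example

```r
library(clpnet)

# a synthetic cohort: 2415 matched participants, default generator
sim <- generate_panel(generator_config(n_participants = 2415, seed = 7))
scr <- screen_panel(sim$panel, cutoff = 8)
scr$prevalence_w1; scr$prevalence_w2
#> [1] 13.75
#> [1] 17.93

net <- estimate_clpn(scr$panel, seed = 7)
net
#> Cross-lagged panel network: 20 nodes, n = 332
#>   118 of 380 cross-lagged edges nonzero (31.1%)
#>   autoregressive coefficients: 0.06 to 0.34

rank_report(centrality_table(net), k = 3)$oei
#>   rank  item     value
#> 1    1  iat1 2.3822934
#> 2    2  iat5 0.7485264
#> 3    3 iat10 0.6872292
```

13.75% of the cohort screens positive at wave 1 (those 332 participants
form the analysis subgroup) and 17.93% at wave 2. The generator planted
its high-OEI hub at item 1, and the screened-subgroup estimate ranks it
first by a wide margin. Comparing the two waves' cross-sectional networks
and assessing stability:

```r
nct <- nct_paired(scr$panel$wave1_items, scr$panel$wave2_items,
                  n_permutations = 1000, seed = 7)
nct
#> Permutation network comparison test (paired)
#>   global strength: 8.21 vs 9.47, S = 1.26, p = 0.001
#>   structure: M = 0.18, p = 0.230  (1000 permutations)

stab <- case_dropping_bootstrap(scr$panel, n_boot = 100, seed = 7)
cs_coefficient(stab)
#> oei iei
#> 0.5 0.7
```

In this synthetic cohort the wave-2 network is genuinely denser than the
wave-1 network (the cross-lagged dynamics add dependence), so the global
strength test rejects while the structure statistic does not; both
centrality orderings are stable under case dropping (CS coefficients at
or above 0.5).

`run_pipeline()` chains every stage from one config (R list or YAML; see
`inst/extdata/demo-config.yaml`) and writes all artifacts — descriptives,
network matrix and edge list, centralities, NCT results, stability curves,
sensitivity correlations, and a `summary.json` that reproduces the run. A
thin CLI lives at `inst/cli/clpnet.R`.

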