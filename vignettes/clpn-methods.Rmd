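---
title: "Cross-lagged panel networks for two-wave symptom data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel networks for two-wave symptom data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Symptom-network psychometrics treats a mental-health construct not as a
latent disease entity but as a system of interacting symptoms. For
longitudinal questionnaire data measured at two waves, the natural network
is *directed*: an edge $i \to j$ asks how much symptom $i$ at the first
wave predicts symptom $j$ at the second wave, over and above every other
first-wave symptom. clpnet implements this cross-lagged panel network
(CLPN) workflow for two-wave Likert panels — the motivating use case is a
20-item Internet-addiction questionnaire administered to adolescents
before and after a period of online learning, with a 9-item depression
screener (items 0–3, total 0–27, cutoff 8) defining the analysed
subgroup — together with everything around it: cohort screening,
descriptive tables, permutation comparison of the per-wave networks,
bootstrap stability and accuracy, and a synthetic-data generator with
known ground truth.

## The cross-lagged panel network model

Let $x^{(1)}_i$ and $x^{(2)}_i$ be the $p$ item scores of one participant
at waves 1 and 2. For each target item $j$ the package fits a penalized
linear regression

$$ x^{(2)}_j = \beta_{0j} + \sum_{i=1}^{p} w_{ij}\, x^{(1)}_i
   + \gamma_{1j}\,\mathrm{age} + \gamma_{2j}\,\mathrm{gender}
   + \varepsilon_j , $$

with the lasso penalty $\lambda_j \sum_i |w_{ij}|$, which shrinks small
coefficients exactly to zero and yields a sparse network. The fitted
$w_{ij}$ populate column $j$ of the weight matrix: rows are wave-1 sources,
columns wave-2 targets, and the diagonal $w_{jj}$ is the autoregressive
coefficient of item $j$. A 20-item panel therefore has $400$ estimable
directed edges, $20$ autoregressive and $380$ cross-lagged. Age and gender
coefficients are estimated per node but kept outside the weight matrix;
no centrality or comparison ever mixes covariate and symptom edges.

Decisions the model description leaves open, and what this package does:

* **Standardization.** Predictors *and* outcome are z-scored within the
  analysis sample, so edge weights are standardized regression
  coefficients, comparable across nodes — a prerequisite for summing them
  into centralities. An unstandardized variant is not offered.
* **Penalty selection.** $\lambda_j$ is chosen per node by seeded 10-fold
  cross-validation minimizing held-out squared error (the `"min"` rule;
  `"1se"` is available as an option). One fold assignment, drawn from the
  estimation seed, is shared by all $p$ node fits, which makes each column
  of the network invariant to the order in which nodes are fit.
* **Penalty grid.** 100 log-spaced values from $\lambda_{\max} =
  \max_i |x_i^\top y|/n$ (the smallest penalty that zeroes every
  coefficient) down to $10^{-4}\lambda_{\max}$.
* **Ordinal items are treated as continuous**, as is standard in this
  workflow; no polychoric step is applied.

The lasso solver is a cyclic coordinate-descent implementation (compiled
code, Gram-matrix form with warm starts along the penalty path and
active-set iteration). Convergence is declared when the largest
coefficient change in a full sweep falls below $10^{-7}$. The solver is
validated in the test suite against closed forms: the ordinary
least-squares solution at $\lambda = 0$, the univariate soft-threshold
solution, emptiness at $\lambda \ge \lambda_{\max}$, and the glmnet path
on random problems.

## Centrality

For a directed network the relevant expected-influence indices are the
signed sums of a node's cross-lagged edges:

$$ \mathrm{OEI}_i = \sum_{j \ne i} w_{ij}, \qquad
   \mathrm{IEI}_j = \sum_{i \ne j} w_{ij} . $$

OEI measures how much a symptom predicts the rest of the network; IEI how
much it is predicted. Autoregressive edges are excluded from both and
reported separately. Because both indices sum the same off-diagonal
entries, $\sum_i \mathrm{OEI}_i = \sum_j \mathrm{IEI}_j$ exactly — a
conservation identity the test suite checks to machine precision. Sums
are signed (expected influence), not absolute-value strength.

## Per-wave cross-sectional networks

The network comparison and sensitivity analyses need an undirected
network per wave. The package estimates a regularized partial-correlation
network: graphical lasso on the item correlation matrix over a descending
100-point penalty grid ($\lambda_{\min}/\lambda_{\max} = 0.01$), scored by
the extended Bayesian information criterion

$$ \mathrm{EBIC}_\gamma = -2\,\ell(\Theta) + E \log n + 4\gamma E \log p, $$

with $E$ the number of nonzero upper-triangle precision entries and
$\gamma = 0.5$, the conservative psychometric default. The selected
precision matrix $\Theta$ is converted to partial correlations
$\rho_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}$. The penalty
applies to off-diagonal entries only. The graphical lasso is a compiled
block coordinate descent; warm starts run down the penalty path, and the
recovered precision matrices keep exact zeros so EBIC edge counts are
well defined. Pearson correlations of the raw scores are the default
input (Spearman optional).

## Network comparison test

Two networks estimated from the same participants at two waves are
compared by a paired permutation test on three statistics: the
global-strength difference $S = |\,\sum |e^{(1)}| - \sum |e^{(2)}|\,|$,
the structure statistic $M = \max_{ij} |e^{(1)}_{ij} - e^{(2)}_{ij}|$, and
each edge's absolute difference. The null distribution swaps each
participant's wave-1 and wave-2 item vectors independently with
probability one half and re-estimates both networks; this within-person
swap is the exchangeability-respecting null for paired data, and an
unpaired group-relabeling mode is provided for independent samples.
P-values use the add-one estimator $(1 + \#\{\text{null} \ge
\text{observed}\}) / (1 + B)$, so they are never exactly zero. Per-edge
p-values are unadjusted by default; a Holm flag is available. The default
$B = 1000$; any estimator failure inside a permutation is retried with a
fresh swap pattern and counted. The test suite verifies calibration at
the null (rejection rates 0.06 for $S$ and 0.03 for $M$ at $\alpha =
0.05$ over 100 replicates of $n = 300$, $p = 8$, 200 permutations).

## Stability and accuracy

* **Case-dropping bootstrap.** For each drop proportion $q$ in
  $\{0.05, 0.10, \dots, 0.75\}$, subsamples retaining
  $\lceil (1-q)n \rceil$ rows are drawn without replacement, the network
  re-estimated, and each centrality's Pearson correlation with the
  full-sample centrality stored. The correlation-stability coefficient
  CS is the largest $q$ whose empirical 5th percentile of correlations is
  still $\ge 0.7$; CS $\ge 0.25$ is conventionally acceptable. The
  quantile rule is the plain plug-in (type-7) quantile with no smoothing.
* **Edge accuracy.** Nonparametric bootstrap (resampling rows with
  replacement, 1000 iterations by default) with percentile 95% CIs per
  edge; no BCa correction.
* **Difference tests.** For any pair of edges or centrality values, the
  percentile CI of the bootstrap difference; a pair is flagged when the
  CI excludes zero. The significance matrix is symmetric with an
  all-FALSE diagonal.

All resampling derives every replicate's seed deterministically from one
master seed, so results are bit-reproducible and increasing the iteration
count leaves earlier replicates unchanged.

A caveat the user should know: percentile CIs around a *regularized*
estimator inherit its shrinkage bias. In simulations with a strong
planted edge (standardized weight 0.5, $n = 5000$), CIs from the CV-lasso
estimator cover the true value only ~85% of the time — the CV-selected
penalty shrinks the edge by about a third of the CI half-width, and this
ratio does not vanish with $n$. The coverage validation in the test suite
therefore drives the bootstrap with an unpenalized node-wise estimator
(coverage 90% over 50 replicates, unbiased point estimates); interpret
lasso-edge CIs as accuracy envelopes around the *regularized* estimate,
not as confidence intervals for unshrunk effects.

## The synthetic-data generator

No raw cohort accompanies the motivating study, so the generator is the
package's test bed and defines the study conditions everything is
validated under.

**Generating model.** Wave-1 latents are multivariate normal with unit
variances and correlation $\Sigma_{ij} = \rho + \delta\,c^{|i-j|-1}$
($i \ne j$): an exchangeable baseline $\rho = 0.38$ plus a local component
($\delta = 0.25$, decay $c = 0.5$) that gives neighbouring items extra
shared variance. The average inter-item correlation (~0.43) implies an
internal consistency near 0.93 for 20 items, matching a high-reliability
questionnaire. The local component matters for the *cross-sectional*
analyses: a purely exchangeable structure makes every true partial
correlation identical and tiny ($\rho / (1 + (p-2)\rho) \approx 0.03$), so
EBIC-selected networks of screened subgroups collapse to empty and
matrix-correlation sensitivity checks degenerate to noise — a single
common factor is the wrong texture for item-level network analysis. The
mixed structure keeps an interpretable single-parameter baseline while
planting the heterogeneous partial-correlation backbone
(adjacent-item partials up to ~0.35) that real questionnaires show.
Setting `latent_local_correlation = 0` restores the purely exchangeable
design. Wave-2 latents follow

$$ X^{(2)} = X^{(1)} (B + \mathrm{diag}(a)) + \mathbf{z}_{\mathrm{age}}
   \gamma_1 + \mathbf{g}\,\gamma_2 + E, $$

with $B$ a sparse cross-lagged matrix, autoregressive coefficients $a_i
\sim U(0.2, 0.45)$, age z-scored and gender 0/1 with additive effects
(default 0.1 each), and $E$ normal innovations (sd 0.8) that are
independent of the wave-1 latents but, by default, share the wave-1
correlation structure across items: stable trait and common-method
variance persists across waves in real questionnaires, and without it
wave-2 internal consistency collapses (~0.6) and the wave-2
cross-sectional network of a screened subgroup degenerates to empty.
Because the innovations are independent of wave 1, this choice does not
affect the cross-lagged coefficients; `correlated_innovations = FALSE`
gives item-independent innovations. Generation
refuses lag matrices with spectral radius $\ge 1$, the stationarity
boundary of the implied first-order vector autoregression. Both waves are
discretized to 1..5 by fixed equal-probability quintile thresholds, which
puts item means near 3 and SDs near 1.4, within the range of published
adolescent questionnaire descriptives.

**Planted structure.** The default $B$ (density 0.12, weights 0.05–0.25,
85% positive) plants one hub-out node (first item) and one hub-in node
(last item) whose absolute row/column sums dominate by construction — the
ground truth for parameter-recovery and centrality-ranking tests. At the
default study size ($n = 2000$) the estimated and true cross-lagged
weights correlate above 0.9 and the planted hubs top the OEI and IEI
rankings in essentially every seed.

**Screener.** Each wave's screener latent is the standardized mean
symptom latent times a loading, plus independent noise; nine items with
communality 0.75 are discretized to 0–3 and summed. Two constants were
fixed by a one-off calibration and are not user dials: the latent loading
is inflated by $1/0.80$ so that, after the attenuation of two rounds of
ordinal discretization, the *observed* correlation between screener total
and mean symptom score lands at the configured `screener_loading`
(default 0.6); and the item thresholds (cumulative probabilities 0.76,
0.93, 0.982) put roughly 14% of a default cohort at or above the cutoff
of 8 at wave 1, with a wave-2 latent shift of 0.14 raising this to
roughly 18% — the screening conditions of the motivating cohort.

**What the generator does not emulate.** There is no missingness or
attrition mechanism (matched completers only); covariate effects are
uniform across items; wave-2 marginals drift only through the lag
dynamics (no item-specific severity shifts); and the
latent scale is genuinely continuous-normal, so polychoric-style ordinal
subtleties are absent. Passing tests therefore demonstrate correctness of
the estimators under a well-specified sparse linear lag model, not
robustness to the full messiness of field questionnaire data.

## Pipeline and reproducibility

`run_pipeline()` drives the stages from one configuration (R list or
YAML): data (generate, or read + match on a participant key), screen,
describe, estimate, compare, stability, sensitivity. One master seed fans
out to named child streams per stage, so any stage can be re-run in
isolation with identical results, and `summary.json` echoes everything
needed to reproduce a run. A thin command-line wrapper
(`inst/cli/clpnet.R`) exposes the stages as verbs.

The sensitivity stage mirrors the matched-versus-lost design: when the
cohort has unmatched rows, it estimates each wave's cross-sectional
network on the matched and on the unmatched ("lost") participants and
reports the Pearson correlation of their edge vectors; high correlations
indicate the matching process did not distort the network structure.

The accompanying acceptance script analyses a synthetic cohort at the
motivating study's scale — wave tables of 10,104 and 8,390 rows with
2,415 matched participants, cutoff 8 (a screened subgroup of roughly
340) — using 1000 NCT permutations, 1000 edge-CI bootstrap iterations,
and 100 case-dropping iterations per drop proportion; these problem
sizes are the package's defaults for a single-machine run and are stated
here as such.

## Known limitations

* The CLPN estimates predictive, not causal, relations; edges are
  regularized partial regression coefficients under linearity.
* $\lambda$ selection by CV-min trades a small number of spurious edges
  for sensitivity; the `"1se"` rule is sparser but can miss weak edges.
* Edge CIs inherit lasso shrinkage (see above).
* CS coefficients are reported on the drop-proportion grid; values
  between grid points are not interpolated.
* With very small screened subgroups (tens of rows), all network
  quantities are noisy; the package warns below $n = 30$ and for
  subsamples under $3p$ rows, but proceeds.
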