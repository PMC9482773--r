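---
title: "Estimating directed and undirected symptom networks from ordinal questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating directed and undirected symptom networks from ordinal questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(symptomnet)
```

## The model

`symptomnet` analyses questionnaires whose items are ordinal severity ratings
— the motivating instrument is the nine-item Patient Health Questionnaire
(PHQ-9), scored 0 ("not at all") to 3 ("nearly every day") — under the
network view of psychopathology: symptoms are nodes that influence one
another directly, rather than passive indicators of a single latent disease
factor. The estimation pipeline has four stages.

**1. Latent thresholds and polychoric correlations.** Community severity
ratings are heavily right-skewed, so Pearson correlations of the raw codes
are biased toward zero. Each item $j$ is instead modelled as a discretized
standard normal variable $Z_j$: observing category $k$ means
$\tau_{j,k-1} < Z_j \le \tau_{j,k}$. Estimation is the classic two-step
method: thresholds from the marginal cumulative proportions,
$\tau_{j,k} = \Phi^{-1}(\hat F_j(k))$, then each pairwise latent correlation
$\rho_{ij}$ by maximizing the contingency-table likelihood
$\sum_{ab} n_{ab} \log P_{ab}(\rho)$, where $P_{ab}$ is a bivariate-normal
rectangle probability between consecutive thresholds. Two-step estimation is
used rather than full joint maximum likelihood because it is the standard
fast choice and, at 9 items and several hundred respondents, the efficiency
difference is negligible next to sampling error.

**2. Undirected network (graphical lasso + EBIC).** The regularized partial
correlation network solves
$\hat\Theta_\lambda = \arg\max_\Theta \; \log\det\Theta - \mathrm{tr}(R\Theta)
- \lambda \sum_{i \ne j} |\theta_{ij}|$
over a log-spaced grid of 100 penalties from
$\lambda_{\max} = \max_{i<j} |\rho_{ij}|$ down to $0.01\,\lambda_{\max}$.
The penalty is chosen by the extended Bayesian information criterion,
$\mathrm{EBIC}_\gamma = -n\,[\log\det\Theta - \mathrm{tr}(R\Theta)] +
E\log n + 4E\gamma\log p$, with $E$ the edge count, $\gamma = 0.5$ by
default (the canonical EBIC-glasso setting), and ties broken toward the
sparser model. Precision entries are reported as partial correlations
$-\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$.

**3. Directed network (dependency matrix + TMFG).** Direction comes from
node dependence: $D_{ij}$, the dependency of $i$ on $j$, averages over the
remaining nodes $k$ how much the correlation $r_{ik}$ drops when $j$ is
partialled out,
$$D_{ij} = \frac{1}{p-2} \sum_{k \notin \{i,j\}}
  \left( r_{ik} - r_{ik \cdot j} \right),$$
with $r_{ik\cdot j}$ the first-order partial correlation. $D$ is asymmetric:
a symptom that many others depend on is an *influencer*. The Triangulated
Maximally Filtered Graph then reduces the dense dependency structure to a
planar backbone of exactly $3p-6$ edges: seed with the 4-clique of the four
nodes most strongly associated overall, then repeatedly insert the
node/triangular-face pair that maximizes the three new edge weights,
splitting the face. Every retained edge $\{i,j\}$ carries both opposing
arcs — $i \to j$ weighted $D_{ji}$ (influence of $i$ on $j$) and $j \to i$
weighted $D_{ij}$ — because empirically every node shows nonzero incoming
*and* outgoing strength and total out-strength must balance total
in-strength; the arc with larger magnitude marks the edge's dominant
direction.

**4. Centrality, stability, invariance.** Out-/in-strength sum absolute arc
weights by origin/destination; relative influence is
$(s_{out}-s_{in})/(s_{out}+s_{in})$; betweenness and closeness use shortest
directed paths under the standard inverse-weight length $1/|w|$, with
Brandes fractional credit for ties (betweenness raw, to match the integer
scale such tables are usually printed on; a normalized variant is available).
Stability is a case-dropping bootstrap: at retention levels 70/60/50%,
subsamples are drawn without replacement, the directed pipeline re-run, each
node's centrality averaged over replications, and the Spearman correlation
with the full-sample values reported. Invariance across two groups refits
the pipeline per group and compares centrality profiles with the paired
Wilcoxon signed-rank test (zero differences dropped, midranks for ties,
exact p by enumeration for tie-free $n' \le 25$, otherwise a
continuity-corrected normal approximation with tie-corrected variance).

## Parameters that matter

| parameter | default | why |
|---|---|---|
| EBIC $\gamma$ | 0.5 | canonical EBIC-glasso default; higher favours sparsity |
| $\lambda$ grid | 100 points, min ratio 0.01 | standard glasso path resolution |
| edge floor | $10^{-6}$ | numerical definition of a nonzero edge |
| retention levels | 0.7, 0.6, 0.5 | the conventional case-dropping ladder |
| bootstrap reps | 1000 (tests use 200) | Monte-Carlo error on a Spearman rank correlation of 9 values is already small at 200 |
| age split | ≤28 vs ≥29 | the demographic dichotomy used for invariance |
| missing data | listwise | keeps one consistent N; pairwise optional for the polychoric tables |

## The synthetic-data generator

`make_ground_truth()` + `simulate_responses()` generate ordinal datasets
with a *known* sparse latent partial-correlation structure: a standardized
precision matrix $I - P$ is inverted to a correlation matrix (positive
definiteness checked at construction), latent normal vectors drawn,
coordinates discretized at per-item thresholds. Defaults emulate a
community PHQ-9 survey: $N = 975$, nine items, thresholds
$(0.25, 0.9, 1.6)$ giving right-skewed marginals (about 60/22/13/5% across
the four categories) — the non-normality that motivates polychoric
correlations in the first place — a 65% female split, and an even split at
the 28/29 age cut. Group differences, when requested, scale the latent edge
weights of one group, giving a controllable alternative for power checks.

What the generator does *not* emulate: empirical marginals of any specific
survey, item-specific threshold differences, respondent heterogeneity
(careless responding, acquiescence), and any true directionality — the
latent model is an undirected Gaussian graphical model, so directed-network
"recovery" checks can only test structural properties (a hub collecting
dominant outgoing arcs), not arrow-level truth. Passing tests therefore
demonstrate estimator correctness and procedural stability under idealized
ordinal-from-Gaussian sampling, not validity of directional claims on real
data.

## Numerical choices

* Bivariate-normal rectangle probabilities use a vectorized port of Genz's
  BVND Gauss–Legendre scheme (absolute error well below $10^{-7}$, verified
  against an independent implementation in the test suite); the pairwise
  likelihood is maximized with Brent search on $[-0.999, 0.999]$ at
  tolerance $10^{-7}$, returning a flagged boundary value for perfectly
  concordant tables.
* A non-positive-definite pairwise matrix is repaired by eigenvalue
  clipping (floor $10^{-6}$, rescale to unit diagonal) — simple,
  deterministic, and adequate at 9 items; the flag is kept on the result.
* Graphical lasso: block coordinate descent over columns with an inner
  soft-threshold coordinate descent; convergence when the working
  covariance changes by less than $10^{-4}$ between sweeps. The likelihood
  carries the multiplier $n$ (not $n/2$) in the EBIC consistently; only
  differences matter for selection.
* TMFG ties (seed selection, node/face gains) break by lowest node index,
  then lowest face index, so the skeleton is fully deterministic.
* Degenerate items (a single occupied category) are excluded with a
  warning; in group comparisons such an item is dropped from *all* groups
  so the paired test keeps a common node set. Unreachable node pairs in
  centrality are skipped with a coverage flag rather than producing
  infinite distances (TMFG skeletons are connected, so this is an edge
  case).
* Bootstrap replications are seeded counter-style (`seed + replication`),
  so results are reproducible and a longer run extends a shorter one.

## Design choices where the design was open

* **Skeleton from the dependency matrix** (symmetrized by the elementwise
  maximum), not from zero-order correlations: the directed method is built
  on node dependence, so the retained backbone should reflect dependency
  strength. The alternative is exposed via `skeleton_on = "correlation"`.
* **Arc orientation convention**: the arc $i \to j$ carries $D_{ji}$, the
  dependency of $j$ on $i$. The reverse convention relabels in- as
  out-strength; the convention is stated here and used consistently.
* **Dependency divisor** $p-2$ (the average over third parties). Any
  constant divisor rescales all weights uniformly and preserves every
  rank-based result, so reported magnitudes are comparable only within a
  convention.
* **Wilcoxon p-values** are reported with their method flag but the
  substantive outputs are the $W^+/W^-$ statistics: different software
  chooses exact vs approximate p differently, and the statistics themselves
  are the reproducible part.
* **No command-line wrapper**: the package is an analysis library; the
  exported functions (`simulate_responses()`, `symptom_network()`,
  `centrality_stability()`, `centrality_invariance()`, `run_pipeline()`,
  `write_report()`) are the intended interface from R scripts.

## A worked run

```{r, eval = FALSE}
spec <- make_ground_truth("chain", n_items = 9, edge_weight_range = 0.3,
                          n_respondents = 975, seed = 1)
d <- simulate_responses(spec)
fit <- symptom_network(d)
summary(fit)
st <- centrality_stability(d, reps = 200, seed = 1)
stability_table(st, digits = 2)
inv <- centrality_invariance(d, "gender")
inv$tests
```

The test suite exercises these paths at the following problem sizes, chosen
to keep Monte-Carlo error well below the tolerances being asserted while
remaining desk-scale: pairwise polychoric recovery at $n$ up to 50{,}000;
chain-structure recovery at $n = 5000$ over 20 seeds; stability at
$n = 2000$ with 200 replications; invariance null behaviour at roughly 2000
respondents per group over 10 seeds; TMFG oracle equivalence on 100 random
instances of 4–7 nodes.

## Known limitations

* The paired signed-rank invariance test treats the nine node-wise
  centrality differences as independent, but they share the network-level
  sampling error: if one group's sample happens to correlate more strongly
  overall, all differences shift together and the test can reject even when
  both groups follow the identical data-generating process. Simulations
  under the exchangeable null show this anti-conservativeness directly
  (individual runs reject at well above the nominal rate even though no
  index rejects systematically). Group comparisons should therefore be read
  descriptively, alongside the profile correlations, rather than as
  calibrated hypothesis tests.
* Closeness magnitudes depend on the overall weight scale (distances are
  $1/|w|$), so only rank order is comparable across fits; the same holds
  for dependency-weight magnitudes given the divisor convention above.
* Cross-sectional dependency direction is not causal direction; the
  directed network orders conditional-dependence asymmetries, nothing more.
* The glasso EBIC selection inherits the usual small-$n$ caveat: at a few
  hundred respondents with $\gamma = 0.5$ it errs toward sparsity, and weak
  true edges are the first to vanish.
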