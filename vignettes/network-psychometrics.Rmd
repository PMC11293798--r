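---
title: "Mixed graphical model networks for cohort outcome data: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed graphical model networks for cohort outcome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortmgm)
```

# Overview

`cohortmgm` implements a network-psychometric analysis pipeline for cohort
tables that mix one (or more) binary variables with continuous outcome
scores — the setting of studies that relate a group indicator such as
sexual-minority status to depression, interpersonal difficulties and
substance use. The pipeline estimates a pairwise mixed graphical model
(MGM) by nodewise penalized regression, summarizes the resulting signed
weighted network through centrality indices and shortest-path mediation,
detects communities of variables and of individuals, and quantifies
uncertainty by nonparametric bootstrap. A conjugate Gibbs-sampler
generator draws synthetic cohorts from the *same* model class, so every
stage can be validated against known ground truth without access to any
restricted cohort data.

This vignette documents the statistical model, the algorithms, the
tunable parameters, and the design decisions that were genuinely open —
in enough detail that a maintainer can tell which behaviour is principled
and which is convention.

# The model

## Pairwise mixed graphical model

For variables $x_1, \dots, x_p$ of mixed type (Bernoulli or Gaussian),
the pairwise MGM specifies each node's conditional distribution given all
others:

* continuous node $s$:
  $x_s \mid x_{-s} \sim N\!\big(\alpha_s + \textstyle\sum_{t \ne s}
  \theta_{st} x_t,\ \sigma_s^2\big)$,
* binary node $s$ (coded 0/1):
  $x_s \mid x_{-s} \sim \mathrm{Bernoulli}\big(\mathrm{logit}^{-1}(
  \alpha_s + \textstyle\sum_{t \ne s} \theta_{st} x_t)\big)$,

with a symmetric interaction matrix $\Theta = (\theta_{st})$, zero
diagonal. The edge set of the network is the support of $\Theta$.

**Scale convention.** Written literally, the Gaussian conditionals above
are mutually *incompatible* as a joint distribution whenever residual
standard deviations differ across coupled nodes (symmetry of the joint
precision requires $\theta_{st}/\sigma_s^2 = \theta_{ts}/\sigma_t^2$).
`cohortmgm` therefore defines $\Theta$ on the *standardized* scale: the
generator samples latent unit-residual variables
$z_s \mid z_{-s} \sim N(\sum_t \theta_{st} u_t, 1)$ (where $u_t$ is $z_t$
for continuous and the raw 0/1 value for binary nodes) and returns
$x_s = \alpha_s + \sigma_s z_s$. This has a proper joint distribution for
any symmetric $\Theta$ whose continuous sub-block satisfies
$I - \Theta_{cc} \succ 0$ (checked before sampling; unstable matrices are
rejected), and it coincides exactly with the textbook form above whenever
$\sigma_s = 1$ and $\alpha_s = 0$. It also makes the generator conjugate
to the estimator: regressing any standardized continuous node on the
others recovers the corresponding row of $\Theta$, which is what the
parameter-recovery tests exploit.

## Gibbs sampler

`simulate()` on an `mgm_spec` runs one independent Markov chain *per
output row*, advancing all chains in parallel with a systematic scan over
nodes. Because chains are independent, the returned rows are independent
draws — there is no residual autocorrelation for the estimator to absorb,
unlike single-chain thinning. The defaults (`burn_in = 1000`, `thin = 10`;
total scans = `burn_in + thin`) are deliberately conservative: empirical
convergence checks on the calibrated 10-variable specification show group
means stable to within Monte-Carlo noise from roughly 100 scans onward,
and the test suite uses 50–300 scans to keep fixture generation fast.
Identical `(spec, n, seed)` give bitwise-identical tables.

## The calibrated cohort specification

`mcs_like_spec()` encodes a 10-variable cohort: a binary minority-status
indicator `MS` with marginal prevalence $490/8017 \approx 6.1\%$ and nine
continuous outcomes (depression, conduct problems, peer problems, social
support, victimization, closeness to parents, smoking, drinking, drug
use; all coded so that higher is worse). Its sparse interaction matrix
carries 12 edges, every magnitude at least 0.15:

* `MS` couples directly to depression (solved coupling ≈ 0.87, by far the
  strongest edge), conduct problems (0.55), peer problems (0.35),
  victimization (0.25) and smoking (0.22);
* the continuous block links depression–victimization (0.45),
  depression–parents (0.35), parents–support (0.40), depression–drinking
  (0.25), peer–conduct (0.30), conduct–smoking (0.60) and smoking–drug
  use (0.40).

Calibration is closed-form moment matching and is exact for three things:
the binary marginal prevalence (the binary intercept is
$\mathrm{logit}(490/8017) - \tfrac{1}{2}\theta_{MS}^\top (I -
\Theta_{cc})^{-1} \theta_{MS}$, integrating the continuous block out of
the joint), every non-minority group mean and standard deviation (the
latent scale of each variable is chosen from the marginal variance
implied by $(I - \Theta_{cc})^{-1}$), and the minority-group depression
mean (12.21 vs 5.22), pinned by solving the one free `MS`–depression
coupling linearly. The remaining minority-group means are approximate —
conduct problems is the furthest off (implied ≈ 3.1 vs the 1.50 target) —
because five minority couplings cannot satisfy nine mean constraints once
three structural requirements take precedence:

1. every true edge has magnitude ≥ 0.15 so that structure recovery is a
   well-posed task;
2. the shortest-path structure matches the study's finding — direct
   geodesics from `MS` to depression, peer problems and conduct problems;
   smoking and drug use reached via conduct problems; support, closeness
   to parents, victimization and drinking reached via depression; this
   bounds how strong the direct `MS`–smoking and `MS`–victimization
   edges may be relative to their mediated routes;
3. the node-community structure is non-trivial: the support pair shares
   an internal edge (parents–support) rather than both hanging off
   depression, so that community detection has three to four planted
   clusters to find, not two.

A single shared conditional covariance also cannot reproduce the
*different* group standard deviations printed for the two groups (e.g.
depression 7.42 vs 5.45); the non-minority values were matched exactly.
The implied moments are attached to the spec as the `"calibration"`
attribute so users can inspect the deviations rather than take them on
trust.

## Planted subgroups

`plant_subgroups()` splits the minority rows into groups of exact sizes
and adds per-group mean shifts, recording ground-truth labels.
`mcs_subgroup_shifts()` provides the default three-profile pattern — one
group elevated on peer/conduct problems, one on smoking/drinking/drug
use, one on depression/victimization with poor support and closeness —
with a default separation of 2.5 full-sample standard deviations. The
separation was fixed at a value where the planted clusters are
unambiguous ("highly related within"), so the recovery harness tests the
clustering machinery; at 1.5 SD the task becomes marginal signal
detection and recovery degrades to ARI ≈ 0.7 regardless of algorithm
quality.

# Estimation

## Nodewise lasso with EBIC selection

`fit_mgm()` standardizes continuous columns (binary stays 0/1), then
regresses each node on all others with an L1 penalty — squared-error loss
for continuous nodes, logistic loss for binary nodes — over a log-spaced
grid of 100 penalties from $\lambda_{\max}$ (the smallest penalty giving
an all-zero model, computed from the null-model gradient) down to
$0.01\,\lambda_{\max}$. The penalty per node is selected by the extended
Bayesian information criterion

$$\mathrm{EBIC}_\gamma = -2\ell + k \log n + 2\gamma k \log(p - 1),$$

with $k$ the number of nonzero coefficients, $p - 1$ the number of
candidate predictors, and $-2\ell = n \log(\mathrm{RSS}/n)$ for Gaussian
nodes. The default $\gamma = 0.3$ balances discovery against parsimony.
A standard exchange argument shows the selected $k$ is non-increasing in
$\gamma$ for fixed data; the suite asserts this across fixtures.

Two implementation choices deserve comment:

* **Penalty standardization.** Coefficients are reported on the data
  scale — a binary predictor keeps its per-category interpretation — but
  the penalty is applied on internally standardized predictors (the
  conventional default of penalized-regression software). Penalizing the
  raw 0/1 coefficient of a 6%-prevalence indicator would shrink its
  gradient scale by more than an order of magnitude relative to the
  z-scored continuous predictors and make moderate group–outcome edges
  essentially undetectable at realistic cohort sizes.
* **Post-selection thresholding.** Selected coefficients below
  $\tau = \sqrt{k}\sqrt{\log(p)/n}$ are zeroed (`threshold = TRUE`),
  mirroring the high-dimensional-consistency threshold applied by
  standard MGM software. EBIC alone occasionally admits spurious
  coefficients of magnitude ~0.01 at $n = 8000$; the threshold removes
  them while leaving true edges (one order of magnitude larger)
  untouched. The solver is `glmnet`'s coordinate descent (tolerance
  `1e-6`, iteration cap `1e5`); at vanishing penalty it agrees with
  ordinary least squares to `1e-4`, which the suite checks against `lm`.

## Edge aggregation and signs

The two directed coefficients per pair are combined by the **AND rule**:
an edge exists only when both are nonzero; its magnitude is the mean of
the absolute coefficients; its sign is the shared sign, or *undefined*
(0) when the two disagree — the state categorical–categorical
associations occupy in this model family. Sign-undefined edges
participate in everything magnitude-based (strength, distances,
betweenness, closeness) and are excluded from expected influence, which
is sign-dependent by definition.

## Node predictability

Predictability is **in-sample**, from the selected nodewise model:
$R^2 = 1 - SS_{res}/SS_{tot}$ for continuous nodes, and correct
classification at the 0.5 probability threshold for binary nodes. A
binary node with an empty neighbourhood reduces exactly to the
majority-class rate (≈ 0.94 at 6% prevalence — which is why a high CC for
a rare indicator must be read against that base rate), and a continuous
node with an empty neighbourhood has $R^2 = 0$.

# Graph metrics

Distances use edge lengths $1/|w|$ — the convention of the visualization
and analysis stack this model family is used with; the choice only needs
to be monotone in edge strength. Shortest paths are computed by Dijkstra
with **lexicographic tie-breaking** on the node sequence (the underlying
tie-break is otherwise arbitrary; fixing it makes path reports
deterministic). Betweenness uses Brandes accumulation with fractional
credit over tied geodesics and endpoints excluded; tie detection uses a
relative tolerance of `1e-9` on path lengths. Closeness is the inverse of
the summed distance to reachable nodes — the "mean distance" variant
differs by the constant factor $p-1$, which vanishes under the per-index
z-standardization the centrality table also reports. On disconnected
networks closeness is computed over each node's reachable set and the
table is flagged. `mediation_report()` classifies each source–target
relation as direct (the geodesic is the single edge) or mediated (the
geodesic's interior nodes are listed in order).

Both algorithms are verified exactly against brute force — Floyd–Warshall
for distances, exhaustive simple-path enumeration for betweenness — on
hundreds of random graphs.

# Communities

## Node communities: signed spinglass

`spinglass_communities()` minimizes the signed-network Hamiltonian in
which positive within-community weight is rewarded and negative
within-community weight penalized, each against its own
configuration-model null with resolution parameters
$\gamma^+ = \gamma^- = 1$. Optimization is simulated annealing
(geometric cooling 0.99 from $T = 1$ to $T = 0.01$, $10p$ proposals per
temperature, at most 25 spin states) followed by greedy zero-temperature
sweeps, so the returned partition is always a single-move local optimum
and the Hamiltonian never increases once the temperature reaches zero.
On networks up to 8 nodes the result matches exhaustive search over all
set partitions; on the calibrated synthetic fit it returns 3 communities
(minority status–depression–victimization–drinking; conduct–peer–
substances; support–parents), stable across seeds.

## Person communities: signed Louvain with consensus

Individuals are compared by `person_similarity()`: each outcome is
z-scored against the **full cohort** (so minority profiles are
population-referenced; referencing within the minority subsample is the
flagged alternative, selectable by passing a pre-subset table), and the
similarity of two individuals is the Pearson correlation of their
z-profile vectors. The minority-status indicator itself is excluded — it
is constant within the clustered subsample.

`louvain_signed()` maximizes the *asymmetric* signed modularity: the
positive part is normalized by the total positive weight $v^+$, the
negative part enters as $-\big(\sum_{in}(w^- - e^-)\big)/(v^+ + v^-)$
with its null $e^-$ normalized by $v^-$. The asymmetry reflects that
negative similarity should discourage co-assignment without dominating
the objective. Aggregation keeps self-loop (within-community) weight in
node strengths — dropping it corrupts the null model at coarse levels and
over-merges (a bug class worth naming because it produces silently
plausible single-community output on large matrices).

`consensus_cluster()` wraps the stochastic Louvain in the standard
agreement-matrix loop: run `iterations` seeds, form the co-assignment
frequency matrix, zero entries below `tau = 0.5`, re-cluster, and stop
when all runs agree — equivalently when the agreement matrix is exactly
0/1 block-diagonal. `iterations = 1000` follows the upstream analysis
convention; the acceptance harness uses 100 (the consensus on the
planted fixtures is already unanimous after one round, so extra
iterations only re-confirm it). The final modularity is reported on the
*original* similarity matrix, not the agreement matrix.

# Bootstrap inference

`bootstrap_edges()` resamples rows with replacement and refits the whole
MGM per replicate ("1000 permutations" in the source literature denotes
exactly this nonparametric case-resampling bootstrap). Edges absent in a
replicate contribute 0 to that replicate's draw; confidence intervals are
percentile (not BCa), per the methodology this workflow cites.
`edge_difference_test()` declares two edges different when the
percentile interval of the difference of their bootstrap draws excludes
zero; comparing an edge to itself yields the degenerate interval
$[0, 0]$, which *contains* zero, hence never significant.
`centrality_stability()` implements the case-dropping bootstrap: the
CS-coefficient of an index is the largest drop proportion at which the
subsample–full-sample correlation stays ≥ 0.7 in ≥ 95% of replicates.

# Group statistics

`welch_t()` is the unequal-variance t-test with Welch–Satterthwaite
degrees of freedom. The choice of the Welch variant over the pooled test
is forced by the data it must reproduce: recomputing from the published
group summaries (minority vs heterosexual means, SDs and ns) matches the
printed statistics for depression, peer problems and victimization to
within rounding under Welch but not under pooling. The printed conduct
problems row (t = 2.44 alongside an uncorrected p of 0.007) is internally
inconsistent under any two-sided test and is left unreconciled. The sign
convention subtracts the minority mean from the heterosexual mean, so
minority-worse outcomes give negative t. Bonferroni correction uses
`p_adjusted = min(1, m * p_raw)` with `m = 9` comparisons by default.
`z_profiles()` returns group (optionally stratum) means of full-sample
z-scores — the plot-ready profile data.

# Pipeline, sizes and limitations

`run_pipeline()` chains the stages (fit → predictability → metrics →
spinglass → bootstrap → group statistics → minority-subset consensus) with
one seed driving every stochastic stage, writes all artifacts (edge list
CSV, GraphML, centrality CSV, path JSON, CI CSV, group and profile CSVs,
partition JSON) plus a manifest with versions, configuration and an MD5
configuration hash; a rerun from the same manifest reproduces every
number bit for bit. A stratifier column (e.g. sex) reruns the network
stages per stratum without entering any network as a node.

Problem sizes used by the validation harnesses were chosen to keep the
full suite in the low minutes on one CPU while leaving the statistical
conclusions unambiguous: structure recovery at $n = 8000$, generator
fidelity at $n = 10000$, bootstrap harnesses at $n = 2000$ with $B =
200$, subgroup recovery at the study's minority size $n = 490$ with 100
consensus iterations, and Gibbs scans of 50–300 where convergence
diagnostics show that suffices.

What passing tests on synthetic cohorts does **not** show: the generator
draws from the same parametric family the estimator assumes, with
continuous (not few-level ordinal) substance-use scores, no missingness
(complete cases are enforced at ingest), no survey weights or attrition,
and group standard deviations equal across groups within each variable.
Real questionnaire data violate all of these to some degree, so the
synthetic results certify the *machinery* — estimator, algorithms,
inference plumbing — rather than robustness to real-data pathologies.
The published real-data quantities that depend on the restricted cohort
microdata (the 0.51 minority–depression edge, the exact predictability
table, the four-community node partition, person-cluster modularity 0.42
and subgroup sizes 148/157/185) are structural reference points here, not
reproduction targets; the package's own headline numbers are recomputed
from scratch by `scripts/acceptance.R`.
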