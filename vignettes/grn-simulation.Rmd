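---
title: "Simulating gene regulatory networks and in silico knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gene regulatory networks and in silico knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnforge)
```

`grnforge` simulates gene regulatory networks (GRNs) end to end: it grows
directed scale-free network structures with modular group organisation,
places a stochastic gene-expression model on top of them, knocks out every
gene in turn, and summarises the resulting perturbation-effect
distributions the way genome-scale Perturb-seq analyses do. This vignette
documents the model, its parameters and defaults, the numerical choices,
and what the synthetic data can and cannot say about real experiments.

## The network generator

Networks grow by preferential attachment. The seed graph has `k` isolated
nodes, one per group. Each growth step either adds a node (probability
`p`) that receives one incoming edge, or adds an edge between existing
nodes. Sources are drawn with weight proportional to
`out_degree + delta_out`, targets with weight proportional to
`in_degree + delta_in`, and candidates in the anchor node's group have
their weight multiplied by the affinity `w`. Growth stops at `n` nodes.

The parameters tune interpretable structural properties:

* `p` — sparsity: the mean number of regulators per gene is ~`1/p`
  (each added node brings one edge and a `1/p - 1` expected tail of
  edge-only steps).
* `k`, `w` — modularity: under uniform random group assignment the
  expected within-group edge fraction is `w / (w + k - 1)`; `k = 1` or
  `w = 1` dissolves group structure and recovers the classic ungrouped
  directed preferential-attachment model.
* `delta_in`, `delta_out` — degree dispersion: small offsets make the
  selection weights degree-dominated, producing heavy-tailed (hub-rich)
  in-/out-degree distributions; large offsets flatten them. The
  coefficient of variation of the out-degree distribution decreases
  monotonically in `delta_out`, and likewise for the in-degree pair.

Two conventions deserve a note because the growth process could be wired
several ways:

* *Orientation.* Each selection reinforces the degree it increments:
  sources are chosen by out-degree, targets by in-degree. This is the only
  wiring in which `delta_out` tunes the out-degree tail and `delta_in` the
  in-degree tail, which is how the package (and the validation tests)
  interpret those knobs.
* *Single affinity application.* The group affinity multiplies exactly one
  endpoint choice per edge — the source when a new node is the anchor, the
  target (relative to the already-chosen source) for edges between
  existing nodes. Applying it twice would square the within-group odds and
  break the `w / (w + k - 1)` expectation.

Self-loops and duplicate edges are disallowed: the endpoint is resampled
up to 100 times, then the whole growth event is resampled; 1000
consecutive failed events raise an error, which only happens in saturated
regimes (requested edge count close to the number of distinct ordered
pairs). Group labels of new nodes are uniform random, so realised group
sizes are multinomial rather than balanced.

```{r generator-demo}
g <- generate_network(graph_params(n = 500, k = 10, w = 9, p = 0.5,
                                   delta_in = 100, delta_out = 3, seed = 1))
degree_summary(g)
```

## The expression model

Each gene `i` carries a baseline synthesis offset `alpha_i` and a decay
rate `ell_i`; each regulatory edge `j -> i` carries a signed weight
`beta_ji`. Expression evolves by Euler–Maruyama steps of

```
x' = x + dt * (sigmoid(alpha + t(beta) %*% x) - ell * x)
       + s * sqrt(dt * x) * z,     z ~ N(0, I)
```

with `dt = 0.01` and global noise `s = 1e-4` by default. The saturating
sigmoid keeps synthesis rates in `(0, 1)`, expression is floored at zero
after each step (the multiplicative noise can otherwise produce tiny
negative excursions near `x = 0`), and any deterministic steady state
satisfies `x* = sigmoid(alpha + t(beta) %*% x*) / ell`.

Parameters are sampled as follows (`sample_expression_params()`):

* `sigmoid(alpha) ~ Beta(2, 8)` — genes are lowly but non-trivially
  expressed without regulation.
* `ell ~ Beta(8, 2)`, then hard-clipped from below at `exp(-alpha)`.
  Because `alpha` is almost surely negative, the clip almost always binds,
  so `ell > 1` for most genes and the maximum attainable expression
  `1/ell` is capped at `exp(alpha)`, the odds of the gene's baseline
  activation. This cap matters beyond bounding expression: it keeps the
  sigmoid input `alpha + sum(beta * x)` in its responsive range even for
  genes with many regulators. Without it, densely regulated genes saturate
  (`sigmoid -> 1`), knockouts of single regulators barely move their
  targets, and dense networks become inert — the opposite of the
  behaviour the screens below are designed to study. The Euler step
  remains well-behaved since `dt * ell` stays far below the stability
  boundary for all but astronomically rare draws.
* Each regulator is an activator with probability 0.8; the sign is drawn
  once per regulator and shared across its outgoing edges, while the
  magnitudes `|beta| = 1 + |N(0, 1)|` are per-edge, so every interaction
  has at least unit strength.

### Steady-state detection

Simulations start from all-zero expression, discard `b = 5000` burn-in
iterations, and then accumulate running means. Every `h = 1000` iterations
the running mean is compared with its snapshot from the previous check via
the maximum absolute log2 fold-change over genes whose running mean
exceeds the noise floor `s`; the system is converged when this falls below
`1e-3`, with a hard cap of 20000 iterations. Two details:

* The first *comparable* check happens at `b + 2h` iterations (before
  that the lagged mean is undefined), so a converging run uses at least
  7000 iterations.
* If no gene exceeds the noise floor the maximum is vacuous and the
  system is declared converged: an all-silent network is at rest.

A converged equilibrium can additionally be assessed for linear stability
(`stability_analysis()`): the Jacobian
`J[i, j] = beta_ji * sigmoid'(u_i) - (i == j) * ell_i` is built at the
steady state and the equilibrium is stable when all eigenvalues have
negative real part.

## Knockout screens

A knockout of gene `j` zeroes row `j` of `beta` (equivalently, it nullifies
`j`'s outgoing regulation). `knockout_screen()` re-equilibrates every
knockout from the baseline steady state under the same
burn-in/convergence protocol and records

```
log2FC[j, i] = log2(xbar_i | KO j) - log2(xbar_i)
```

for all `i != j`. Genes whose baseline expression is below `s` are dropped
from all downstream summaries (their measured expression is noise);
post-knockout means are floored at machine epsilon before the log. Each
knockout runs on an RNG stream derived from `(seed, j)` — the screen is
bitwise identical to one-at-a-time `simulate_to_steady_state()` calls on
matching streams, which the tests exploit.

Downstream summaries follow the conventions of pooled perturbation
studies:

* `hub_counts()` — a *hub KO* changes at least 100 other expressed genes
  by more than 0.1 absolute log2 fold-change; a *hub target* is changed by
  at least 100 knockouts. Thresholded summaries use `|log2FC|`: a
  repressor knockout that doubles its target counts just as an activator
  knockout that halves it.
* `stratify_effects()` — effects partitioned by directed shortest-path
  distance (direct = distance 1; mediated = everything else) and by group
  co-membership.
* `effect_fractions_from_screen()` — per-gene fractions of the analyzed
  network affected by / affecting a gene, with the discovery rate fixed at
  the top 3.16% of absolute effects to mirror the share of significant
  pairs in the reference experimental analysis. The threshold is the
  `(M - ceiling(rate * M))`-th order statistic with strict exceedance;
  ties at the threshold (measure-zero for continuous effects) are not
  called.

## Comparison with experimental effect tables

`load_pairwise_pvalues()` ingests a perturbation-by-gene table of
FDR-corrected p-values (gzip CSV, ENSEMBL IDs), keeps perturbations whose
target is itself measured, and arbitrates duplicate perturbations of one
gene by their significance on their own transcript.
`effect_fractions_from_pvalues()` thresholds at p < 0.05, and
`match_report()` compares each simulated network's outgoing and incoming
effect-fraction distributions with the reference via the two-sample
Kolmogorov–Smirnov test, ranking networks by p-value on both axes and
selecting the smallest rank `r` at which the requested number of networks
is in the top `r` of both lists. Expression-level filtering of the
external table is assumed done upstream by the data provider; the p-value
comparison is asymptotic by default (an exact option exists for small
samples).

## Gene programs and cross-dataset concordance

`assemble_cells()` builds mixed cell populations mimicking a pooled
knockout experiment: by default 75,328 cells of which 8.1% are unperturbed
and the rest are assigned uniformly at random across knockout conditions
(~35 cells per condition for 2000 genes). Baseline cells are consecutive
SDE states from the steady state; each condition's cells are consecutive
post-convergence states of its re-equilibrated dynamics. The sampling
protocol for perturbed conditions is the package's own choice — consecutive
stationary states, matching how baseline cells are drawn — since pooled
experiments do not dictate a unique simulated analogue. For program-level
analyses the noise is raised to `s = 0.3`: at the default `1e-4` the
between-cell variation is too small for dimensionality reduction to be
meaningfully comparable with single-cell data.

Cells are z-normalised per gene, decomposed with `truncated_svd()` (top
200 components by default), and each gene singular vector defines a
*program*: its 100 genes with the largest squared loadings (ties broken by
gene index; programs of different components may overlap).
`program_overlap()` reports, per reference program, the maximum gene-count
overlap with any program of another decomposition, and `cca()` computes
canonical correlations between two loading matrices. Since truncated-SVD
loadings are orthonormal, whitening is the identity and the canonical
correlations are exactly the singular values of `t(V) %*% V'`; inputs that
are not orthonormal are orthonormalised by QR first, making the result
invariant to orthogonal rotation of either input.

## Evaluating pairwise statistics as edge predictors

`build_pair_table()` joins, per ordered gene pair, the ground-truth edge
indicator and weight with the knockout effect, the coexpression (Pearson
correlation across sampled cells), and the network distance.
`edge_enrichment()` measures how strongly the top quantile by either
statistic concentrates true edges, and `rank_correlations()` reports the
Spearman correlations of the two statistics with edge weights and with
each other. `hub_fraction_regression()` regresses empirical-logit hub
fractions on the generator knobs `1/p`, `k'`, `w`, `delta_in`,
`delta_out`, where `k' = n` recodes single-group networks (dissolved group
structure is equivalent to one group per gene). Boundary fractions use the
standard empirical-logit correction `(count + 0.5) / (n + 1)`.

## Problem sizes, defaults and reproducibility

The bundled study driver `run_screen_study()` runs the full
generate–equilibrate–screen pipeline over 13 fixed generator
configurations chosen to stratify every knob across its grid of interest
(`study_configs()`): six networks feed pooled effect-distribution
summaries and nine heavy-tailed out-degree (`delta_out = 1`) networks feed
the hub-knockout median. The driver uses networks of `n = 500` genes —
the same scale at which the generator's structural properties are
validated — with the hub *count* threshold scaled proportionally
(`round(100 * n / 2000) = 25`) so that "hub" keeps its meaning as a fixed
fraction of the network; effect thresholds are dimensionless and
unchanged. A full screen at this scale is ~2000 gene-equilibrations of
~7000 steps each and completes in well under a minute per network on one
core; the 13-network study takes on the order of ten minutes.

All randomness is seeded. Graph generation and parameter sampling use R's
RNG under a locally restored state; the SDE noise uses an internal
xoshiro256++ generator with a ziggurat normal sampler, with per-condition
streams derived from `(seed, stream)`, so results are reproducible
bit-for-bit across platforms and independent of the caller's RNG state.

## What the synthetic data do and do not capture

The generator produces directed scale-free graphs with tunable sparsity,
modularity and degree asymmetry — the structural backbone of regulatory
networks — but groups are pre-assigned labels rather than emergent
functional modules, group sizes are random, and there is no explicit
hierarchy, cell-type mixture or developmental trajectory. The expression
model is intentionally minimal: quantitative, saturating, with
multiplicative noise, but with no transcription/translation two-stage
kinetics, no measurement or count noise, and knockouts only (knockdowns,
overexpression, enhancer edits and noise edits are natural extension
points of the same update rule but are not implemented). Passing tests
therefore demonstrate internal consistency of the simulation-and-analysis
pipeline and qualitative agreement of its effect distributions with
genome-scale perturbation data — not that any particular biological
network is captured.

Known limitations worth keeping in mind:

* Pooled effect statistics depend on network size: smaller networks have
  shorter path distances and relatively fewer unreachable pairs, which
  shifts distance-stratified summaries relative to very large networks.
* Non-converged re-equilibrations (oscillatory regimes, most common in
  dense, low-noise networks) are flagged per knockout and retained, as the
  capped-iteration running mean is still the protocol's defined output.
* The KS-based best-match ranking is a relative criterion; with enough
  samples every synthetic network is statistically distinguishable from
  experimental data.
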