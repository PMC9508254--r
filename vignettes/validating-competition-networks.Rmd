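---
title: "Validating tree competition networks with spatial null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating tree competition networks with spatial null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Individual-based networks are an appealing way to describe competition in a
forest stand -- every tree is a node, every plausible interaction an edge --
but a network definition is a modelling choice, and a metric computed on it
is only useful if it actually responds to the ecological process one wants
to detect. This package implements a validation workflow for that question:
simulate stands under contrasting spatial null models, build the candidate
networks on each simulated stand, and keep only the metrics whose
distributions separate the processes.

```{r setup, eval = FALSE}
library(crownet)
```

## The three networks

For trees at positions $P_i$ with crown radii $R_i$ (crowns modelled as
disks):

* **CS** (competition for space): undirected edge whenever
  $\lVert P_i - P_j \rVert < d_{\max}$, with $d_{\max} = 10$ m by default,
  a common rough extent of tree-tree interaction.
* **CL** (competition for light): undirected edge whenever the crowns
  overlap, $\lVert P_i - P_j \rVert < R_i + R_j$.
* **WCL**: the CL graph with each overlap split into two directed edges.
  The edge from tree $i$ to tree $j$ carries the competition index
  $CI_{ij} = R_{ij} \, R_i / R_j$, where
  $R_{ij} = (R_i + R_j) - \lVert P_i - P_j \rVert$ is the overlap depth.
  The larger crown exerts the larger index, and
  $CI_{ij} \cdot CI_{ji} = R_{ij}^2$.

Ties at the threshold are *not* connected (strict inequalities), coincident
treetops are allowed, and trees without a crown measurement are dropped
from CL/WCL (never from CS) with the dropped count recorded -- that is the
only mechanism by which the CS and CL node counts of the same stand can
differ.

Per network we compute the node count $N$, edge count $E$, average degree
$k = 2E/N$, density $D = 2E/(N(N-1))$, average shortest-path length $L$ and
clustering coefficient $C = \frac1N \sum_i 2e_i / (k_i(k_i-1))$ (nodes with
$k_i < 2$ contribute zero). Edge weights never enter $C$, $D$ or $L$, so
for WCL those three equal the CL values; the weighted average degree
substitutes the summed edge weights for $E$ in $k = 2E/N$. Because "sum of
edge weights" is ambiguous on a directed graph, the factor of 2 is a
configurable choice (`weighted_degree_factor`, default 2, i.e. the sum over
both directions divided by $N$ equals the mean total node strength).
Average path length averages hop counts over *connected* pairs only --
sparse null realizations are routinely disconnected and the alternative
(infinite or $N$-dependent penalties) would make $L$ useless as a summary;
the connected-pair count is reported alongside. A directed-path variant is
exposed (`net_path_length(mode = "directed")`), though for WCL every edge
is mutual and it coincides with the skeleton value; tabulated WCL path lengths
in the literature sometimes differ from their CL counterparts for reasons
that cannot be reconstructed from counts alone, so neither variant is
declared canonical here.

## The five null models

All models run in a rectangular window (default 200 m x 200 m) with target
intensity $\kappa = 0.015$ trees/m^2:

* **CSR**: homogeneous Poisson.
* **Matern cluster**: Poisson parents, each with a Poisson($\mu = 3$)
  number of offspring placed uniformly in a disc of radius $r_d = 5$ m;
  parents die. Parents are simulated in the window dilated by $r_d$ so the
  border is not thinned.
* **Thomas cluster**: as Matern with an isotropic Gaussian kernel.
* **Gibbs hard core**: pairwise-interaction process forbidding pairs closer
  than $r_g = 4$ m.
* **Strauss**: softened inhibition; a configuration with $s$ close pairs
  has density proportional to $p^{s}$ with $p = 0.5$.

Crown radii are attached by random labelling -- i.i.d. marks, uniform on
2-5 m for the batteries, independent of location -- so the networks differ
across models only through the point geometry.

Three conventions deserve explanation because the verbal model
descriptions do not pin them down:

* **What $\kappa$ counts in the cluster models.** We take $\kappa$ as the
  intensity of the *total* pattern (parents at $\kappa/\mu$), so all five
  models realize about $\kappa \lvert W \rvert \approx 600$ trees and their
  networks are comparable at equal stocking; `kappa_is = "parents"` gives
  the literal parents-at-$\kappa$ reading (offspring intensity
  $\kappa\mu$). The total reading is also what makes the documented
  envelope separation from CSR robust: the scaled excess of Ripley's K for
  a Thomas process saturates at $\mu/\kappa$ (total reading) versus
  $1/\kappa_{\text{parent}}$, and only the former keeps the Thomas lower
  envelope above the CSR upper envelope all the way to 15 m.
* **The Thomas scale.** Only $r_d$ is specified for both cluster models.
  Matching $\sigma = r_d$ (or even moment-matching the disc) makes the
  Thomas process *more* diffuse than Matern and inverts the documented
  edge-count ordering: with $d_{\max} = 2 r_d$ the fixed-radius graph
  counts essentially every within-cluster pair under either kernel (a
  convolution preserves the total mass of the pair-distance distribution),
  so only a clearly tighter Gaussian lets Thomas dominate through the
  crown-overlap graph. We read $r_d$ as the effective maximum dispersal
  distance and set $\sigma = r_d/4$ (99.99% of offspring within $r_d$),
  mirroring the hard bound of the Matern disc; `sigma` is a free argument.
* **Gibbs simulation.** The inhibition processes are sampled by the
  standard birth-death Metropolis-Hastings chain (in C) with activity
  $\beta = \kappa$ and interaction $\gamma \in \{0, p\}$, 1e5 steps from a
  CSR start. Their realized intensity is therefore *below* $\kappa$
  (about 0.0093 for the hard core, 0.0113 for Strauss at the defaults, as
  mean-field theory predicts) -- that thinning is part of what inhibition
  means and is what pushes the Gibbs degree ranges cleanly below CSR. A
  conditional variant (`n_mode = "fixed"`: exactly
  $\text{round}(\kappa\lvert W\rvert)$ points, relocation chain) is kept
  for experiments where the count must be held fixed; note it weakens the
  group separation. Hard-core results are guaranteed conflict-free: the
  chain continues in chunks until no pair violates $r_g$ and errors after
  a million fruitless extra steps.

## Second-order statistics

`ripley_k()` implements
$\hat K(r) = \frac{\lvert W\rvert}{N(N-1)} \sum_{i \ne j} e_{ij}
\mathbf 1[d_{ij} \le r]$ with Ripley's isotropic edge correction by default
(the exact circle-fraction geometry for a rectangle; translation and
uncorrected variants by flag), `besag_l()` the variance-stabilising
$L = \sqrt{K/\pi}$ with an optional centred $L - r$, and `pcf()` the
kernel estimator of the pair correlation function $g$ with an Epanechnikov
kernel and Stoyan's bandwidth $h = 0.15/\sqrt{\hat\lambda}$. The default
$r$ grid has 513 points from 0 to a quarter of the shorter window side --
beyond that the estimators warn. `mc_envelope()` returns the pointwise
minimum and maximum of the statistic over `n_sim = 199` simulations (a
rank-1 min-max band, no global correction), optionally with an observed
curve and with the null intensity re-estimated from the data.

## The validation battery and verdicts

`run_null_battery()` crosses the five models with 199 replicates and all
three networks (5 x 199 x {CS, CL} = 1990 undirected plus 995 directed
networks per run). Replicate $i$ of *every* model uses seed
$\text{seed} + i$, which makes batteries reproducible bit-for-bit and, as
a useful side effect, pairs the models on common random numbers so that
between-model contrasts are sharper than independent seeding would give.
Failed replicates (a non-converging chain) are retried once with a
deterministic fallback seed and then dropped with a warning -- never
silently resampled.

`compare_models()` runs a classical one-way ANOVA across models followed by
Tukey's HSD on all ten model pairs, and separately reports whether each
pair's simulated min-max ranges overlap. Practitioners often judge
metrics by eye from range overlap plus these tests; the operational rule in
`classify_metric()` labels a metric *distinguishing* when every
cross-group pair (cluster vs random vs Gibbs) is Tukey-significant **and**
has disjoint ranges. Both ingredients are exposed so users can apply a
different rule. ANOVA is kept on the raw metric distributions (they are
not exactly normal; the classical test is the field's customary choice), `aov()` is the
classical rather than Welch variant, and zero-variance degenerate groups
produce a warning with an unusable p-value rather than an error.

`empirical_vs_null()` closes the loop for a real stem map: $\kappa$ is
estimated as the observed density, crown radii are replaced by draws from
a maximum-likelihood gamma fit of the observed radii, the battery is run
on the stand's own window, and each observed metric is reported as a
percentile of each model's simulated distribution plus an in-range flag.

## Spatial fields of node metrics

`node_metrics()` returns per-tree degree, strength and betweenness
(shortest-path betweenness on the unweighted skeleton, unnormalised,
endpoints excluded -- the convention under which the centre of a 3-node
path scores exactly 1). `interpolate_metric()` fits a thin-plate
regression spline (`mgcv::gam`, smoothness by GCV unless an explicit
`sp` is given; `smoothing = 0` with a full basis reproduces the data at
the tree locations) and evaluates it on a regular grid, 2 m spacing by
default, to map where competition concentrates.

## What the generators do and do not emulate

The simulators reproduce the *geometry* of stands assembled by dispersal
limitation, randomness, or competitive exclusion at realistic densities
(0.015 trees/m^2, crowns 2-5 m), and random labelling deliberately severs
any crown-location dependence. Real stands violate several of these
idealizations: crown size correlates with local crowding and species, tree
density is rarely homogeneous across a hectare, crowns are not disks, and
inhibition and clustering operate simultaneously at different scales. A
metric that separates the null models is therefore *capable* of detecting
those processes in isolation; passing the battery does not mean it
decomposes their mixture in real data.

## Problem sizes and numerical choices

The shipped tests run the full 5 x 199 battery (about 600 trees per
pattern, roughly four minutes on one core) plus a reduced 50-replicate
battery for the ordering checks; the second-order checks use 99 CSR
replicates and 49-simulation envelopes. Monte-Carlo tolerances in the
tests are derived from replicate standard errors, not tuned constants.
Gamma fitting requires at least 10 positive radii and refuses
(near-)constant data, where the MLE diverges. K is evaluated by sorted
cumulative weights (identical arithmetic to the naive double loop up to
summation order, which the oracle tests bound at 1e-9), and the isotropic
correction is the exact rectangle geometry, verified against numerical
circle-fraction integration.
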