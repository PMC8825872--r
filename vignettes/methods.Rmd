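---
title: "Methods: graph-attention variational autoencoders for single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-attention variational autoencoders for single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`scvgae` embeds single cells with a variational graph autoencoder (VGAE)
whose encoder is built from multi-head graph-attention (GAT) layers. The
inputs are a cells-by-genes expression matrix **X** (used as node features)
and a simple undirected cell graph **A** (no loops, no multi-edges) that
encodes which cells are transcriptionally close. The posterior over each
cell's latent coordinate is a diagonal Gaussian,

$$ q(z_i \mid X, A) = \mathcal{N}(z_i \mid \mu_i, \operatorname{diag}\sigma_i^2), $$

whose parameters are produced by two parallel attention layers on top of a
shared stack of inner attention layers:

* inner layers concatenate their $K$ heads, so layer $i$ outputs $K \cdot D_i$
  features; ReLU is applied **between** layers (the first layer consumes the
  raw features, outputs are left linear),
* the two output layers average their heads and emit $\mu$ and
  $\log\sigma$, each $N \times L$.

Each attention head scores ordered cell pairs over the node's
neighbourhood *plus itself* with
$e_{ij} = \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])$, normalizes the
scores row-wise with a softmax into coefficients $\alpha_{ij}$, and
aggregates $\sum_j \alpha_{ij} W h_j$. The self-loop is added for attention
only — the graph itself stays simple — because a cell's own expression
should always be allowed to inform its embedding, and self-attention is
routinely observed to carry weight in trained models. A GATv2 variant
(nonlinearity before the attention vector) and a symmetric-normalized GCN
layer are provided through the same interface.

The decoder is the parameter-free inner product: the probability of an
edge is $\sigma(z_i^\top z_j)$. Only the graph is reconstructed by
default; an optional linear feature-reconstruction head adds an MSE term.

## Losses

* **Edge reconstruction**: binary cross entropy over the observed edges and
  an equal number of uniformly re-sampled non-edges per epoch, averaged
  over all scored edges jointly. Decoded probabilities are clamped to
  $[10^{-15}, 1-10^{-15}]$ so the loss stays finite for any parameters.
* **Regularization**: either the closed-form KL divergence from the
  standard-normal prior (mean over cells, summed over latent dimensions) or
  a biased Gaussian-kernel MMD estimate against prior draws (bandwidth
  defaults to the latent dimension; a median heuristic is available).

### KL weighting

The KL term enters the training objective scaled by $1/N$ (cells), the
convention of the original VGAE reference implementation. This is a
deliberate deviation from a unit weight: with the mean-per-cell KL at
weight 1, shrinking $\sigma$ below 1 costs far more than edge
reconstruction can recover on KNN-scale graphs, and the optimum is
posterior collapse ($\mu \to 0$, $\sigma \to 1$, reconstruction stuck at
chance) — we verified this directly. `kl_loss()` itself reports the
unweighted mean-per-cell divergence; the weight is a `training_config`
field (`reg_weight`, `NULL` = automatic: $1/N$ for KL, 1 for MMD).

## Training

Full-graph Adam (default learning rate $10^{-3}$, 200 epochs), one
gradient step per epoch, fresh negative edges every epoch. Gradients are
computed by hand-derived analytic backpropagation through the attention
layers, the reparameterization $Z = \mu + e^{\log\sigma} \odot \varepsilon$
and all loss terms; the test suite verifies them against central finite
differences to $10^{-4}$ on a toy model (they agree to $\sim 10^{-11}$).
The embedding handed to downstream analysis is the posterior mean $\mu$,
not a sample, so clustering and interpretation are deterministic given a
trained model. All randomness — initialization (Glorot uniform),
negative sampling, noise draws, holdout splits — derives from the single
config seed; identical configurations reproduce byte-identical outputs.
An optional held-out edge fraction is scored each epoch by ROC-AUC of the
decoder against an equal number of non-edges, for convergence monitoring.

# Preprocessing and graph construction

Counts are scaled per cell to a common total (default 10 000) and
`log1p`-transformed; features are then min-max scaled per gene to
$[0, 1]$. Constant genes map to all-zeros rather than an arbitrary
constant — they carry no signal and should not inject a bias feature.

Highly variable genes are ranked by dispersion (variance/mean) **on the
log-normalized values, before min-max scaling**. The order matters: min-max
scaling equalizes per-gene variance, after which variance/mean simply
favours low-mean noise genes and the ranking is meaningless. Ties break to
the lower gene index so selection is deterministic and invariant to cell
order. Dispersion on log-normalized data is one of several defensible HVG
criteria; it is the simplest deterministic one and is exposed as the
package's single criterion rather than a configurable family.

The cell graph connects each cell to its $k$ nearest neighbours (default
$k = 5$) under Euclidean, Manhattan, cosine or Pearson distance
($1 - r$; ranking by $1 - r$ and by raw $r$ are equivalent). The graph can
be built on a separate HVG subset (`khvg`) and optionally on a PCA
projection. Directed neighbour lists are symmetrized **by union**: an edge
survives if either endpoint selects the other. Union preserves
connectivity (mutual-KNN graphs fragment sparse regions), which matters
because the decoder can only learn from edges that exist. Neighbour ties
break to the lower cell index. Indices are 1-based inside the package
(idiomatic R); edge-list files are 0-based at the I/O boundary, matching
the convention of external graph tools.

# Clustering

The latent means are clustered with HDBSCAN, implemented natively in the
package: mutual-reachability distances (core distance = distance to the
`min_samples`-th neighbour, self included), exact Prim MST, single-linkage
hierarchy, condensation at `min_cluster_size`, and excess-of-mass cluster
selection. Cells that never join a selected cluster are noise
(label $-1$); cluster labels are contiguous from 0. The implementation is
cross-checked in the test suite against scikit-learn's HDBSCAN on a mixed
fixture (identical labels). Defaults: `min_cluster_size = max(5, 0.5%)` of
cells, `min_samples = min_cluster_size`. Degenerate input with all points
identical is a single cluster by definition. The hierarchy root is not
selectable (standard practice), so data with no density structure comes
back as all noise rather than one meaningless cluster.

**Small-cluster rescue** re-runs the same clustering on the noise points
only, with a reduced minimum size, and appends any groups found as new
clusters. It never touches existing assignments, so the cluster count can
only grow. This is a conservative reading of "make sure tiny clusters are
not swallowed by noise": a tight clump among scattered noise is recovered,
but a clump that is the *entire* noise set cannot be (the root rule above);
widely spaced outliers stay noise.

## Metrics

The adjusted Rand index is computed from the contingency-table pair counts
(cross-checked against `mclust::adjustedRandIndex`). Noise handling is
explicit: `"drop"` (default) excludes cells unassigned by either labelling,
matching how density-based clusterings are usually compared against a
reference with noise reported separately; `"singleton"` makes each noise
cell its own cluster; `"keep"` treats $-1$ as an ordinary label. The
silhouette coefficient (noise excluded, Euclidean) delegates to
`cluster::silhouette`. Cluster overlap is
$100 \cdot |F \cap R| / |R|$ against the reference cluster; found clusters
are matched to reference labels by maximal overlap with ties to the
smaller reference label.

# Interpretability

* **Attention overlays** collapse the directed coefficients to one value
  per node. The default direction, `incoming`, averages the coefficients
  *received* by a node — how much the rest of the model draws on that
  cell — which is the reading under which influential small populations
  light up; `outgoing` (a node's own softmax row) is also exposed.
* **Top-n attention edges** keep the n largest coefficients as a weighted
  directed graph ($\alpha_{ij} \neq \alpha_{ji}$ is preserved), with
  deterministic lexicographic tie-breaks, plus node/weight-range filters.
  Pairing top coefficients with latent Euclidean distances shows whether
  attention merely mirrors latent proximity (it typically does not).
* **Weight products** chain the transposed linear maps of the encoder,
  $P_\mu = W_1^\top W_2^\top \cdots W_\mu^\top$ ($D \times L$), linking
  input genes to latent dimensions. Per-head blocks of inner layers are
  stacked to the concatenated width; the head-averaging output layers
  contribute their head-mean matrix. On a linear path (attention frozen,
  ReLU in its active regime) $P_\mu$ equals the encoder Jacobian — the
  test suite verifies this numerically.
* **Marker retrieval**: per cluster, latent dimensions are ranked by the
  cluster's mean absolute embedding value — the linking statistic is not
  uniquely determined by prior art, and this choice mirrors the established
  weight-analysis procedure for dense VAEs — and only the few most active
  dimensions (default 3) are kept: the per-dimension gene lists themselves
  do not depend on the cluster, so cluster specificity comes entirely from
  this restriction. Per kept dimension the top 15 genes by $|P_\mu|$ are
  collected and appearance counts accumulated. Genes appearing once but
  inside the global top-100 $|P_\mu|$ entries form a secondary list. On
  synthetic data the latent embedding itself tracks planted markers almost
  perfectly (by gene-latent correlation), while the weight products — a
  linearization of a nonlinear encoder — recover markers at clearly
  above-chance but far from perfect rates; the test suite logs this
  recovery rather than asserting a tight bound.
* **Learnt expression**: $E \cdot g$ with $g$ the gene's row of $P_\mu$
  gives a signed per-cell expression score; the sign is preserved
  (positive = learnt high expression).

# The synthetic-data generator

`generate_counts()` draws negative-binomial counts (variance
$\mu + \phi\mu^2$, default $\phi = 0.3$) around log-normal gene base means
(`sdlog = 0.4`, scale 8 — an expressed-gene panel rather than a whole
transcriptome), with each cluster's marker block (10 genes per cluster by
default) multiplied by `fold_change` (default 8) in that cluster only.
Balanced clusters by default; a `proportions` knob creates the
tiny-cluster regime used to exercise rescue. These defaults were fixed
once, on the criterion that planted markers should dominate the
highly-variable-gene ranking at fold change 8 — the regime the package is
designed to resolve. `generate_block_graph()` wraps a seeded stochastic
block model for link-prediction fixtures. The generator emulates
cluster-structured overdispersed counts only: no batch effects, no
library-size gradients, no doublets, no dropout beyond what the NB
produces, no gene-gene correlation within a cluster. Passing tests
therefore certify the machinery — preprocessing, graph construction,
optimization, clustering, interpretation — on data whose structure is
knowable, not performance on any real tissue.

The 2-block link-prediction fixture uses $p_{in} = 0.95$,
$p_{out} = 0.02$ on 30 nodes with 20% of edges held out. Dense blocks are
deliberate: with sparser blocks a large share of held-out negatives are
*within-block* non-edges that a correctly block-structured embedding
scores high, capping the attainable AUC well below 1 for reasons unrelated
to model quality.

# Problem sizes and numerical choices

The test suite and the acceptance script run at 300 cells x 500 genes for
the end-to-end recovery study (10 seeds, 200 epochs each), 30-node graphs
for link prediction, and 5-6-node graphs for oracle and gradient checks —
sizes at which every expected value can be verified by brute force or
closed form while the full workflow still exercises realistic code paths.
Other conventions: LeakyReLU slope 0.2 for attention scores; Glorot
uniform initialization; Adam $(\beta_1, \beta_2) = (0.9, 0.999)$,
$\epsilon = 10^{-8}$; negative:positive edge sampling 1:1; dropout is not
applied to attention coefficients (exposed nowhere — the small graphs the
package targets do not need it); divergent training (non-finite loss)
aborts with a diagnostic rather than continuing.

# Known limitations

* Full-graph dense attention is $O(N^2)$ memory per head; the
  implementation targets datasets up to a few thousand cells, not
  atlas-scale data.
* The HVG criterion is a single fixed convention; mean-binned dispersion
  methods may rank differently on data with strong mean-variance trends.
* The latent-dimension relevance statistic in marker retrieval (mean
  absolute embedding value) is the main fidelity risk for gene-report
  comparisons with other implementations of the same idea.
* ARI values depend on the noise-handling mode; comparisons across tools
  must state it. The default (`drop`) excludes unassigned cells, which
  flatters methods that declare many cells noise — the noise count is
  always reported alongside for that reason.
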