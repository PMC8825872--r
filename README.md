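# scvgae

Unsupervised embedding, clustering and interpretation of single-cell
RNA-seq data with a **variational graph autoencoder (VGAE)** whose encoder
is built from **multi-head graph-attention (GAT) layers**. The package is
aimed at analysts who want a dimensionality-reduction method that uses
cell-cell connectivity as an inductive bias — not just the expression
matrix — and that can afterwards be interrogated: which cells the model
attends to, which genes drive each latent dimension, and what the model
believes a gene's expression looks like per cell.

## The model

Cells are nodes of a simple undirected graph *A* (k-nearest-neighbour by
Euclidean distance, Pearson-correlation KNN, or user-supplied), with
log-normalized, min-max-scaled expression of the top highly variable genes
as node features *X*. The encoder maps each cell to a Gaussian posterior

q(z_i | X, A) = N(z_i | mu_i, diag(sigma_i^2)),

where mu and log sigma are produced by two head-averaging graph-attention
layers on top of a stack of head-concatenating inner layers. Attention
coefficients alpha_ij = softmax_j LeakyReLU(a^T [W h_i || W h_j]) are
computed over each node's neighbourhood plus itself. The decoder is the
inner product p(A_ij = 1) = sigmoid(z_i^T z_j); training minimizes
binary cross entropy over observed edges and sampled non-edges plus a KL
(or MMD) regularizer, by full-graph Adam with analytic gradients. The
deterministic embedding used downstream is the posterior mean mu.

The latent space is clustered with HDBSCAN (implemented natively:
mutual-reachability MST, condensed tree, excess-of-mass selection), with
unassignable cells reported as noise. Interpretability tools: per-node
attention overlays, top-n attention graphs, encoder weight products
P_mu = W_1^T W_2^T W_mu^T linking genes to latent dimensions, per-cluster
marker-gene reports, and learnt per-gene expression scores E·g.

Everything — including a negative-binomial synthetic-data generator with
planted marker genes and a stochastic-block-model graph generator — is
seeded and reproducible.

## Worked example

Three planted clusters, 300 cells x 500 genes, markers at 8-fold change;
Pearson-KNN graph with k = 5; 200 epochs of KL-regularized training:

```r
library(scvgae)

ds <- generate_counts(n_cells = 300, n_genes = 500, n_clusters = 3,
                      fold_change = 8, seed = 1)
ds
#> <synthetic_dataset> 300 cells x 500 genes, 3 clusters (seed 1)

ln       <- log_normalize(ds$counts)                     # CP10k + log1p
features <- subset_expression(minmax_scale(ln),
                              genes = select_hvg(ln, 250))
graph    <- build_knn_graph(features, k = 5, metric = "pearson")
graph
#> <cell_graph> 300 nodes, 1009 edges

fit <- fit_vgae(features, graph,
                training_config(latent_dim = 16, epochs = 200, seed = 1))
fit
#> <vgae_fit> 300 cells -> 16 latent dims | 200 epochs, final loss 0.6245

clusters <- cluster_latent(fit$embedding)
clusters
#> <cluster_assignment> 300 cells: 3 clusters, 3 noise

m <- clustering_metrics(fit$embedding, clusters, ds$true_labels)
sprintf("ARI vs planted labels: %.3f | silhouette: %.3f", m$ari, m$sc)
#> "ARI vs planted labels: 1.000 | silhouette: 0.805"
```

The model recovers the three planted clusters exactly (adjusted Rand
index 1.0 against the generative labels; 3 of 300 cells are left as
density noise) and the clusters are well separated in the latent space
(mean silhouette 0.81). Interpretation of the trained model:

```r
wp     <- model_weight_products(fit)        # P_mu, P_sigma: genes x latents
report <- ranked_genes(wp, fit$embedding, clusters,
                       gene_ids = features$gene_ids)
head(report$cluster_0$primary, 3)
#>       gene gene_index appearances max_weight
#> 1  gene_20         35           6  0.4079587
#> 2  gene_60        170           5  0.2724694
#> 3 gene_119        171           5  0.2778535

overlay <- node_attention_overlay(fit$attention, "incoming")
head(order(-overlay), 3)   # cells the model draws on most
#> [1] 106 268 270
```

Per cluster, the report lists genes by how often they appear among the
top weight-product entries of the cluster's most active latent dimensions
(`gene_20` is a planted marker of the cluster this label maps to);
`appearances` counts latent dimensions, `max_weight` is the gene's largest
|P_mu| entry. The attention overlay scores how much the rest of the model
attends to each cell.

The same workflow runs from the shell via the bundled CLI:

```sh
Rscript inst/scripts/run_scvgae.R --input counts.csv --graph pknn --k 5 \
  --hvg 250 --khvg 250 --latent 16 --epochs 200 --seed 1 --outdir out/
```

which writes embeddings, cluster labels, metrics JSON, the attention
record, the gene report and a run log (each stamped with the config hash).

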