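# zinbclust

Semisupervised deep clustering of single-cell RNA-seq count matrices.

Clustering scRNA-seq data is hard for three reasons: the data are
high-dimensional, extremely sparse, and contain "false" zeros from dropout
events (transcripts that were expressed but not captured). `zinbclust`
addresses all three with a zero-inflated negative binomial (ZINB) denoising
autoencoder coupled to deep embedded clustering in the latent space, and —
when a fraction of cells carries known type labels — sharpens the clustering
with three semisupervised constraint losses. It is aimed at analysts who have
a counts matrix, know (or can estimate) the number of cell types, and hold
partial labels for a subset of cells, e.g. from a curated atlas or marker
scoring.

## Model

Each count `X[i,j]` is modeled by a ZINB mixture

    P_ZINB(x | pi, mu, theta) = pi * I(x = 0) + (1 - pi) * NB(x | mu, theta)

whose three parameters (dropout probability `pi`, mean `mu`, dispersion
`theta`) are produced per cell and gene by the three output heads of a
symmetric autoencoder (widths 256-128-32-128-256, ReLU, linear bottleneck).
The reconstruction loss is the mean ZINB negative log-likelihood on the raw
counts, with the mean head scaled by per-cell size factors.

Clustering happens in the 32-dimensional latent space with K learnable
centers:

* a weighted soft K-means loss with Gaussian-kernel weights and an annealed
  temperature,
* a KL loss `KL(P || Q)` between the Student's-t soft assignment `Q` and its
  sharpened, frequency-normalized target `P` (the DEC construction).

A stratified fraction `r` of cells (default 10%) is treated as labeled and
feeds three constraint terms:

* a triplet hinge on assignment similarities `s(a,b) = sum_j q_aj q_bj`:
  `max(s(A,N) - s(A,P) + alpha, 0)` over sampled (anchor, positive,
  negative) triples (default 10000, margin `alpha` = 0.1),
* a must-link/cannot-link binary cross-entropy between the cosine similarity
  of assignment rows and the label-agreement matrix,
* a class-weighted cross-entropy (inverse-frequency weights) that protects
  rare cell types, routed through a Hungarian cluster-to-class alignment.

The full objective is

    L = L_ZINB + g1 (L_SoftK + L_KL) + g2 L_Triplet + g3 L_Pairwise + g4 L_WCE

optimized with AdaDelta (lr 1.0, rho 0.9, batch 256) after 300 epochs of
ZINB-only denoising pretraining, until cluster assignments stabilize.

The package also ships a splat-style count simulator (gamma gene means,
per-group DE factors, log-normal library sizes, NB counts, logistic
dropout) with presets `splat1`..`splat5`, and the four standard agreement
metrics (NMI, ARI, AMI, Hungarian-matched ACC).

## Worked example

```r
library(zinbclust)

# simulate a small group-structured dataset (4 imbalanced groups)
cm <- simulate_splat(splat_params(n_cells = 500, n_genes = 500,
                                  group_prob = c(0.05, 0.1, 0.2, 0.65),
                                  de_fac_loc = 1.0, lib_loc = 8, seed = 101))
pd <- preprocess(cm)

# treat 10% of the true labels as known, build constraints, fit
cfg <- train_config(pretrain_epochs = 150, max_joint_epochs = 60, seed = 1)
cs  <- constraint_set(cm$labels, labeled_fraction = 0.10,
                      n_triplets = 10000, seed = 1)
fit <- zc_fit(pd, K = 4, constraints = cs, cfg = cfg)
fit
#> zc_fit: 500 cells, K = 4, 2 joint epochs
#>   cluster sizes: 23 311 60 106

round(cluster_metrics(cm$labels, fit$hard_labels), 3)
#>  nmi  ari  ami  acc
#>    1    1    1    1
```

The four numbers are the agreement between the recovered clusters and the
simulated ground truth: normalized mutual information, adjusted Rand index,
adjusted mutual information, and Hungarian-matched accuracy (all 1.0 =
perfect recovery; the same run without any labeled cells is noticeably
worse on the rare groups). `write_results(fit$hard_labels, fit$z, "out")`
saves the labels and the latent embedding.

The same workflow is scriptable:

```sh
Rscript inst/cli/zinbclust.R simulate --preset splat1 --seed 0 --out sim
Rscript inst/cli/zinbclust.R fit --counts sim.csv --labels sim.labels.tsv \
    --k 4 --labeled-fraction 0.1 --seed 0 --out fit
Rscript inst/cli/zinbclust.R evaluate --truth sim.labels.tsv --pred fit.labels.tsv
```

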