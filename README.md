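# comorbnet

Predicting comorbid disease pairs from the protein–protein interaction
network by geometric embedding.

## The problem

Comorbidity — two diseases co-occurring in the same patients more often
than chance — is measured clinically by the relative risk RR (RR > 1 means
comorbid). Network medicine links it to the interactome: each disease
defines a *module*, the subgraph of its associated genes on the PPI
network, and comorbid pairs tend to share genes and have close modules.
The classical predictor is the module-separation statistic

    S_AB = <d_AB> − (<d_AA> + <d_BB>) / 2,

the difference between cross-module and within-module nearest-neighbour
shortest-path distances (negative = overlapping modules). S_AB sees only
proximity and is a weak ranker of comorbidity.

`comorbnet` implements a richer pipeline for researchers working on
disease networks:

1. **Embed** the interactome's largest connected component into an
   m-dimensional geometric space — classical double-centered
   eigen-embedding of geodesic distances (`embed_mds()`, i.e. Isomap), or
   minimum curvilinear embedding over minimum-spanning-tree distances
   (`embed_mce()`, `embed_ncmce()`), via A = −½ J D² J and
   X = E_m Λ_m^(1/2). Pathway knowledge (GMT gene sets) can weight edges
   by w(e) = 1/(1 + freq(e)) so pathway-supported edges are favoured by
   the spanning tree (`pathway_edge_weights()`).
2. **Fingerprint** each disease pair's gene-set union as an
   (m+3)-dimensional feature vector: the module's projection
   f_i = Σ_g z_i(g) onto each axis, plus mean degree, mean betweenness
   centrality, and mean per-gene pathway count
   (`build_feature_matrix()`).
3. **Classify** pairs as comorbid vs non-comorbid with an SVM (linear,
   RBF with C = 3.5, γ = 1.06, or polynomial of degree 4) or a random
   forest, under stratified 10-fold cross-validation with per-fold
   standardization, reporting precision/recall/F1/accuracy/ROC AUC
   (`cross_validate()`), against the −S_AB baseline ranking
   (`sab_baseline_scores()`).

A synthetic-data module (`synthetic_config()`, `generate_interactome()`,
`generate_pathways()`, `generate_disease_dataset()`,
`randomize_pair_genes()`) builds scale-free interactomes, locally
connected pathway sets and disease-pair datasets with planted comorbidity
structure, so the whole pipeline is testable without external downloads.

## Worked example

A small synthetic benchmark end to end:

```r
library(comorbnet)

cfg <- preset_config("small", seed = 7)       # 400 nodes, 40 disease pairs
g   <- generate_interactome(cfg)
ann <- generate_pathways(g, cfg)
ds  <- generate_disease_dataset(g, ann, cfg)

emb <- embed_mce(g, m = 10)                   # centered MCE embedding
emb
#> <comorb_embedding> mce: 400 nodes x 10 dimensions
#>   leading eigenvalues: 1384.1,  842.6,  560.1,  379.5,  365.6

feats  <- build_feature_matrix(emb, g, ann, ds$pairs, ds$map)
labels <- label_pairs(ds$pairs, threshold = 1)   # comorbid iff RR >= 1

cross_validate(feats, labels, classifier_config("svm_rbf"), k = 5, seed = 1)
#> 5-fold cross-validation means:
#> precision    recall        f1  accuracy   roc_auc
#>    0.8700    0.7500    0.7722    0.8000    0.8500

d <- all_pairs_shortest_paths(g)
roc_auc(sab_baseline_scores(ds$pairs, d, ds$map), labels)
#> [1] 0.67
```

The classifier's mean ROC AUC (0.85 here, ≈ 0.95 at the full benchmark
scale of 2000 nodes / 200 pairs) is the probability that a random comorbid
pair is ranked above a random non-comorbid pair; the module-separation
baseline on the same data reaches only 0.67, because gene sharing and
proximity alone do not determine comorbidity in the planted data (nor in
clinical data).

A command-line front end covers the same pipeline
(`simulate`, `embed`, `featurize`, `baseline`, `evaluate`):

```sh
Rscript inst/cli/comorbnet.R simulate --out data/ --preset small --seed 7
Rscript inst/cli/comorbnet.R embed --edges data/edges.tsv --dim 10 --method mce --out data/emb
Rscript inst/cli/comorbnet.R featurize --edges data/edges.tsv --embedding data/emb.tsv \
    --pathways data/pathways.gmt --disease-genes data/disease_genes.tsv \
    --pairs data/comorbidity.tsv --out data/features.tsv
Rscript inst/cli/comorbnet.R evaluate --features data/features.tsv \
    --threshold 1 --classifier svm_rbf --folds 5 --seed 1 --out-prefix data/run
```

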